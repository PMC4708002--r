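#include <Rcpp.h>
#include "fm.h"
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;
using namespace svbwt;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 3;
    case 'T': case 't': return 4;
    default: return -1;
  }
}

static FMView fm_view(const RawVector& bwt, const IntegerVector& C,
                      const IntegerMatrix& occ) {
  FMView v;
  v.bwt = RAW(bwt);
  v.n = bwt.size();
  v.C = INTEGER(C);
  v.occ = INTEGER(occ);
  v.ncp = occ.nrow();
  return v;
}

static std::vector<uint8_t> code_pattern(const std::string& p) {
  std::vector<uint8_t> out(p.size());
  for (size_t i = 0; i < p.size(); i++) {
    int c = base_code(p[i]);
    if (c < 0) stop("pattern contains a non-ACGT character");
    out[i] = (uint8_t)c;
  }
  return out;
}

// Build BWT + FM structures over a collection of strings. Each entry gets
// its own separator; separator values descend with position so the final
// one is the unique SA-IS sentinel. Separators are collapsed to '$' (0)
// in the stored BWT. Optionally keeps the suffix array and the collapsed
// text (genome index) and computes per-position uniqueness lengths via
// Kasai's LCP construction.
// [[Rcpp::export]]
List fm_build_cpp(CharacterVector entries, bool keep_sa = false,
                  bool compute_mlu = false) {
  int m = entries.size();
  if (m == 0) stop("empty collection");
  long total = 0;
  for (int i = 0; i < m; i++) total += LENGTH(STRING_ELT(entries, i));
  long n = total + m;
  if (n > INT_MAX / 2) stop("collection too large for this index");

  std::vector<int> T((size_t)n);
  {
    long p = 0;
    for (int i = 0; i < m; i++) {
      SEXP s = STRING_ELT(entries, i);
      const char* cs = CHAR(s);
      int len = LENGTH(s);
      for (int k = 0; k < len; k++) {
        int c = base_code(cs[k]);
        if (c < 0) stop("entry %d contains a non-ACGT character", i + 1);
        T[p++] = m + c;  // bases sort above every separator
      }
      T[p++] = m - i;  // separators: descending values, last one is 1
    }
  }

  std::vector<int> SA((size_t)n);
  sais(T.data(), SA.data(), (int)n, m + 5);

  RawVector bwt((R_xlen_t)n);
  for (long i = 0; i < n; i++) {
    long j = SA[i] == 0 ? n - 1 : SA[i] - 1;
    int v = T[j];
    bwt[i] = (Rbyte)(v <= m ? 0 : v - m);
  }

  IntegerVector C(6);
  {
    std::vector<long> cnt(5, 0);
    for (long i = 0; i < n; i++) cnt[bwt[i]]++;
    long s = 0;
    for (int c = 0; c < 5; c++) { C[c] = (int)s; s += cnt[c]; }
    C[5] = (int)s;
  }

  int ncp = (int)(n / CP_STEP) + 1;
  IntegerMatrix occ(ncp, 5);
  {
    int run[5] = {0, 0, 0, 0, 0};
    for (long i = 0; i < n; i++) {
      if (i % CP_STEP == 0) {
        int k = (int)(i / CP_STEP);
        for (int c = 0; c < 5; c++) occ(k, c) = run[c];
      }
      run[bwt[i]]++;
    }
    if (n % CP_STEP == 0) {
      int k = (int)(n / CP_STEP);
      for (int c = 0; c < 5; c++) occ(k, c) = run[c];
    }
  }

  List out = List::create(_["bwt"] = bwt, _["C"] = C, _["occ"] = occ,
                          _["n_entries"] = m, _["n"] = (double)n);

  if (compute_mlu) {
    // Kasai LCP on the distinct-separator text, then per-position
    // uniqueness length = 1 + max(lcp with SA neighbours).
    std::vector<int> isa((size_t)n);
    for (long i = 0; i < n; i++) isa[SA[i]] = (int)i;
    std::vector<int> lcp((size_t)n, 0);  // lcp[i] = LCP(SA[i-1], SA[i])
    int h = 0;
    for (long i = 0; i < n; i++) {
      int r = isa[i];
      if (r > 0) {
        long j = SA[r - 1];
        while (i + h < n && j + h < n && T[i + h] == T[j + h]) h++;
        lcp[r] = h;
        if (h > 0) h--;
      } else {
        h = 0;
      }
    }
    IntegerVector mlu((R_xlen_t)n);
    for (long i = 0; i < n; i++) {
      int r = isa[i];
      int hmax = lcp[r];
      if (r + 1 < n && lcp[r + 1] > hmax) hmax = lcp[r + 1];
      mlu[i] = hmax + 1;  // boundary masking done by the caller
    }
    out["mlu"] = mlu;
  }

  if (keep_sa) {
    IntegerVector sa((R_xlen_t)n);
    std::copy(SA.begin(), SA.end(), sa.begin());
    RawVector text((R_xlen_t)n);
    for (long i = 0; i < n; i++) text[i] = (Rbyte)(T[i] <= m ? 0 : T[i] - m);
    out["sa"] = sa;
    out["text"] = text;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector fm_step_cpp(RawVector bwt, IntegerVector C, IntegerMatrix occ,
                          int lo, int hi, std::string base) {
  FMView v = fm_view(bwt, C, occ);
  if (base.size() != 1) stop("base must be a single character");
  int c = base_code(base[0]);
  if (c < 0) stop("base must be one of A, C, G, T");
  v.step(c, lo, hi);
  return IntegerVector::create(lo, hi);
}

// [[Rcpp::export]]
int fm_count_cpp(RawVector bwt, IntegerVector C, IntegerMatrix occ,
                 std::string pattern) {
  FMView v = fm_view(bwt, C, occ);
  std::vector<uint8_t> p = code_pattern(pattern);
  int lo = 0, hi = v.n;
  for (int i = (int)p.size() - 1; i >= 0 && lo < hi; i--) v.step(p[i], lo, hi);
  return hi - lo;
}

namespace svbwt {
// DFS over leftward extensions of the interval [lo, hi). Emits maximal
// extensions (length == ext_len, or no base extends further). With
// emit_ends additionally emits internal prefixes at which indexed entries
// start (occurrences terminate), which carry their own support.
void fm_enum_ext(const FMView& v, int lo, int hi, int ext_len, bool emit_ends,
                 std::vector<std::string>& exts, std::vector<int>& supports) {
  if (lo >= hi || ext_len < 1) return;
  const char* BASES = "#ACGT";
  struct Frame { int lo, hi, depth, next_c; };
  std::vector<Frame> stack;
  std::string path;  // chars prepended so far, rightmost first
  stack.push_back({lo, hi, 0, 1});

  while (!stack.empty()) {
    Frame& f = stack.back();
    if (f.depth == ext_len) {
      std::string s(path.rbegin(), path.rend());
      exts.push_back(s);
      supports.push_back(f.hi - f.lo);
      stack.pop_back();
      path.pop_back();
      continue;
    }
    if (f.next_c > 4) {
      int child_sum = 0;
      for (int c = 1; c <= 4; c++) {
        int clo = f.lo, chi = f.hi;
        v.step(c, clo, chi);
        child_sum += chi - clo;
      }
      bool leaf = (child_sum == 0);
      bool ends_here = (f.hi - f.lo) > child_sum;
      if (f.depth > 0 && (leaf || (emit_ends && ends_here))) {
        std::string s(path.rbegin(), path.rend());
        exts.push_back(s);
        supports.push_back(f.hi - f.lo);
      }
      bool pop_char = f.depth > 0;
      stack.pop_back();
      if (pop_char) path.pop_back();
      continue;
    }
    int c = f.next_c++;
    int clo = f.lo, chi = f.hi;
    v.step(c, clo, chi);
    if (chi > clo) {
      path.push_back(BASES[c]);
      stack.push_back({clo, chi, f.depth + 1, 1});
    }
  }
}
}  // namespace svbwt

// [[Rcpp::export]]
DataFrame fm_extensions_cpp(RawVector bwt, IntegerVector C, IntegerMatrix occ,
                            std::string seed, int ext_len,
                            bool emit_ends = false) {
  FMView v = fm_view(bwt, C, occ);
  std::vector<uint8_t> p = code_pattern(seed);
  int lo = 0, hi = v.n;
  for (int i = (int)p.size() - 1; i >= 0 && lo < hi; i--) v.step(p[i], lo, hi);

  std::vector<std::string> exts;
  std::vector<int> supports;
  fm_enum_ext(v, lo, hi, ext_len, emit_ends, exts, supports);
  return DataFrame::create(_["extension"] = wrap(exts),
                           _["support"] = wrap(supports),
                           _["stringsAsFactors"] = false);
}

// Reconstruct every indexed entry by LF-walking from its terminator row.
// Entry j's terminator suffix has rank n_entries - 1 - j.
// [[Rcpp::export]]
CharacterVector fm_invert_cpp(RawVector bwt, IntegerVector C,
                              IntegerMatrix occ, int n_entries) {
  FMView v = fm_view(bwt, C, occ);
  const char* BASES = "#ACGT";
  CharacterVector out(n_entries);
  for (int j = 0; j < n_entries; j++) {
    int r = n_entries - 1 - j;
    std::string rev;
    int c = v.bwt[r];
    while (c != 0) {
      rev.push_back(BASES[c]);
      r = v.C[c] + v.rank(c, r);
      c = v.bwt[r];
    }
    std::string s(rev.rbegin(), rev.rend());
    out[j] = s;
  }
  return out;
}

// Exact-seed mapper against a genome FM index (text holds both strands as
// separate entries). Seed = first seed_len bases, searched exactly; on
// zero hits a pigeonhole rescue splits the seed in two halves so any
// single-mismatch seed is still recovered. Candidates are scored by full
// read mismatch count against the text; a unique best placement gets
// MAPQ 60, ties get 0.
// [[Rcpp::export]]
List map_reads_cpp(RawVector bwt, IntegerVector C, IntegerMatrix occ,
                   IntegerVector sa, RawVector text, CharacterVector reads,
                   int seed_len = 30, int max_hits = 100, int mm_cap = 10) {
  FMView v = fm_view(bwt, C, occ);
  const int* SA = INTEGER(sa);
  const Rbyte* TX = RAW(text);
  long ntext = text.size();
  int nr = reads.size();
  IntegerVector pos(nr), mapq(nr), nm(nr);

  std::vector<uint8_t> rc;
  std::vector<int> cand;

  for (int i = 0; i < nr; i++) {
    SEXP s = STRING_ELT(reads, i);
    const char* cs = CHAR(s);
    int rl = LENGTH(s);
    rc.resize(rl);
    bool bad = false;
    for (int k = 0; k < rl; k++) {
      int c = base_code(cs[k]);
      if (c < 0) { bad = true; break; }
      rc[k] = (uint8_t)c;
    }
    int sl = seed_len < rl ? seed_len : rl;
    if (bad || sl < 12) { pos[i] = NA_INTEGER; mapq[i] = 0; nm[i] = NA_INTEGER; continue; }

    cand.clear();
    // exact seed
    int lo = 0, hi = v.n;
    for (int k = sl - 1; k >= 0 && lo < hi; k--) v.step(rc[k], lo, hi);
    int w = hi - lo;
    if (w > 0) {
      int take = w < max_hits ? w : max_hits;
      for (int t = 0; t < take; t++) cand.push_back(SA[lo + t]);
    } else {
      // pigeonhole halves
      int h = sl / 2;
      for (int half = 0; half < 2; half++) {
        int a = half == 0 ? 0 : h;
        int b = half == 0 ? h : sl;
        int l2 = 0, h2 = v.n;
        for (int k = b - 1; k >= a && l2 < h2; k--) v.step(rc[k], l2, h2);
        int w2 = h2 - l2;
        if (w2 > 0 && w2 <= 5 * max_hits) {
          int take = w2 < max_hits ? w2 : max_hits;
          for (int t = 0; t < take; t++) cand.push_back(SA[l2 + t] - a);
        }
      }
    }

    int best_mm = mm_cap + 1, best_pos = -1, best_count = 0;
    for (size_t q = 0; q < cand.size(); q++) {
      long st = cand[q];
      if (st < 0 || st + rl > ntext) continue;
      if (q > 0 && (int)st == best_pos) continue;  // cheap dup guard
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < rl; k++) {
        uint8_t tc = TX[st + k];
        if (tc == 0) { ok = false; break; }  // crosses an entry boundary
        if (tc != rc[k] && ++mm > mm_cap) { ok = false; break; }
      }
      if (!ok) continue;
      if (mm < best_mm) { best_mm = mm; best_pos = (int)st; best_count = 1; }
      else if (mm == best_mm && (int)st != best_pos) best_count++;
    }

    if (best_pos < 0) {
      pos[i] = NA_INTEGER; mapq[i] = 0; nm[i] = NA_INTEGER;
    } else {
      pos[i] = best_pos;  // 0-based text position
      mapq[i] = best_count == 1 ? 60 : 0;
      nm[i] = best_mm;
    }
  }
  return List::create(_["pos"] = pos, _["mapq"] = mapq, _["nm"] = nm);
}
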