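// One scan pass over a breakpoint-region side: for each scan position
// (a text coordinate, visited right to left by the caller-supplied order),
// the uniqueness-length query is looked up in the read dictionary, all
// leftward extensions are enumerated, and each extension branch is scored
// by normalized minimum edit distance against its own local reference
// context and against both strands of the partner region sequence.
#include <Rcpp.h>
#include "fm.h"
#include <vector>
#include <string>
using namespace Rcpp;
using namespace svbwt;

// [[Rcpp::export]]
List scan_pass_cpp(RawVector bwt, IntegerVector C, IntegerMatrix occ,
                   RawVector text, IntegerVector positions,
                   IntegerVector qlens, RawVector partner_fwd,
                   RawVector partner_rc, int ext_len, int own_pad,
                   bool emit_ends = true) {
  FMView v;
  v.bwt = RAW(bwt);
  v.n = bwt.size();
  v.C = INTEGER(C);
  v.occ = INTEGER(occ);
  v.ncp = occ.nrow();
  const Rbyte* TX = RAW(text);
  long ntext = text.size();
  const Rbyte* PF = RAW(partner_fwd);
  int npf = partner_fwd.size();
  const Rbyte* PR = RAW(partner_rc);
  int npr = partner_rc.size();
  int np = positions.size();

  IntegerVector qcount(np);
  std::vector<int> o_pos;
  std::vector<std::string> o_ext;
  std::vector<int> o_sup, o_endf, o_endr;
  std::vector<double> o_down, o_dpf, o_dpr;

  std::vector<std::string> exts;
  std::vector<int> sups;
  std::vector<uint8_t> pat;

  for (int k = 0; k < np; k++) {
    int p = positions[k];
    int ql = qlens[k];
    if (ql == NA_INTEGER || ql <= 0 || p < 0 || p + ql > ntext) {
      qcount[k] = NA_INTEGER;
      continue;
    }
    // backward search of the query text[p .. p+ql)
    int lo = 0, hi = v.n;
    bool ok = true;
    for (int i = ql - 1; i >= 0 && lo < hi; i--) {
      uint8_t c = TX[p + i];
      if (c == 0) { ok = false; break; }
      v.step(c, lo, hi);
    }
    if (!ok) { qcount[k] = NA_INTEGER; continue; }
    qcount[k] = hi - lo;
    if (lo >= hi) continue;

    exts.clear();
    sups.clear();
    fm_enum_ext(v, lo, hi, ext_len, emit_ends, exts, sups);

    for (size_t e = 0; e < exts.size(); e++) {
      const std::string& s = exts[e];
      int blen = (int)s.size();
      pat.resize(blen);
      for (int i = 0; i < blen; i++) {
        switch (s[i]) {
          case 'A': pat[i] = 1; break;
          case 'C': pat[i] = 2; break;
          case 'G': pat[i] = 3; break;
          default: pat[i] = 4;
        }
      }
      // own reference context: the scanned text immediately left of the
      // query, padded on both sides
      long a = (long)p - blen - own_pad;
      if (a < 0) a = 0;
      long b = (long)p + own_pad;
      if (b > ntext) b = ntext;
      int dow = myers_min(pat.data(), blen, TX + a, (int)(b - a), nullptr);
      int ef = -1, er = -1;
      int dpf = myers_min(pat.data(), blen, PF, npf, &ef);
      int dpr = myers_min(pat.data(), blen, PR, npr, &er);

      o_pos.push_back(p);
      o_ext.push_back(s);
      o_sup.push_back(sups[e]);
      o_down.push_back((double)dow / blen);
      o_dpf.push_back((double)dpf / blen);
      o_dpr.push_back((double)dpr / blen);
      o_endf.push_back(ef + 1);  // 1-based index into partner_fwd
      o_endr.push_back(er + 1);  // 1-based index into partner_rc
    }
  }

  DataFrame br = DataFrame::create(
      _["pos"] = wrap(o_pos), _["extension"] = wrap(o_ext),
      _["support"] = wrap(o_sup), _["d_own"] = wrap(o_down),
      _["d_partner_fwd"] = wrap(o_dpf), _["d_partner_rc"] = wrap(o_dpr),
      _["end_fwd"] = wrap(o_endf), _["end_rc"] = wrap(o_endr),
      _["stringsAsFactors"] = false);
  return List::create(_["branches"] = br, _["query_count"] = qcount);
}
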