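// Myers (1999) bit-parallel approximate matching: minimum edit distance of
// a pattern against any substring of a text (semi-global; text start and
// end free, pattern fully consumed), with the end position of the best
// alignment. Patterns up to 64 symbols run in one machine word; longer
// patterns fall back to the classic dynamic program.
#include <Rcpp.h>
#include "fm.h"
#include <vector>
#include <string>
using namespace Rcpp;

namespace svbwt {

int myers_min(const uint8_t* pat, int m, const uint8_t* txt, int n,
              int* end_pos) {
  if (m <= 0) { if (end_pos) *end_pos = 0; return 0; }
  if (n <= 0) { if (end_pos) *end_pos = 0; return m; }
  if (m <= 64) {
    uint64_t Peq[5] = {0, 0, 0, 0, 0};
    for (int k = 0; k < m; k++) Peq[pat[k]] |= (uint64_t)1 << k;
    Peq[0] = 0;  // entry separators never match
    uint64_t Pv = ~(uint64_t)0, Mv = 0;
    uint64_t Hmask = (uint64_t)1 << (m - 1);
    int score = m, best = m + 1, best_end = -1;
    for (int j = 0; j < n; j++) {
      uint64_t Eq = Peq[txt[j]];
      uint64_t Xv = Eq | Mv;
      uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      if (Ph & Hmask) score++;
      else if (Mh & Hmask) score--;
      Ph <<= 1;
      Mh <<= 1;
      Pv = Mh | ~(Xv | Ph);
      Mv = Ph & Xv;
      if (score < best) { best = score; best_end = j; }
    }
    if (best > m) best = m;
    if (end_pos) *end_pos = best_end;
    return best;
  }
  // classic DP, first row zero (free text prefix)
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; j++) prev[j] = 0;
  for (int i = 1; i <= m; i++) {
    cur[0] = i;
    for (int j = 1; j <= n; j++) {
      int sub = prev[j - 1] + (pat[i - 1] == txt[j - 1] && pat[i - 1] != 0 ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int v = sub < del ? sub : del;
      cur[j] = v < ins ? v : ins;
    }
    std::swap(prev, cur);
  }
  int best = prev[1], best_end = 0;
  for (int j = 2; j <= n; j++)
    if (prev[j] < best) { best = prev[j]; best_end = j - 1; }
  if (end_pos) *end_pos = best_end;
  return best;
}

}  // namespace svbwt

static void code_str(const std::string& s, std::vector<uint8_t>& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); i++) {
    switch (s[i]) {
      case 'A': case 'a': out[i] = 1; break;
      case 'C': case 'c': out[i] = 2; break;
      case 'G': case 'g': out[i] = 3; break;
      case 'T': case 't': out[i] = 4; break;
      default: out[i] = 0;
    }
  }
}

// [[Rcpp::export]]
List min_edit_distance_cpp(std::string pattern, std::string text) {
  std::vector<uint8_t> p, t;
  code_str(pattern, p);
  code_str(text, t);
  int end = -1;
  int d = svbwt::myers_min(p.data(), (int)p.size(), t.data(), (int)t.size(), &end);
  return List::create(_["distance"] = d, _["end"] = end + 1);  // 1-based end
}
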