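// Shared view over an FM-index stored as plain R vectors:
// bwt  : raw vector, symbols 0='$', 1..4 = A,C,G,T
// C    : integer[6], C[c] = number of bwt symbols < c (cumulative starts)
// occ  : integer matrix (ncp x 5, column-major), occ[c*ncp + k] =
//        count of symbol c in bwt[0 .. 64*k)
#ifndef SVBWT_FM_H
#define SVBWT_FM_H

#include <cstdint>

namespace svbwt {

const int CP_STEP = 64;

struct FMView {
  const uint8_t* bwt;
  int n;
  const int* C;
  const int* occ;
  int ncp;

  // occurrences of symbol c in bwt[0..i)
  inline int rank(int c, int i) const {
    int k = i / CP_STEP;
    int r = occ[(long)c * ncp + k];
    for (int j = k * CP_STEP; j < i; j++)
      if (bwt[j] == c) r++;
    return r;
  }

  // one backward-search step with symbol c on half-open interval [lo, hi)
  inline void step(int c, int& lo, int& hi) const {
    lo = C[c] + rank(c, lo);
    hi = C[c] + rank(c, hi);
  }
};

void sais(const int* T, int* SA, int n, int K);

int myers_min(const uint8_t* pat, int m, const uint8_t* txt, int n,
              int* end_pos);

#include <string>
#include <vector>
void fm_enum_ext(const FMView& v, int lo, int hi, int ext_len, bool emit_ends,
                 std::vector<std::string>& exts, std::vector<int>& supports);

}  // namespace svbwt

#endif
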