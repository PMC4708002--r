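// SA-IS suffix-array construction (Nong, Zhang & Chan induced sorting)
// over an integer alphabet. The last symbol of the input must be the
// unique minimum (sentinel); callers arrange this by giving the final
// entry separator the smallest value.
#include <vector>
#include <algorithm>
#include <cstdint>

namespace svbwt {

static void get_buckets(const int* T, int n, int K, std::vector<int>& bkt, bool end) {
  std::fill(bkt.begin(), bkt.end(), 0);
  for (int i = 0; i < n; i++) bkt[T[i]]++;
  int sum = 0;
  for (int k = 0; k < K; k++) {
    sum += bkt[k];
    bkt[k] = end ? sum : sum - bkt[k];
  }
}

static void induce_L(const std::vector<uint8_t>& t, int* SA, const int* T,
                     int n, int K, std::vector<int>& bkt) {
  get_buckets(T, n, K, bkt, false);
  for (int i = 0; i < n; i++) {
    int j = SA[i] - 1;
    if (SA[i] > 0 && !t[j]) SA[bkt[T[j]]++] = j;
  }
}

static void induce_S(const std::vector<uint8_t>& t, int* SA, const int* T,
                     int n, int K, std::vector<int>& bkt) {
  get_buckets(T, n, K, bkt, true);
  for (int i = n - 1; i >= 0; i--) {
    int j = SA[i] - 1;
    if (SA[i] > 0 && t[j]) SA[--bkt[T[j]]] = j;
  }
}

#define IS_LMS(i) ((i) > 0 && t[i] && !t[(i) - 1])

void sais(const int* T, int* SA, int n, int K) {
  if (n == 1) { SA[0] = 0; return; }
  std::vector<uint8_t> t(n);
  t[n - 1] = 1;                      // sentinel is S-type
  t[n - 2] = 0;                      // sentinel is unique minimum
  for (int i = n - 3; i >= 0; i--)
    t[i] = (T[i] < T[i + 1] || (T[i] == T[i + 1] && t[i + 1])) ? 1 : 0;

  std::vector<int> bkt(K);

  // stage 1: sort LMS suffixes approximately, then refine by recursion
  get_buckets(T, n, K, bkt, true);
  std::fill(SA, SA + n, -1);
  for (int i = 1; i < n; i++)
    if (IS_LMS(i)) SA[--bkt[T[i]]] = i;
  induce_L(t, SA, T, n, K, bkt);
  induce_S(t, SA, T, n, K, bkt);

  // compact sorted LMS substrings into SA[0..n1)
  int n1 = 0;
  for (int i = 0; i < n; i++)
    if (IS_LMS(SA[i])) SA[n1++] = SA[i];

  // name LMS substrings
  std::fill(SA + n1, SA + n, -1);
  int name = 0, prev = -1;
  for (int i = 0; i < n1; i++) {
    int pos = SA[i];
    bool diff = false;
    for (int d = 0; d < n; d++) {
      if (prev == -1 || T[pos + d] != T[prev + d] || t[pos + d] != t[prev + d]) {
        diff = true;
        break;
      }
      if (d > 0 && (IS_LMS(pos + d) || IS_LMS(prev + d))) break;
    }
    if (diff) { name++; prev = pos; }
    SA[n1 + pos / 2] = name - 1;
  }
  for (int i = n - 1, j = n - 1; i >= n1; i--)
    if (SA[i] >= 0) SA[j--] = SA[i];

  // recurse if names are not yet unique
  int* SA1 = SA;
  int* s1 = SA + n - n1;
  if (name < n1) {
    sais(s1, SA1, n1, name);
  } else {
    for (int i = 0; i < n1; i++) SA1[s1[i]] = i;
  }

  // map the order of LMS suffixes back to text positions
  {
    std::vector<int> lms;
    lms.reserve(n1);
    for (int i = 1; i < n; i++)
      if (IS_LMS(i)) lms.push_back(i);
    for (int i = 0; i < n1; i++) SA1[i] = lms[SA1[i]];
  }

  // stage 3: induce the full suffix array from the sorted LMS suffixes
  get_buckets(T, n, K, bkt, true);
  std::fill(SA + n1, SA + n, -1);
  for (int i = n1 - 1; i >= 0; i--) {
    int j = SA[i];
    SA[i] = -1;
    SA[--bkt[T[j]]] = j;
  }
  induce_L(t, SA, T, n, K, bkt);
  induce_S(t, SA, T, n, K, bkt);
}

#undef IS_LMS

}  // namespace svbwt
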