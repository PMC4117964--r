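#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend, i.e. the first gapped base pays both the
// opening and the extension penalty. 'N' never matches anything.
// Tie-break for the optimum: smallest end coordinate in `a`, then in `b`
// (first maximum encountered scanning rows then columns, strict updates).

static inline int subst(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // H/E/F stored row-wise; traceback bytes per matrix.
  // tbH: 0 = stop at zero, 1 = diagonal, 2 = from E (gap in a), 3 = from F.
  // tbE: 0 = opened from H, 1 = extended from E. tbF likewise from H/F.
  const size_t W = (size_t)m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0), E(H), F(H);
  std::vector<unsigned char> tbH(H.size(), 0), tbE(H.size(), 0), tbF(H.size(), 0);
  const int NEG = -1000000000;
  for (size_t j = 0; j <= (size_t)m; ++j) { E[j] = NEG; F[j] = NEG; }
  for (size_t i = 0; i <= (size_t)n; ++i) { E[i * W] = NEG; F[i * W] = NEG; }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j;
      int eOpen = H[c - 1] + gap_open + gap_extend;
      int eExt  = E[c - 1] + gap_extend;
      E[c] = (eOpen >= eExt) ? eOpen : eExt;
      tbE[c] = (eOpen >= eExt) ? 0 : 1;
      int fOpen = H[c - W] + gap_open + gap_extend;
      int fExt  = F[c - W] + gap_extend;
      F[c] = (fOpen >= fExt) ? fOpen : fExt;
      tbF[c] = (fOpen >= fExt) ? 0 : 1;
      int diag = H[c - W - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      H[c] = h; tbH[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int a_end = bi, b_end = bj, a_start = 0, b_start = 0;
  int align_len = 0, n_match = 0;
  if (best > 0) {
    int i = bi, j = bj; int state = 0; // 0 = H, 1 = E, 2 = F
    while (true) {
      const size_t c = (size_t)i * W + j;
      if (state == 0) {
        unsigned char t = tbH[c];
        if (t == 0) break;
        if (t == 1) {
          ++align_len;
          if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++n_match;
          --i; --j;
        } else if (t == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        ++align_len;
        state = (tbE[c] == 0) ? 0 : 1;
        --j;
      } else {
        ++align_len;
        state = (tbF[c] == 0) ? 0 : 2;
        --i;
      }
    }
    a_start = i + 1; b_start = j + 1; // 1-based inclusive
  } else {
    a_end = 0; b_end = 0; // empty alignment
  }

  return List::create(
    _["score"] = best,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["align_len"] = align_len, _["n_match"] = n_match);
}
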