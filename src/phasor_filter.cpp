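#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// symmetric (reflect) padding: -1 -> 0, n -> n-1, -2 -> 1, ...
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline double median_of(std::vector<double>& buf) {
  const size_t k = buf.size() / 2;
  std::nth_element(buf.begin(), buf.begin() + k, buf.end());
  double hi = buf[k];
  if (buf.size() % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + k);
  return 0.5 * (lo + hi);
}

// Sliding-window statistic of a complex field given as (re, im), window
// wr x wc (odd), reflect padding. mode: mean of re/im, or marginal median
// (median of re and of im independently). Returns the complex statistic
// per pixel as two matrices.
// [[Rcpp::export(name = ".phasor_window_stat")]]
List phasor_window_stat(NumericMatrix re, NumericMatrix im,
                        int wr, int wc, bool use_median) {
  const int n = re.nrow(), m = re.ncol();
  const int hr = (wr - 1) / 2, hc = (wc - 1) / 2;
  NumericMatrix out_re(n, m), out_im(n, m);
  std::vector<double> bre(wr * wc), bim(wr * wc);
  std::vector<int> ridx(wr), cidx(wc);

  for (int j = 0; j < m; ++j) {
    for (int dc = -hc; dc <= hc; ++dc) cidx[dc + hc] = reflect_index(j + dc, m);
    for (int i = 0; i < n; ++i) {
      for (int dr = -hr; dr <= hr; ++dr) ridx[dr + hr] = reflect_index(i + dr, n);
      if (use_median) {
        int t = 0;
        for (int b = 0; b < wc; ++b) {
          const int jj = cidx[b];
          for (int a = 0; a < wr; ++a, ++t) {
            bre[t] = re(ridx[a], jj);
            bim[t] = im(ridx[a], jj);
          }
        }
        out_re(i, j) = median_of(bre);
        out_im(i, j) = median_of(bim);
      } else {
        double sre = 0.0, sim = 0.0;
        for (int b = 0; b < wc; ++b) {
          const int jj = cidx[b];
          for (int a = 0; a < wr; ++a) {
            sre += re(ridx[a], jj);
            sim += im(ridx[a], jj);
          }
        }
        const double inv = 1.0 / (wr * wc);
        out_re(i, j) = sre * inv;
        out_im(i, j) = sim * inv;
      }
    }
  }
  return List::create(_["re"] = out_re, _["im"] = out_im);
}
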