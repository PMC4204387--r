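#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// reflect index into [0, n): symmetric padding including the edge pixel
static inline int reflect(int idx, int n) {
  if (n == 1) return 0;
  while (idx < 0 || idx >= n) {
    if (idx < 0) idx = -idx - 1;
    if (idx >= n) idx = 2 * n - idx - 1;
  }
  return idx;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int wr, int wc) {
  const int nr = x.nrow(), nc = x.ncol();
  const int hr = wr / 2, hc = wc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(static_cast<size_t>(wr) * wc);
  const int mid = (wr * wc) / 2;  // odd*odd window: exact middle order stat

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -hc; dj <= hc; ++dj) {
        const int cj = reflect(j + dj, nc);
        for (int di = -hr; di <= hr; ++di) {
          buf[k++] = x(reflect(i + di, nr), cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}
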