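#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact square-window median filter applied independently to each frame of
// a [ny, nx, nframes] stack, with replicated borders.  window is the full
// (odd) side length.
// [[Rcpp::export(name = ".medianFilterStackCpp")]]
NumericVector medianFilterStackCpp(NumericVector stack, int ny, int nx,
                                   int nframes, int window) {
  if (window % 2 != 1 || window < 1)
    stop("window must be an odd positive integer");
  if (window == 1) return clone(stack);
  NumericVector out(stack.size());
  if (window == 3) {
    // branchless 19-exchange median-of-9 network per pixel
    for (int f = 0; f < nframes; ++f) {
      const double *in = &stack[(R_xlen_t)f * ny * nx];
      double *o = &out[(R_xlen_t)f * ny * nx];
      for (int j = 0; j < nx; ++j) {
        const int jm = j > 0 ? j - 1 : 0, jp = j < nx - 1 ? j + 1 : nx - 1;
        for (int i = 0; i < ny; ++i) {
          const int im = i > 0 ? i - 1 : 0, ip = i < ny - 1 ? i + 1 : ny - 1;
          double p0 = in[im + (R_xlen_t)jm * ny], p1 = in[i + (R_xlen_t)jm * ny],
                 p2 = in[ip + (R_xlen_t)jm * ny], p3 = in[im + (R_xlen_t)j * ny],
                 p4 = in[i + (R_xlen_t)j * ny],  p5 = in[ip + (R_xlen_t)j * ny],
                 p6 = in[im + (R_xlen_t)jp * ny], p7 = in[i + (R_xlen_t)jp * ny],
                 p8 = in[ip + (R_xlen_t)jp * ny];
          double t;
#define SWAP(a, b) { t = std::min(a, b); b = std::max(a, b); a = t; }
          SWAP(p1, p2); SWAP(p4, p5); SWAP(p7, p8);
          SWAP(p0, p1); SWAP(p3, p4); SWAP(p6, p7);
          SWAP(p1, p2); SWAP(p4, p5); SWAP(p7, p8);
          SWAP(p0, p3); SWAP(p5, p8); SWAP(p4, p7);
          SWAP(p3, p6); SWAP(p1, p4); SWAP(p2, p5);
          SWAP(p4, p7); SWAP(p4, p2); SWAP(p6, p4);
          SWAP(p4, p2);
#undef SWAP
          o[i + (R_xlen_t)j * ny] = p4;
        }
      }
    }
    return out;
  }
  const int half = window / 2;
  const int wsz = window * window;
  std::vector<double> buf(wsz);
  for (int f = 0; f < nframes; ++f) {
    const double *in = &stack[(R_xlen_t)f * ny * nx];
    double *o = &out[(R_xlen_t)f * ny * nx];
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        int k = 0;
        for (int dj = -half; dj <= half; ++dj) {
          int jj = std::min(std::max(j + dj, 0), nx - 1);
          for (int di = -half; di <= half; ++di) {
            int ii = std::min(std::max(i + di, 0), ny - 1);
            buf[k++] = in[ii + (R_xlen_t)jj * ny];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + wsz / 2,
                         buf.begin() + wsz);
        o[i + (R_xlen_t)j * ny] = buf[wsz / 2];
      }
    }
  }
  return out;
}
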