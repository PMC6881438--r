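#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

//' Sum-of-squared-differences over a window of integer shifts
//'
//' Evaluates, for every integer shift (dy, dx) with |dy|, |dx| <= radius,
//' the SSD between `templ` and `frame` translated by (dy, dx) with edge
//' replication. Row r / column c of the result correspond to
//' dy = r - radius - 1 and dx = c - radius - 1 (1-based).
//'
//' @param frame,templ numeric matrices of identical dimensions.
//' @param radius maximum shift in pixels.
//' @return a (2*radius+1) x (2*radius+1) matrix of SSD values.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix ssd_shift_search(NumericMatrix frame, NumericMatrix templ, int radius) {
  int ny = frame.nrow(), nx = frame.ncol();
  if (templ.nrow() != ny || templ.ncol() != nx)
    stop("frame and template dimensions differ");
  if (radius < 0 || 2 * radius >= ny || 2 * radius >= nx)
    stop("search radius must be non-negative and smaller than half the frame");
  int w = 2 * radius + 1;
  NumericMatrix out(w, w);
  for (int dy = -radius; dy <= radius; ++dy) {
    for (int dx = -radius; dx <= radius; ++dx) {
      double s = 0.0;
      for (int x = 0; x < nx; ++x) {
        int xs = clampi(x - dx, 0, nx - 1);
        for (int y = 0; y < ny; ++y) {
          int ys = clampi(y - dy, 0, ny - 1);
          double d = templ(y, x) - frame(ys, xs);
          s += d * d;
        }
      }
      out(dy + radius, dx + radius) = s;
    }
  }
  return out;
}

//' Translate an image by an integer shift with edge replication
//'
//' out[y, x] = img[y - dy, x - dx], indices clamped to the image border.
//' Positive dy moves content down, positive dx moves it right.
//'
//' @param img numeric matrix.
//' @param dy,dx integer shift in pixels.
//' @return shifted matrix of the same dimensions.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix shift_replicate(NumericMatrix img, int dy, int dx) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    int xs = clampi(x - dx, 0, nx - 1);
    for (int y = 0; y < ny; ++y) {
      int ys = clampi(y - dy, 0, ny - 1);
      out(y, x) = img(ys, xs);
    }
  }
  return out;
}
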