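#include <Rcpp.h>
using namespace Rcpp;

// Patch extremum (min or max) over a square window clipped at the image
// boundary.  Returns the extremal value per pixel together with the 1-based
// (row, col) coordinates of the attaining pixel.  Ties are broken by the
// first occurrence in row-major scan order over the patch, so the selection
// map is deterministic.
// [[Rcpp::export]]
List patch_extremum_cpp(NumericMatrix img, int patch_size, bool maximum) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (patch_size - 1) / 2;
  NumericMatrix val(nr, nc);
  IntegerMatrix argr(nr, nc), argc(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int c0 = std::max(0, j - r), c1 = std::min(nc - 1, j + r);
    for (int i = 0; i < nr; ++i) {
      const int r0 = std::max(0, i - r), r1 = std::min(nr - 1, i + r);
      double best = img(r0, c0);
      int br = r0, bc = c0;
      for (int ii = r0; ii <= r1; ++ii) {       // row-major over the patch
        for (int jj = c0; jj <= c1; ++jj) {
          const double v = img(ii, jj);
          if (maximum ? (v > best) : (v < best)) {
            best = v; br = ii; bc = jj;
          }
        }
      }
      val(i, j) = best;
      argr(i, j) = br + 1;
      argc(i, j) = bc + 1;
    }
  }
  return List::create(_["values"] = val, _["arg_row"] = argr,
                      _["arg_col"] = argc);
}

// Direct 2-D convolution with a unit-mass kernel, borders clipped and the
// kernel mass renormalized over the in-bounds support.  The kernel center is
// at ((k-1)/2, (k-1)/2); convolution flips the kernel.
// [[Rcpp::export]]
NumericMatrix conv2_clip_cpp(NumericMatrix img, NumericMatrix kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kern.nrow(), kc = kern.ncol();
  const int rr = (kr - 1) / 2, rc = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0, mass = 0.0;
      for (int a = 0; a < kr; ++a) {
        const int ii = i - (a - rr);  // flipped kernel: src = i - offset
        if (ii < 0 || ii >= nr) continue;
        for (int b = 0; b < kc; ++b) {
          const int jj = j - (b - rc);
          if (jj < 0 || jj >= nc) continue;
          acc += kern(a, b) * img(ii, jj);
          mass += kern(a, b);
        }
      }
      out(i, j) = mass > 0.0 ? acc / mass : 0.0;
    }
  }
  return out;
}

// Plain 'valid' cross-correlation used by the SSIM window statistics:
// output size (nr-kr+1) x (nc-kc+1), no flipping, no renormalization.
// [[Rcpp::export]]
NumericMatrix filter2_valid_cpp(NumericMatrix img, NumericMatrix kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kern.nrow(), kc = kern.ncol();
  const int outr = nr - kr + 1, outc = nc - kc + 1;
  NumericMatrix out(outr, outc);
  for (int j = 0; j < outc; ++j) {
    for (int i = 0; i < outr; ++i) {
      double acc = 0.0;
      for (int a = 0; a < kr; ++a)
        for (int b = 0; b < kc; ++b)
          acc += kern(a, b) * img(i + a, j + b);
      out(i, j) = acc;
    }
  }
  return out;
}
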