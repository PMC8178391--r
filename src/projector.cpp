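#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray-driven parallel-beam projector with unit steps along the ray and
// bilinear interpolation of the image at every sample point.  The
// backprojector scatters with the identical weights, so it is the exact
// transpose of the forward operator and the adjoint identity
// <Ax, y> == <x, A^T y> holds to rounding error by construction.
//
// Conventions: pixel (i, j) of an N x N image (column-major, i fastest) is
// centred at (i - c, j - c) with c = (N - 1) / 2.  Angle 0 sends rays along
// the +x axis; the detector axis is (-sin t, cos t) and detector bin p sits
// at offset (p - rotation_center) * pixel_size.  Object rotation is
// counterclockwise.  Rays are sampled at unit (1 pixel) spacing; samples
// falling outside the image contribute zero, so detector truncation simply
// drops the part of the object outside the field of view.

static inline void ray_sample_bounds(int N, double &smax) {
  // half-diagonal plus one step of slack
  smax = 0.5 * std::sqrt(2.0) * N + 1.0;
}

// [[Rcpp::export(name = ".fp_cpp")]]
NumericMatrix fp_cpp(NumericMatrix image, NumericVector angles,
                     int ndet, double center, double pixel_size) {
  const int N = image.nrow();
  if (image.ncol() != N) stop("image must be square");
  const int nang = angles.size();
  NumericMatrix sino(nang, ndet);
  const double c = 0.5 * (N - 1);
  double smax;
  ray_sample_bounds(N, smax);
  const int ns = (int)std::floor(smax);
  const double *img = image.begin();

  for (int a = 0; a < nang; ++a) {
    const double th = angles[a];
    const double dx = std::cos(th), dy = std::sin(th);
    const double ux = -dy, uy = dx;
    for (int p = 0; p < ndet; ++p) {
      const double t = (p - center) * pixel_size;
      double acc = 0.0;
      const double bx = t * ux + c, by = t * uy + c;
      for (int s = -ns; s <= ns; ++s) {
        const double gx = bx + s * dx;
        const double gy = by + s * dy;
        const int i0 = (int)std::floor(gx);
        const int j0 = (int)std::floor(gy);
        if (i0 < -1 || i0 > N - 1 || j0 < -1 || j0 > N - 1) continue;
        const double fx = gx - i0, fy = gy - j0;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy,       w11 = fx * fy;
        if (i0 >= 0 && j0 >= 0)             acc += w00 * img[i0 + N * j0];
        if (i0 + 1 < N && j0 >= 0)          acc += w10 * img[i0 + 1 + N * j0];
        if (i0 >= 0 && j0 + 1 < N)          acc += w01 * img[i0 + N * (j0 + 1)];
        if (i0 + 1 < N && j0 + 1 < N)       acc += w11 * img[i0 + 1 + N * (j0 + 1)];
      }
      sino(a, p) = acc;  // unit step length => sum approximates the line integral
    }
  }
  return sino;
}

// [[Rcpp::export(name = ".bp_cpp")]]
NumericMatrix bp_cpp(NumericMatrix sino, NumericVector angles,
                     int N, double center, double pixel_size) {
  const int nang = angles.size();
  if (sino.nrow() != nang) stop("sinogram rows must match angle count");
  const int ndet = sino.ncol();
  NumericMatrix image(N, N);
  const double c = 0.5 * (N - 1);
  double smax;
  ray_sample_bounds(N, smax);
  const int ns = (int)std::floor(smax);
  double *img = image.begin();

  for (int a = 0; a < nang; ++a) {
    const double th = angles[a];
    const double dx = std::cos(th), dy = std::sin(th);
    const double ux = -dy, uy = dx;
    for (int p = 0; p < ndet; ++p) {
      const double v = sino(a, p);
      if (v == 0.0) continue;
      const double t = (p - center) * pixel_size;
      const double bx = t * ux + c, by = t * uy + c;
      for (int s = -ns; s <= ns; ++s) {
        const double gx = bx + s * dx;
        const double gy = by + s * dy;
        const int i0 = (int)std::floor(gx);
        const int j0 = (int)std::floor(gy);
        if (i0 < -1 || i0 > N - 1 || j0 < -1 || j0 > N - 1) continue;
        const double fx = gx - i0, fy = gy - j0;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy,       w11 = fx * fy;
        if (i0 >= 0 && j0 >= 0)             img[i0 + N * j0]             += w00 * v;
        if (i0 + 1 < N && j0 >= 0)          img[i0 + 1 + N * j0]         += w10 * v;
        if (i0 >= 0 && j0 + 1 < N)          img[i0 + N * (j0 + 1)]       += w01 * v;
        if (i0 + 1 < N && j0 + 1 < N)       img[i0 + 1 + N * (j0 + 1)]   += w11 * v;
      }
    }
  }
  return image;
}
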