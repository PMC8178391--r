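#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Width-1 mixed-scale dense network.
//
// Hidden layer i (1-based) consumes the input channels plus every previous
// feature map, applies one 3x3 convolution per incoming map with dilation
// d_i = ((i - 1) mod dilation_cycle) + 1, adds a bias, and applies ReLU,
// producing a single feature map.  The output layer is a 1x1 linear map over
// all feature maps and input channels.  Padding is reflect-without-edge by
// default (index -1 maps to 1); a periodic mode exists as a test hook, and
// `linear_act` replaces ReLU by the identity so the whole network becomes a
// linear operator (used by the loss-decomposition checks).
//
// Weight vector layout (doubles, in order):
//   for i in 1..depth: for c in 0..(in_ch + i - 2): 9 taps; then 1 bias
//   for o in 1..out_ch: (in_ch + depth) weights; then 1 bias
// Tap k = (ki + 1) + 3 * (kj + 1) corresponds to source pixel
// (x + ki * d, y + kj * d), ki/kj in {-1, 0, 1}.

struct IdxMaps {
  std::vector<int> lo, hi;  // lo[i] = index of (i - d), hi[i] = index of (i + d)
};

static IdxMaps make_idx(int N, int d, int pad_mode) {
  IdxMaps m;
  m.lo.resize(N);
  m.hi.resize(N);
  for (int i = 0; i < N; ++i) {
    int a = i - d, b = i + d;
    if (pad_mode == 1) {  // periodic
      a = ((a % N) + N) % N;
      b = b % N;
    } else {              // reflect about the boundary, excluding the edge
      if (a < 0) a = -a;
      if (b > N - 1) b = 2 * (N - 1) - b;
      if (a < 0) a = 0;              // only reachable when d >= N
      if (b > N - 1) b = N - 1;
    }
    m.lo[i] = a;
    m.hi[i] = b;
  }
  return m;
}

// out += 3x3 dilated conv of `in` with taps w[9]
static void conv3x3_acc(const double *__restrict in, double *__restrict out,
                        int N, int d, const double *__restrict w,
                        const IdxMaps &ix) {
  for (int j = 0; j < N; ++j) {
    const double *__restrict rm = in + (size_t)N * ix.lo[j];
    const double *__restrict r0 = in + (size_t)N * j;
    const double *__restrict rp = in + (size_t)N * ix.hi[j];
    double *__restrict o = out + (size_t)N * j;
    const int lo_end = d < N ? d : N;         // [0, lo_end): left edge
    const int hi_beg = N - d > d ? N - d : d; // [hi_beg, N): right edge
    for (int i = 0; i < lo_end; ++i) {
      const int a = ix.lo[i], b = ix.hi[i];
      o[i] += w[0] * rm[a] + w[1] * rm[i] + w[2] * rm[b]
            + w[3] * r0[a] + w[4] * r0[i] + w[5] * r0[b]
            + w[6] * rp[a] + w[7] * rp[i] + w[8] * rp[b];
    }
    for (int i = d; i < N - d; ++i) {
      o[i] += w[0] * rm[i - d] + w[1] * rm[i] + w[2] * rm[i + d]
            + w[3] * r0[i - d] + w[4] * r0[i] + w[5] * r0[i + d]
            + w[6] * rp[i - d] + w[7] * rp[i] + w[8] * rp[i + d];
    }
    for (int i = hi_beg; i < N; ++i) {
      const int a = ix.lo[i], b = ix.hi[i];
      o[i] += w[0] * rm[a] + w[1] * rm[i] + w[2] * rm[b]
            + w[3] * r0[a] + w[4] * r0[i] + w[5] * r0[b]
            + w[6] * rp[a] + w[7] * rp[i] + w[8] * rp[b];
    }
  }
}

// gw[k] += sum over pixels of g[i,j] * act[shift_k(i,j)]   (weight gradient)
// gin[shift_k(i,j)] += w[k] * g[i,j]                       (input gradient)
static void conv3x3_backward(const double *g, const double *act, double *gin,
                             const double *w, double *gw, int N, int d,
                             const IdxMaps &ix) {
  for (int j = 0; j < N; ++j) {
    const int jm = ix.lo[j], jp = ix.hi[j];
    const double *gr = g + (size_t)N * j;
    const double *am = act + (size_t)N * jm;
    const double *a0 = act + (size_t)N * j;
    const double *ap = act + (size_t)N * jp;
    double *im = gin + (size_t)N * jm;
    double *i0 = gin + (size_t)N * j;
    double *ip = gin + (size_t)N * jp;
    for (int i = 0; i < N; ++i) {
      const double v = gr[i];
      if (v == 0.0) continue;
      const int a = ix.lo[i], b = ix.hi[i];
      gw[0] += v * am[a]; gw[1] += v * am[i]; gw[2] += v * am[b];
      gw[3] += v * a0[a]; gw[4] += v * a0[i]; gw[5] += v * a0[b];
      gw[6] += v * ap[a]; gw[7] += v * ap[i]; gw[8] += v * ap[b];
      im[a] += w[0] * v; im[i] += w[1] * v; im[b] += w[2] * v;
      i0[a] += w[3] * v; i0[i] += w[4] * v; i0[b] += w[5] * v;
      ip[a] += w[6] * v; ip[i] += w[7] * v; ip[b] += w[8] * v;
    }
  }
}

static void run_forward(const double *input, int N, int in_ch, int depth,
                        int out_ch, int dil_cycle, int pad_mode, bool linear_act,
                        const double *wts, std::vector<double> &maps,
                        std::vector<double> &pre, std::vector<double> &out,
                        const std::vector<IdxMaps> &idx) {
  const size_t npix = (size_t)N * N;
  const int nmaps = in_ch + depth;
  maps.assign((size_t)nmaps * npix, 0.0);
  pre.assign((size_t)depth * npix, 0.0);
  for (int c = 0; c < in_ch; ++c)
    std::copy(input + c * npix, input + (c + 1) * npix, maps.begin() + c * npix);

  size_t wp = 0;
  for (int i = 0; i < depth; ++i) {
    const int d = (i % dil_cycle) + 1;
    const int nin = in_ch + i;
    double *p = pre.data() + (size_t)i * npix;
    std::fill(p, p + npix, 0.0);
    for (int c = 0; c < nin; ++c) {
      conv3x3_acc(maps.data() + (size_t)c * npix, p, N, d, wts + wp, idx[d]);
      wp += 9;
    }
    const double b = wts[wp++];
    double *m = maps.data() + (size_t)(in_ch + i) * npix;
    if (linear_act)
      for (size_t q = 0; q < npix; ++q) m[q] = p[q] + b;
    else
      for (size_t q = 0; q < npix; ++q) {
        const double z = p[q] + b;
        m[q] = z > 0.0 ? z : 0.0;
      }
    // store pre-activation (with bias) for the backward pass
    for (size_t q = 0; q < npix; ++q) p[q] += b;
  }

  out.assign((size_t)out_ch * npix, 0.0);
  for (int o = 0; o < out_ch; ++o) {
    double *op = out.data() + (size_t)o * npix;
    for (int c = 0; c < nmaps; ++c) {
      const double v = wts[wp++];
      const double *m = maps.data() + (size_t)c * npix;
      for (size_t q = 0; q < npix; ++q) op[q] += v * m[q];
    }
    const double b = wts[wp++];
    for (size_t q = 0; q < npix; ++q) op[q] += b;
  }
}

static size_t n_params(int depth, int in_ch, int out_ch) {
  size_t n = 0;
  for (int i = 1; i <= depth; ++i) n += 9 * (size_t)(in_ch + i - 1) + 1;
  n += (size_t)out_ch * (in_ch + depth + 1);
  return n;
}

// [[Rcpp::export(name = ".msd_forward_cpp")]]
NumericVector msd_forward_cpp(NumericVector input, NumericVector weights,
                              int N, int in_ch, int depth, int out_ch,
                              int dil_cycle, int pad_mode, bool linear_act) {
  if ((size_t)weights.size() != n_params(depth, in_ch, out_ch))
    stop("weight vector has wrong length");
  std::vector<IdxMaps> idx(dil_cycle + 1);
  for (int d = 1; d <= dil_cycle; ++d) idx[d] = make_idx(N, d, pad_mode);
  std::vector<double> maps, pre, out;
  run_forward(REAL(input), N, in_ch, depth, out_ch, dil_cycle, pad_mode,
              linear_act, REAL(weights), maps, pre, out, idx);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(N, N, out_ch);
  return res;
}

// [[Rcpp::export(name = ".msd_loss_grad_cpp")]]
List msd_loss_grad_cpp(NumericVector input, NumericVector target,
                       NumericVector weights, int N, int in_ch, int depth,
                       int out_ch, int dil_cycle, int pad_mode, bool linear_act) {
  const size_t npix = (size_t)N * N;
  const size_t np = n_params(depth, in_ch, out_ch);
  if ((size_t)weights.size() != np) stop("weight vector has wrong length");
  if ((size_t)target.size() != npix * out_ch) stop("target has wrong size");

  std::vector<IdxMaps> idx(dil_cycle + 1);
  for (int d = 1; d <= dil_cycle; ++d) idx[d] = make_idx(N, d, pad_mode);
  std::vector<double> maps, pre, out;
  const double *wts = REAL(weights);
  run_forward(REAL(input), N, in_ch, depth, out_ch, dil_cycle, pad_mode,
              linear_act, wts, maps, pre, out, idx);

  const int nmaps = in_ch + depth;
  const double *tgt = REAL(target);
  const double scale = 2.0 / (double)(npix * out_ch);
  double loss = 0.0;
  std::vector<double> gout((size_t)out_ch * npix);
  for (size_t q = 0; q < (size_t)out_ch * npix; ++q) {
    const double r = out[q] - tgt[q];
    loss += r * r;
    gout[q] = scale * r;
  }
  loss /= (double)(npix * out_ch);

  NumericVector grad(np);
  double *gw = REAL(grad);
  std::vector<double> gmap((size_t)nmaps * npix, 0.0);

  // output layer weight offset
  size_t wp_out = np - (size_t)out_ch * (nmaps + 1);
  for (int o = 0; o < out_ch; ++o) {
    const double *g = gout.data() + (size_t)o * npix;
    size_t wp = wp_out + (size_t)o * (nmaps + 1);
    for (int c = 0; c < nmaps; ++c) {
      const double *m = maps.data() + (size_t)c * npix;
      double *gm = gmap.data() + (size_t)c * npix;
      const double v = wts[wp + c];
      double s = 0.0;
      for (size_t q = 0; q < npix; ++q) {
        s += g[q] * m[q];
        gm[q] += v * g[q];
      }
      gw[wp + c] += s;
    }
    double s = 0.0;
    for (size_t q = 0; q < npix; ++q) s += g[q];
    gw[wp + nmaps] += s;
  }

  // hidden layers, last to first
  // weight offsets per layer
  std::vector<size_t> layer_off(depth);
  size_t off = 0;
  for (int i = 0; i < depth; ++i) {
    layer_off[i] = off;
    off += 9 * (size_t)(in_ch + i) + 1;
  }
  std::vector<double> gpre(npix);
  for (int i = depth - 1; i >= 0; --i) {
    const int d = (i % dil_cycle) + 1;
    const int nin = in_ch + i;
    const double *p = pre.data() + (size_t)i * npix;
    const double *gm = gmap.data() + (size_t)(in_ch + i) * npix;
    if (linear_act)
      std::copy(gm, gm + npix, gpre.begin());
    else
      for (size_t q = 0; q < npix; ++q) gpre[q] = p[q] > 0.0 ? gm[q] : 0.0;
    size_t wp = layer_off[i];
    for (int c = 0; c < nin; ++c) {
      conv3x3_backward(gpre.data(), maps.data() + (size_t)c * npix,
                       gmap.data() + (size_t)c * npix, wts + wp, gw + wp,
                       N, d, idx[d]);
      wp += 9;
    }
    double s = 0.0;
    for (size_t q = 0; q < npix; ++q) s += gpre[q];
    gw[wp] += s;
  }

  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// [[Rcpp::export(name = ".msd_n_params_cpp")]]
double msd_n_params_cpp(int depth, int in_ch, int out_ch) {
  return (double)n_params(depth, in_ch, out_ch);
}
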