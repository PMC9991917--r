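// Compiled forward/backward pass for one decoder branch:
// conv1 (GEMM on a precomputed im2col matrix) -> relu -> dropout ->
// conv2 (im2col + GEMM) -> relu -> dropout -> LSTM (final state), with
// full backpropagation through time. Sequences are flat (n*T) x D
// matrices in block-time layout: rows (t-1)*n + 1 .. t*n hold step t.
//
// The forward cache lives in an external pointer, so nothing is copied
// between the forward and backward calls. Dropout masks are generated
// R-side (seed-deterministic) and passed in; an empty matrix disables a
// mask. Sigmoid/tanh are computed through exp (mathematically exact),
// which is several times faster than libm tanh on this class of CPU.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigmoid1(double v) { return 1.0 / (1.0 + std::exp(-v)); }

static inline void sigmoid_ip(mat& x) {
  x.for_each([](double& v) { v = sigmoid1(v); });
}

static inline void tanh_ip(mat& x) {
  x.for_each([](double& v) { v = 2.0 * sigmoid1(2.0 * v) - 1.0; });
}

static inline void relu_inplace(mat& x) {
  x.for_each([](double& v) { if (v < 0) v = 0; });
}

static mat im2col_flat(const mat& x, int n, int t_in, int k, int stride) {
  const int c = x.n_cols;
  const int t_out = (t_in - k) / stride + 1;
  mat out(n * t_out, k * c);
  for (int o = 0; o < k; ++o) {
    for (int j = 0; j < t_out; ++j) {
      out.submat(j * n, o * c, j * n + n - 1, (o + 1) * c - 1) =
        x.rows((j * stride + o) * n, (j * stride + o) * n + n - 1);
    }
  }
  return out;
}

static mat col2im_flat(const mat& d, int n, int t_in, int c, int k,
                       int stride) {
  const int t_out = d.n_rows / n;
  mat dx(n * t_in, c, fill::zeros);
  for (int o = 0; o < k; ++o) {
    for (int j = 0; j < t_out; ++j) {
      dx.rows((j * stride + o) * n, (j * stride + o) * n + n - 1) +=
        d.submat(j * n, o * c, j * n + n - 1, (o + 1) * c - 1);
    }
  }
  return dx;
}

static inline void apply_mask(mat& x, const mat& m) {
  if (m.n_elem == x.n_elem) x %= m;
}

struct BranchCache {
  mat c2;              // conv2 im2col input
  umat z1pos, z2pos;   // relu gates
  cube I, F, G, O, TC, CP, XT, HM;
};

// [[Rcpp::export]]
Rcpp::List branch_forward_cpp(const arma::mat& c1, const arma::mat& W1,
                              const arma::vec& b1, const arma::mat& W2,
                              const arma::vec& b2, const arma::mat& Wl,
                              const arma::vec& bl, const arma::mat& m1,
                              const arma::mat& m2, const arma::mat& mask_in,
                              const arma::mat& mask_rec, int n, int t1,
                              int k2, int s2, bool cache) {
  BranchCache* C = cache ? new BranchCache() : nullptr;
  // conv1
  mat z1 = c1 * W1;
  z1.each_row() += b1.t();
  if (cache) C->z1pos = (z1 > 0);
  relu_inplace(z1);                       // z1 now holds a1
  apply_mask(z1, m1);
  // conv2
  mat c2 = im2col_flat(z1, n, t1, k2, s2);
  mat z2 = c2 * W2;
  z2.each_row() += b2.t();
  if (cache) {
    C->c2 = std::move(c2);
    C->z2pos = (z2 > 0);
  }
  relu_inplace(z2);
  apply_mask(z2, m2);                     // z2 now holds a2 (LSTM input)
  // LSTM
  const int D = z2.n_cols;
  const int T = z2.n_rows / n;
  const int H = Wl.n_cols / 4;
  const bool has_in = mask_in.n_elem > 0;
  const bool has_rec = mask_rec.n_elem > 0;
  mat Wx = Wl.rows(0, D - 1);
  mat Wh = Wl.rows(D, D + H - 1);
  rowvec bt = bl.t();
  mat h(n, H, fill::zeros), c(n, H, fill::zeros);
  if (cache) {
    C->I.set_size(n, H, T); C->F.set_size(n, H, T);
    C->G.set_size(n, H, T); C->O.set_size(n, H, T);
    C->TC.set_size(n, H, T); C->CP.set_size(n, H, T);
    C->XT.set_size(n, D, T); C->HM.set_size(n, H, T);
  }
  mat z(n, 4 * H), xt(n, D), hm(n, H);
  for (int t = 0; t < T; ++t) {
    xt = z2.rows(t * n, t * n + n - 1);
    if (has_in) xt %= mask_in;
    hm = h;
    if (has_rec) hm %= mask_rec;
    z = xt * Wx + hm * Wh;
    z.each_row() += bt;
    mat i_g = z.cols(0, H - 1);          sigmoid_ip(i_g);
    mat f_g = z.cols(H, 2 * H - 1);      sigmoid_ip(f_g);
    mat g_g = z.cols(2 * H, 3 * H - 1);  tanh_ip(g_g);
    mat o_g = z.cols(3 * H, 4 * H - 1);  sigmoid_ip(o_g);
    if (cache) {
      C->CP.slice(t) = c;
      C->XT.slice(t) = xt;
      C->HM.slice(t) = hm;
    }
    c = f_g % c + i_g % g_g;
    mat tc = c;
    tanh_ip(tc);
    h = o_g % tc;
    if (cache) {
      C->I.slice(t) = std::move(i_g); C->F.slice(t) = std::move(f_g);
      C->G.slice(t) = std::move(g_g); C->O.slice(t) = std::move(o_g);
      C->TC.slice(t) = std::move(tc);
    }
  }
  if (!cache) return Rcpp::List::create(Rcpp::Named("h") = h);
  Rcpp::XPtr<BranchCache> ptr(C, true);
  return Rcpp::List::create(Rcpp::Named("h") = h, Rcpp::Named("cache") = ptr);
}

// [[Rcpp::export]]
Rcpp::List branch_backward_cpp(SEXP cache_ptr, const arma::mat& c1,
                               const arma::mat& W1, const arma::mat& W2,
                               const arma::mat& Wl, const arma::mat& dh_out,
                               const arma::mat& m1, const arma::mat& m2,
                               const arma::mat& mask_in,
                               const arma::mat& mask_rec, int n, int t1,
                               int k2, int s2, double l2, bool want_dx,
                               int k1, int s1, int t_in, int c_in) {
  Rcpp::XPtr<BranchCache> C(cache_ptr);
  const int T = C->I.n_slices;
  const int H = dh_out.n_cols;
  const int D = C->XT.n_cols;
  const bool has_in = mask_in.n_elem > 0;
  const bool has_rec = mask_rec.n_elem > 0;
  mat Wxt = Wl.rows(0, D - 1).t();
  mat Wht = Wl.rows(D, D + H - 1).t();
  mat dWl(Wl.n_rows, Wl.n_cols, fill::zeros);
  vec dbl(4 * H, fill::zeros);
  mat da2(n * T, D);
  mat dh = dh_out, dc(n, H, fill::zeros);
  mat dz(n, 4 * H);
  for (int t = T - 1; t >= 0; --t) {
    const mat& i_g = C->I.slice(t);
    const mat& f_g = C->F.slice(t);
    const mat& g_g = C->G.slice(t);
    const mat& o_g = C->O.slice(t);
    const mat& tc = C->TC.slice(t);
    mat do_g = dh % tc;
    dc += dh % o_g % (1.0 - tc % tc);
    dz.cols(0, H - 1) = dc % g_g % i_g % (1.0 - i_g);
    dz.cols(H, 2 * H - 1) = dc % C->CP.slice(t) % f_g % (1.0 - f_g);
    dz.cols(2 * H, 3 * H - 1) = dc % i_g % (1.0 - g_g % g_g);
    dz.cols(3 * H, 4 * H - 1) = do_g % o_g % (1.0 - o_g);
    dWl.rows(0, D - 1) += C->XT.slice(t).t() * dz;
    dWl.rows(D, D + H - 1) += C->HM.slice(t).t() * dz;
    dbl += sum(dz, 0).t();
    mat dxt = dz * Wxt;
    if (has_in) dxt %= mask_in;
    da2.rows(t * n, t * n + n - 1) = dxt;
    dh = dz * Wht;
    if (has_rec) dh %= mask_rec;
    dc %= f_g;
  }
  dWl += l2 * Wl;
  // back through conv2
  apply_mask(da2, m2);
  da2 %= conv_to<mat>::from(C->z2pos);
  mat gW2 = C->c2.t() * da2 + l2 * W2;
  vec gb2 = sum(da2, 0).t();
  mat dc2 = da2 * W2.t();
  mat da1 = col2im_flat(dc2, n, t1, W1.n_cols, k2, s2);
  apply_mask(da1, m1);
  da1 %= conv_to<mat>::from(C->z1pos);
  mat gW1 = c1.t() * da1 + l2 * W1;
  vec gb1 = sum(da1, 0).t();
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("W1") = gW1, Rcpp::Named("b1") = gb1,
    Rcpp::Named("W2") = gW2, Rcpp::Named("b2") = gb2,
    Rcpp::Named("Wl") = dWl, Rcpp::Named("bl") = dbl);
  if (want_dx) {
    mat dxcol = da1 * W1.t();
    out["dx"] = col2im_flat(dxcol, n, t_in, c_in, k1, s1);
  }
  return out;
}
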