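// Numerical core: Fast Orthogonal Search / OLS fitting of bivariate VAR
// designs, Geweke causality measures, IAAFT surrogate generation, and the
// surrogate significance loop.  Kept in compiled code because a single
// cohort-level analysis performs ~10^5-10^6 model fits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

typedef std::complex<double> cplx;

// Mixed-radix Cooley-Tukey FFT with a reusable plan (factorization plus a
// global twiddle table).  The IAAFT loop performs two transforms per
// iteration and millions of iterations per cohort analysis; a plan shared
// across all surrogates of one test keeps that affordable at the awkward
// series lengths fMRI runs produce (295 = 5 x 59, 245 = 5 x 7 x 7).
// A prime length degrades to the O(n^2) single-stage DFT, which is still
// exact.
struct FftPlan {
  int n;
  std::vector<int> factors;
  std::vector<cplx> w, wc;    // w[t] = exp(-2*pi*i*t/n) and its conjugate
  std::vector<cplx> slab;     // scratch: one length-n buffer per level
  std::vector<cplx> in, out;  // transform buffers
  std::vector<cplx> B;        // butterfly workspace (max factor size)
  bool use_gemm = false;      // batch leaf prime DFTs through BLAS
  arma::cx_mat Df, Di;        // dense DFT matrix of the last (large) factor

  explicit FftPlan(int n_) : n(n_) {
    int r = n_;
    for (int p = 2; p * p <= r;) {
      if (r % p == 0) { factors.push_back(p); r /= p; }
      else ++p;
    }
    if (r > 1) factors.push_back(r);
    if (factors.empty()) factors.push_back(1);
    w.resize(n);
    wc.resize(n);
    for (int t = 0; t < n; ++t) {
      const double a = -2.0 * M_PI * t / n;
      w[t] = cplx(std::cos(a), std::sin(a));
      wc[t] = std::conj(w[t]);
    }
    slab.resize(static_cast<size_t>(n) * factors.size() + 1);
    in.resize(n);
    out.resize(n);
    B.resize(*std::max_element(factors.begin(), factors.end()));
    // a large prime as the innermost factor (e.g. 295 = 5 x 59) makes the
    // generic butterfly the bottleneck; batching those leaf DFTs as one
    // matrix product is much faster
    const int last = factors.back();
    if (factors.size() >= 2 && last >= 16) {
      use_gemm = true;
      Df.set_size(last, last);
      for (int j = 0; j < last; ++j)
        for (int q = 0; q < last; ++q) {
          const double a = -2.0 * M_PI * (static_cast<long>(q) * j % last) /
                           last;
          Df(j, q) = cplx(std::cos(a), std::sin(a));
        }
      Di = arma::conj(Df);
    }
  }

  // sign = +1 forward, -1 inverse (conjugate twiddle table)
  void rec(const cplx* x, int stride, cplx* y, int len, size_t fi, cplx* sl,
           const cplx* tw) {
    if (len == 1) { y[0] = x[0]; return; }
    const int p = factors[fi];
    const int m = len / p;
    if (use_gemm && fi + 2 == factors.size() && factors[fi + 1] == m) {
      // children are pure prime-m DFTs: do all p of them in one product
      arma::cx_mat In(m, p);
      for (int q = 0; q < p; ++q)
        for (int r = 0; r < m; ++r)
          In(r, q) = x[(q + static_cast<long>(r) * p) * stride];
      const arma::cx_mat Out = (tw == w.data() ? Df : Di) * In;
      for (int q = 0; q < p; ++q)
        std::copy(Out.colptr(q), Out.colptr(q) + m, sl + q * m);
    } else {
      for (int q = 0; q < p; ++q)
        rec(x + q * stride, stride * p, sl + q * m, m, fi + 1, sl + n, tw);
    }
    const long mult = n / len;        // maps w_len exponents into w_n table
    const long pm = static_cast<long>(n) / p;
    cplx* Bp = B.data();
    for (int k0 = 0; k0 < m; ++k0) {
      const long estep = static_cast<long>(k0) * mult;  // < n
      long e = 0;
      for (int q = 0; q < p; ++q) {
        Bp[q] = sl[q * m + k0] * tw[e];
        e += estep;
        if (e >= n) e -= n;
      }
      for (int j = 0; j < p; ++j) {
        const long jstep = static_cast<long>(j) * pm;   // < n
        long ej = 0;
        cplx acc(0.0, 0.0);
        for (int q = 0; q < p; ++q) {
          acc += Bp[q] * tw[ej];
          ej += jstep;
          if (ej >= n) ej -= n;
        }
        y[k0 + j * m] = acc;
      }
    }
  }

  void forward(const cplx* x, cplx* y) {
    rec(x, 1, y, n, 0, slab.data(), w.data());
  }
  void inverse(const cplx* x, cplx* y) {
    rec(x, 1, y, n, 0, slab.data(), wc.data());
    const double s = 1.0 / n;
    for (int t = 0; t < n; ++t) y[t] *= s;
  }
};

struct FosFit {
  vec coef;                 // full-length, zero for unadmitted candidates
  double rss;
  std::vector<int> order;   // admission order (0-based candidate indices)
};

// Greedy orthogonal search on the Gram matrix.  Candidates are the columns
// behind G (M x M) and g = X'y; yy = y'y; the first n_force candidates are
// admitted unconditionally (used to keep the intercept in every model).
// threshold is the minimal relative reduction in residual sum of squares;
// threshold = 0 admits every linearly independent candidate, which equals
// ordinary least squares.
FosFit fos_gram(const mat& G, const vec& g, double yy, double threshold,
                int n_force) {
  const int M = G.n_cols;
  FosFit fit;
  fit.coef = arma::zeros<vec>(M);

  mat Rm(M, M, arma::fill::zeros);   // row k: projections onto k-th basis vec
  std::vector<double> tvec;          // q_k' y
  std::vector<bool> active(M, true);
  vec a(M), b(M);                    // residual norm^2 and residual x'y
  for (int j = 0; j < M; ++j) { a(j) = G(j, j); b(j) = g(j); }

  double rss = yy;
  const double tolA = 1e-12 * std::max(1.0, G.diag().max());

  int step = 0;
  while (step < M) {
    int best = -1;
    if (step < n_force) {
      if (active[step] && a(step) > tolA) best = step;
    } else {
      double bestGain = -1.0;
      for (int j = 0; j < M; ++j) {
        if (!active[j] || a(j) <= tolA) continue;
        const double gain = b(j) * b(j) / a(j);
        if (gain > bestGain) { bestGain = gain; best = j; }
      }
      if (best >= 0 && rss > 0.0 && bestGain / rss < threshold) best = -1;
    }
    if (best < 0) break;

    const double sq = std::sqrt(a(best));
    const double tk = b(best) / sq;
    for (int j = 0; j < M; ++j) {
      if (j == best) { Rm(step, j) = sq; continue; }
      double v = G(best, j);
      for (int k = 0; k < step; ++k) v -= Rm(k, best) * Rm(k, j);
      Rm(step, j) = v / sq;
    }
    for (int j = 0; j < M; ++j) {
      if (!active[j] || j == best) continue;
      a(j) -= Rm(step, j) * Rm(step, j);
      b(j) -= Rm(step, j) * tk;
    }
    active[best] = false;
    fit.order.push_back(best);
    tvec.push_back(tk);
    rss -= tk * tk;
    if (rss < 0.0) rss = 0.0;
    ++step;
  }

  // back-substitute the triangular orthogonalization for raw coefficients
  const int m = static_cast<int>(fit.order.size());
  std::vector<double> beta(m, 0.0);
  for (int l = m - 1; l >= 0; --l) {
    double v = tvec[l];
    for (int k = l + 1; k < m; ++k) v -= Rm(l, fit.order[k]) * beta[k];
    beta[l] = v / Rm(l, fit.order[l]);
  }
  for (int l = 0; l < m; ++l) fit.coef(fit.order[l]) = beta[l];
  fit.rss = rss;
  return fit;
}

FosFit fos_design(const mat& X, const vec& y, double threshold, int n_force) {
  const mat G = X.t() * X;
  const vec g = X.t() * y;
  return fos_gram(G, g, arma::dot(y, y), threshold, n_force);
}

// lag matrix: column l (1-based lag) holds x[t - l] for t = p .. T-1
mat lag_matrix(const vec& x, int p) {
  const int T = x.n_elem;
  mat L(T - p, p);
  for (int l = 1; l <= p; ++l)
    L.col(l - 1) = x.subvec(p - l, T - l - 1);
  return L;
}

// Fisher-Yates permutation of 0..n-1 driven by R's RNG stream
std::vector<int> r_permutation(int n) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// One IAAFT surrogate of x.  Alternates spectrum adjustment (impose the
// original Fourier amplitudes, keep current phases) and amplitude adjustment
// (rank-remap onto the original sorted values); stops when the rank ordering
// is unchanged between iterations or max_iter is reached.  The final step is
// always the amplitude adjustment, so sorted(surrogate) == sorted(x) exactly.
vec iaaft_one(const vec& x, int max_iter, FftPlan& plan, int& iters,
              bool& converged) {
  const int n = x.n_elem;
  const vec sorted_x = arma::sort(x);

  cplx* fin = plan.in.data();
  cplx* fout = plan.out.data();
  vec amp(n);
  for (int i = 0; i < n; ++i) fin[i] = cplx(x(i), 0.0);
  plan.forward(fin, fout);
  for (int k = 0; k < n; ++k) amp(k) = std::abs(fout[k]);

  std::vector<int> perm = r_permutation(n);
  vec s(n);
  for (int i = 0; i < n; ++i) s(i) = x(perm[i]);

  uvec prev_ord(n, arma::fill::zeros);
  bool have_prev = false;
  converged = false;
  iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    ++iters;
    for (int i = 0; i < n; ++i) fin[i] = cplx(s(i), 0.0);
    plan.forward(fin, fout);
    for (int k = 0; k < n; ++k) {
      const double m = std::abs(fout[k]);
      fout[k] = (m > 0.0) ? fout[k] * (amp(k) / m) : cplx(amp(k), 0.0);
    }
    plan.inverse(fout, fin);
    for (int i = 0; i < n; ++i) s(i) = fin[i].real();
    const uvec ord = arma::stable_sort_index(s);
    for (int i = 0; i < n; ++i) s(ord(i)) = sorted_x(i);
    if (have_prev && arma::all(ord == prev_ord)) { converged = true; break; }
    prev_ord = ord;
    have_prev = true;
  }
  return s;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List fos_core(const arma::mat& X, const arma::vec& y, double threshold,
                    int n_force) {
  FosFit fit = fos_design(X, y, threshold, n_force);
  return Rcpp::List::create(
      Rcpp::Named("coef") = fit.coef,
      Rcpp::Named("rss") = fit.rss,
      Rcpp::Named("admitted") = Rcpp::wrap(fit.order));
}

// [[Rcpp::export]]
Rcpp::List iaaft_core(const arma::vec& x, int max_iter) {
  int iters = 0;
  bool converged = false;
  FftPlan plan(x.n_elem);
  vec s = iaaft_one(x, max_iter, plan, iters, converged);
  return Rcpp::List::create(
      Rcpp::Named("series") = s,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged);
}

// Bivariate Geweke decomposition.  Full models regress each series on lags
// 1..p of both series plus an intercept; restricted models on own lags plus
// intercept.  Residual variances use divisor n_eff = T - p.  F values are
// floored at zero (thresholded FOS can produce slightly non-nested fits).
// [[Rcpp::export]]
Rcpp::List geweke_core(const arma::vec& x, const arma::vec& y, int p,
                       double threshold) {
  const int T = x.n_elem;
  const int n = T - p;
  const mat LX = lag_matrix(x, p);
  const mat LY = lag_matrix(y, p);
  const vec xt = x.subvec(p, T - 1);
  const vec yt = y.subvec(p, T - 1);
  const vec ones(n, arma::fill::ones);

  const mat Dy_r = arma::join_rows(ones, LY);
  const mat Dx_r = arma::join_rows(ones, LX);
  const mat Dy_f = arma::join_rows(Dy_r, LX);   // [1, y-lags, x-lags]
  const mat Dx_f = arma::join_rows(Dx_r, LY);   // [1, x-lags, y-lags]

  FosFit fy_r = fos_design(Dy_r, yt, threshold, 1);
  FosFit fx_r = fos_design(Dx_r, xt, threshold, 1);
  FosFit fy_f = fos_design(Dy_f, yt, threshold, 1);
  FosFit fx_f = fos_design(Dx_f, xt, threshold, 1);

  const double vy_r = fy_r.rss / n, vx_r = fx_r.rss / n;
  const double vy_f = fy_f.rss / n, vx_f = fx_f.rss / n;

  const vec ey = yt - Dy_f * fy_f.coef;
  const vec ex = xt - Dx_f * fx_f.coef;
  const double cxy = arma::dot(ex, ey) / n;
  const double det = vx_f * vy_f - cxy * cxy;

  const double f_xy = std::max(0.0, std::log(vy_r / vy_f));
  const double f_yx = std::max(0.0, std::log(vx_r / vx_f));
  const double f_inst =
      (det > 0.0) ? std::max(0.0, std::log(vx_f * vy_f / det)) : R_PosInf;

  return Rcpp::List::create(
      Rcpp::Named("f_x_to_y") = f_xy,
      Rcpp::Named("f_y_to_x") = f_yx,
      Rcpp::Named("f_instantaneous") = f_inst,
      Rcpp::Named("coef_y_full") = fy_f.coef,
      Rcpp::Named("coef_x_full") = fx_f.coef,
      Rcpp::Named("coef_y_restricted") = fy_r.coef,
      Rcpp::Named("coef_x_restricted") = fx_r.coef,
      Rcpp::Named("var_y_full") = vy_f,
      Rcpp::Named("var_x_full") = vx_f,
      Rcpp::Named("var_y_restricted") = vy_r,
      Rcpp::Named("var_x_restricted") = vx_r,
      Rcpp::Named("cov_xy_full") = cxy,
      Rcpp::Named("n_effective") = n);
}

// Surrogate test of the directed influence source -> target.  The observed
// F compares the restricted model of the target (own lags) with the full
// model adding source lags; each replicate replaces the source with an
// independent IAAFT surrogate (and, optionally, the target too) and refits.
// Returns the observed F and the count of surrogate F >= observed F.
// When early_stop_at >= 0 the replicate loop terminates as soon as the
// exceedance count passes that bound: the significance decision (count <=
// early_stop_at after all n_sur replicates) is already fixed, so the
// decision is identical to the full run while null pairs cost a fraction
// of the replicates.  The reported count/n_done pair then yields a
// conservative p-value estimate.
// [[Rcpp::export]]
Rcpp::List test_direction_core(const arma::vec& source,
                               const arma::vec& target, int p, int n_sur,
                               int max_iter, double threshold,
                               bool surrogate_target,
                               int early_stop_at = -1) {
  const int T = target.n_elem;
  const int n = T - p;
  const vec ones(n, arma::fill::ones);

  const mat LT = lag_matrix(target, p);
  const vec tt = target.subvec(p, T - 1);
  const mat D_r = arma::join_rows(ones, LT);
  const double v_r = fos_design(D_r, tt, threshold, 1).rss / n;

  const mat LS = lag_matrix(source, p);
  const mat D_f = arma::join_rows(D_r, LS);
  const double v_f = fos_design(D_f, tt, threshold, 1).rss / n;
  const double f_obs = std::max(0.0, std::log(v_r / v_f));

  int count = 0, iaaft_iters = 0, n_done = 0;
  FftPlan plan(T);
  for (int r = 0; r < n_sur; ++r) {
    if (early_stop_at >= 0 && count > early_stop_at) break;
    ++n_done;
    int it = 0; bool conv = false;
    const vec ss = iaaft_one(source, max_iter, plan, it, conv);
    iaaft_iters += it;
    vec tt_s = tt;
    mat LT_s = LT;
    if (surrogate_target) {
      const vec ts = iaaft_one(target, max_iter, plan, it, conv);
      tt_s = ts.subvec(p, T - 1);
      LT_s = lag_matrix(ts, p);
    }
    const mat D_rs = arma::join_rows(ones, LT_s);
    const double v_rs =
        surrogate_target ? fos_design(D_rs, tt_s, threshold, 1).rss / n : v_r;
    const mat D_fs = arma::join_rows(D_rs, lag_matrix(ss, p));
    const double v_fs = fos_design(D_fs, tt_s, threshold, 1).rss / n;
    const double f_s = std::max(0.0, std::log(v_rs / v_fs));
    if (f_s >= f_obs) ++count;
  }

  return Rcpp::List::create(
      Rcpp::Named("f_observed") = f_obs,
      Rcpp::Named("count_ge") = count,
      Rcpp::Named("n_surrogates") = n_sur,
      Rcpp::Named("n_done") = n_done,
      Rcpp::Named("mean_iaaft_iterations") =
          n_done > 0 ? static_cast<double>(iaaft_iters) / n_done : NA_REAL);
}
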