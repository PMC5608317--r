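// Compiled kernels for the per-patch HLDS identification, the stabilization
// quadratic program, and batch Grassmann-manifold operations. Conventions
// shared with the R reference implementations (and tested against them):
//  * mode-3 unfolding columns are pixels in row-major scan order;
//  * singular-vector signs fixed so the largest-magnitude entry is positive;
//  * QR orthonormalization with the R-factor diagonal forced positive;
//  * vec(A) is column-major, so the QP quadratic form is (Xp Xp^T) kron I.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double CUT_LOCUS_EPS = 1e-10;

// ---------------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------------

// flip column signs so the largest-magnitude entry of each column is positive
static void sign_fix_cols(mat& U) {
  for (uword j = 0; j < U.n_cols; ++j) {
    const uword i = index_max(abs(U.col(j)));
    if (U(i, j) < 0) U.col(j) *= -1.0;
  }
}

// thin QR with positive R diagonal; returns Q, writes rank-revealing diag
static mat qr_pos(const mat& M, vec* rdiag = nullptr) {
  mat Q, R;
  qr_econ(Q, R, M);
  for (uword j = 0; j < R.n_cols; ++j) {
    if (R(j, j) < 0) { Q.col(j) *= -1.0; R.row(j) *= -1.0; }
  }
  if (rdiag) *rdiag = R.diag();
  return Q;
}

// mode-3 unfolding with columns in row-major pixel order: column (r*N + c)
// holds the 3 channel values of pixel (r, c)
static mat unfold3_rowmajor(const cube& Y) {
  const uword N1 = Y.n_rows, N2 = Y.n_cols, K = Y.n_slices;
  mat out(K, N1 * N2);
  for (uword k = 0; k < K; ++k) {
    mat st = Y.slice(k).t();              // col-major of t() == row-major of slice
    out.row(k) = vectorise(st).t();
  }
  return out;
}

// rotate one matrix 90 degrees clockwise: out(i, j) = in(N-1-j, i)
static mat rot90cw(const mat& M) {
  const uword n = M.n_rows, m = M.n_cols;
  mat out(m, n);
  for (uword i = 0; i < m; ++i)
    for (uword j = 0; j < n; ++j)
      out(i, j) = M(n - 1 - j, i);
  return out;
}

static cube rot90cw_cube(const cube& P) {
  cube out(P.n_cols, P.n_rows, P.n_slices);
  for (uword k = 0; k < P.n_slices; ++k) out.slice(k) = rot90cw(P.slice(k));
  return out;
}

// left singular vectors with deterministic signs; identity for a zero matrix
static mat left_singvecs(const mat& M) {
  if (norm(M, "fro") == 0.0) return eye(M.n_rows, M.n_rows);
  mat U, V;
  vec s;
  if (!svd_econ(U, s, V, M)) Rcpp::stop("SVD failed");
  if (U.n_cols < M.n_rows) {         // pad to a full orthogonal basis
    mat Uf, Vf; vec sf;
    svd(Uf, sf, Vf, M);
    U = Uf;
  }
  sign_fix_cols(U);
  return U;
}

// ---------------------------------------------------------------------------
// HOSVD
// ---------------------------------------------------------------------------

static mat unfold1(const cube& Y) {
  return mat(const_cast<double*>(Y.memptr()), Y.n_rows, Y.n_cols * Y.n_slices);
}

static mat unfold2(const cube& Y) {
  mat out(Y.n_cols, Y.n_rows * Y.n_slices);
  for (uword k = 0; k < Y.n_slices; ++k)
    out.cols(k * Y.n_rows, (k + 1) * Y.n_rows - 1) = Y.slice(k).t();
  return out;
}

// mode products against our unfolding conventions
static cube mode1_prod(const cube& Y, const mat& M) {
  cube out(M.n_rows, Y.n_cols, Y.n_slices);
  for (uword k = 0; k < Y.n_slices; ++k) out.slice(k) = M * Y.slice(k);
  return out;
}

static cube mode2_prod(const cube& Y, const mat& M) {
  cube out(Y.n_rows, M.n_rows, Y.n_slices);
  for (uword k = 0; k < Y.n_slices; ++k) out.slice(k) = Y.slice(k) * M.t();
  return out;
}

static cube mode3_prod(const cube& Y, const mat& M) {
  cube out(Y.n_rows, Y.n_cols, M.n_rows);
  out.zeros();
  for (uword k2 = 0; k2 < M.n_rows; ++k2)
    for (uword k = 0; k < Y.n_slices; ++k)
      out.slice(k2) += M(k2, k) * Y.slice(k);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_hosvd(const arma::cube& Y) {
  if (!Y.is_finite()) Rcpp::stop("non-finite values in tensor");
  mat U1 = left_singvecs(unfold1(Y));
  mat U2 = left_singvecs(unfold2(Y));
  mat U3 = left_singvecs(unfold3_rowmajor(Y));
  cube S = mode3_prod(mode2_prod(mode1_prod(Y, U1.t()), U2.t()), U3.t());
  return Rcpp::List::create(Rcpp::Named("core") = S,
                            Rcpp::Named("U1") = U1,
                            Rcpp::Named("U2") = U2,
                            Rcpp::Named("U3") = U3);
}

// [[Rcpp::export]]
arma::cube cpp_tucker_reconstruct(const arma::cube& S, const arma::mat& U1,
                                  const arma::mat& U2, const arma::mat& U3) {
  return mode3_prod(mode2_prod(mode1_prod(S, U1), U2), U3);
}

// ---------------------------------------------------------------------------
// stabilization QP (constraint generation, dual coordinate ascent)
// ---------------------------------------------------------------------------

// minimize a'Pa - 2 q'a  s.t.  G a <= 1, with P SPD (here M kron I3).
// Dual active-set method: with active set W, the KKT system gives
// lambda_W from H_WW lambda_W = 2 (G_W' Pinv q - 1); drop constraints with
// negative multipliers, add the most violated inactive one, repeat. Exact
// for this strictly convex QP; a long, properly-stopped dual coordinate
// ascent is kept as a fallback against (rare) degenerate cycling.
static vec solve_qp_dual(const mat& Pinv, const vec& q, const mat& Gm,
                         std::vector<uword>& active) {
  const uword m = Gm.n_cols;
  mat PiG = Pinv * Gm;                     // 9 x m
  mat H = Gm.t() * PiG;                    // m x m
  vec alpha_u = Pinv * q;
  vec Gau = Gm.t() * alpha_u;
  // successive constraint-generation directions are nearly parallel, so the
  // KKT systems are near-singular; a tiny Tikhonov term keeps them solvable
  const double hreg = 1e-12 * (trace(H) / m + 1.0);
  vec lambda(m, fill::zeros);
  for (int it = 0; it < 300; ++it) {
    lambda.zeros();
    if (!active.empty()) {
      uvec W = conv_to<uvec>::from(active);
      mat Hw = H.submat(W, W);
      Hw.diag() += hreg;
      vec rhs = 2.0 * (Gau.elem(W) - 1.0);
      vec lw = solve(Hw, rhs, solve_opts::likely_sympd);
      const uword imin = lw.index_min();
      if (lw(imin) < -1e-10) {             // drop most negative multiplier
        active.erase(active.begin() + imin);
        continue;
      }
      lambda.elem(W) = clamp(lw, 0.0, datum::inf);
    }
    vec Ga = Gau - 0.5 * (H * lambda);
    const uword iv = (Ga - 1.0).index_max();
    if (Ga(iv) - 1.0 <= 1e-10) return alpha_u - 0.5 * (PiG * lambda);
    if (std::find(active.begin(), active.end(), iv) != active.end()) break;
    active.push_back(iv);
  }
  // fallback: bounded projected dual coordinate ascent
  lambda.zeros();
  for (int sweep = 0; sweep < 3000; ++sweep) {
    double maxstep = 0.0;
    for (uword i = 0; i < m; ++i) {
      const double gia = Gau(i) - 0.5 * dot(H.row(i), lambda);
      const double nl = std::max(0.0, lambda(i) + 2.0 * (gia - 1.0) / H(i, i));
      maxstep = std::max(maxstep, std::fabs(nl - lambda(i)));
      lambda(i) = nl;
    }
    if (maxstep < 1e-12) break;
  }
  return alpha_u - 0.5 * (PiG * lambda);
}

struct StabResult {
  mat A;
  bool converged;
  int n_constraints;
  mat constraints;   // one g per column
};

static StabResult stabilize_core(const mat& A0, const mat& Xp, const mat& Xn,
                                 double tol, int max_iter, double ridge) {
  StabResult res;
  res.A = A0;
  res.converged = false;
  mat M = Xp * Xp.t();
  double rs = trace(M) / 3.0;
  M.diag() += ridge * (rs > 0 ? rs : 1.0);
  mat P = kron(M, eye(3, 3));
  mat Pinv = kron(inv_sympd(M), eye(3, 3));   // (M kron I)^-1 = M^-1 kron I
  vec q = vectorise(Xn * Xp.t());
  std::vector<vec> gs;
  std::vector<uword> active;                  // warm-started across QPs
  mat A = A0;
  for (int it = 0; it < max_iter; ++it) {
    mat U, V;
    vec s;
    svd(U, s, V, A);
    if (s(0) <= 1.0 + tol) { res.converged = true; break; }
    gs.push_back(vectorise(U.col(0) * V.col(0).t()));
    mat Gm(9, gs.size());
    for (uword i = 0; i < gs.size(); ++i) Gm.col(i) = gs[i];
    active.push_back(gs.size() - 1);       // warm start: new cap is binding
    vec alpha = solve_qp_dual(Pinv, q, Gm, active);
    A = reshape(alpha, 3, 3);
  }
  res.A = A;
  res.n_constraints = (int) gs.size();
  res.constraints.set_size(9, gs.size());
  for (uword i = 0; i < gs.size(); ++i) res.constraints.col(i) = gs[i];
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_stabilize(const arma::mat& A, const arma::mat& Xp,
                         const arma::mat& Xn, double tol, int max_iter,
                         double ridge) {
  StabResult r = stabilize_core(A, Xp, Xn, tol, max_iter, ridge);
  mat M = Xp * Xp.t();
  double rs = trace(M) / 3.0;
  M.diag() += ridge * (rs > 0 ? rs : 1.0);
  return Rcpp::List::create(
      Rcpp::Named("A") = r.A,
      Rcpp::Named("converged") = r.converged,
      Rcpp::Named("n_constraints") = r.n_constraints,
      Rcpp::Named("constraints") = r.constraints,
      Rcpp::Named("P") = kron(M, eye(3, 3)),
      Rcpp::Named("q") = vectorise(Xn * Xp.t()),
      Rcpp::Named("r") = trace(Xn.t() * Xn),
      Rcpp::Named("sigma1") = norm(r.A, 2));
}

// ---------------------------------------------------------------------------
// per-patch HLDS fit
// ---------------------------------------------------------------------------

struct FitResult {
  mat A, C;
  vec mean;
  double sigma1;
  bool stabilized;
  bool stab_converged;
  bool degenerate;
};

static FitResult fit_patch_core(const cube& patch, double ridge, double stab_tol,
                                int stab_max_iter, double degen_eps) {
  FitResult out;
  const uword N = patch.n_rows;
  const uword n = N * patch.n_cols;
  out.mean.set_size(3);
  cube Yc = patch;
  for (uword k = 0; k < 3; ++k) {
    out.mean(k) = accu(patch.slice(k)) / (double) n;
    Yc.slice(k) -= out.mean(k);
  }
  out.degenerate = norm(vectorise(Yc), 2) < degen_eps * (double) N;
  out.stabilized = false;
  out.stab_converged = true;
  if (out.degenerate) {
    out.A = zeros(3, 3);
    out.C = eye(3, 3);
    out.sigma1 = 0.0;
    return out;
  }
  mat Y3 = unfold3_rowmajor(Yc);          // 3 x n
  mat C = left_singvecs(Y3);              // 3 x 3 orthogonal, sign-fixed
  mat X3 = C.t() * Y3;                    // states in scan order
  mat Xp = X3.cols(0, n - 2);
  mat Xn = X3.cols(1, n - 1);
  // affine one-step regression: centered states obey x(i+1) = A x(i) + c
  mat G(4, n - 1);
  G.rows(0, 2) = Xp;
  G.row(3).ones();
  mat Mg = G * G.t();
  // scale-relative ridge: guards rank deficiency without biasing well-posed
  // fits whatever the state amplitude (state block only; the intercept row of
  // ones would dominate the trace)
  const double rscale = (Mg(0, 0) + Mg(1, 1) + Mg(2, 2)) / 3.0;
  Mg.diag() += ridge * (rscale > 0 ? rscale : 1.0);
  mat B = solve(Mg, G * Xn.t(), solve_opts::likely_sympd).t();  // 3 x 4
  mat A = B.cols(0, 2);
  vec b = B.col(3);
  double s1 = norm(A, 2);
  if (s1 > 1.0 + stab_tol) {
    mat Xn2 = Xn - repmat(b, 1, n - 1);
    StabResult sr = stabilize_core(A, Xp, Xn2, stab_tol, stab_max_iter, ridge);
    if (sr.converged) {
      A = sr.A;
    } else {
      A = A / s1;                          // certified-stable fallback
    }
    out.stabilized = true;
    out.stab_converged = sr.converged;
    s1 = norm(A, 2);
  }
  out.A = A;
  out.C = C;
  out.sigma1 = s1;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_patch(const arma::cube& patch, double ridge, double stab_tol,
                         int stab_max_iter, double degen_eps) {
  FitResult r = fit_patch_core(patch, ridge, stab_tol, stab_max_iter, degen_eps);
  return Rcpp::List::create(Rcpp::Named("A") = r.A,
                            Rcpp::Named("C") = r.C,
                            Rcpp::Named("mean") = r.mean,
                            Rcpp::Named("sigma1") = r.sigma1,
                            Rcpp::Named("stabilized") = r.stabilized,
                            Rcpp::Named("stab_converged") = r.stab_converged,
                            Rcpp::Named("degenerate") = r.degenerate);
}

// observability matrix [C; CA; ...; CA^(m-1)], orthonormalized
static mat observability_basis(const mat& A, const mat& C, int m, bool& ok) {
  mat O(3 * m, 3);
  mat CA = C;
  for (int i = 0; i < m; ++i) {
    O.rows(3 * i, 3 * i + 2) = CA;
    CA = CA * A;
  }
  vec rd;
  mat Q = qr_pos(O, &rd);
  ok = abs(rd).min() > 1e-10 * std::max(1.0, abs(rd).max());
  return Q;
}

// [[Rcpp::export]]
Rcpp::List cpp_observability_basis(const arma::mat& A, const arma::mat& C, int m) {
  bool ok;
  mat Q = observability_basis(A, C, m, ok);
  return Rcpp::List::create(Rcpp::Named("basis") = Q, Rcpp::Named("full_rank") = ok);
}

// ---------------------------------------------------------------------------
// fused per-image extraction + fit (pipeline hot path)
// ---------------------------------------------------------------------------

// origins: M x 2 (0-based row, col); returns bases/models for every kept
// direction variant. Degeneracy is checked once per base patch (rotation
// leaves the centered Frobenius norm unchanged).
// [[Rcpp::export]]
Rcpp::List cpp_fit_image(const arma::cube& image, const arma::imat& origins,
                         int size, bool four_directions, int m, double ridge,
                         double stab_tol, int stab_max_iter, double degen_eps) {
  const uword n0 = origins.n_rows;
  const int ndir = four_directions ? 4 : 1;
  std::vector<uword> keep;
  keep.reserve(n0);
  std::vector<cube> base_patches;
  base_patches.reserve(n0);
  uword n_degenerate = 0;
  for (uword i = 0; i < n0; ++i) {
    const uword r0 = (uword) origins(i, 0), c0 = (uword) origins(i, 1);
    cube P = image.subcube(r0, c0, 0, r0 + size - 1, c0 + size - 1, 2);
    vec mu(3);
    double fn2 = 0.0;
    for (uword k = 0; k < 3; ++k) {
      mu(k) = accu(P.slice(k)) / (double) (size * size);
      fn2 += accu(square(P.slice(k) - mu(k)));
    }
    if (std::sqrt(fn2) < degen_eps * (double) size) {
      ++n_degenerate;
      continue;
    }
    keep.push_back(i);
    base_patches.push_back(P);
  }
  const uword nk = keep.size();
  const uword M = nk * ndir;
  cube bases(3 * m, 3, std::max<uword>(M, 1), fill::zeros);
  cube Acube(3, 3, std::max<uword>(M, 1), fill::zeros);
  cube Ccube(3, 3, std::max<uword>(M, 1), fill::zeros);
  mat means(3, std::max<uword>(M, 1), fill::zeros);
  vec sigma1(std::max<uword>(M, 1), fill::zeros);
  uvec stabilized(std::max<uword>(M, 1), fill::zeros);
  uvec stab_failed(std::max<uword>(M, 1), fill::zeros);
  imat meta(std::max<uword>(M, 1), 3, fill::zeros);   // row, col, direction
  uword idx = 0;
  for (uword i = 0; i < nk; ++i) {
    cube P = base_patches[i];
    for (int d = 0; d < ndir; ++d) {
      if (d > 0) P = rot90cw_cube(P);
      FitResult fr = fit_patch_core(P, ridge, stab_tol, stab_max_iter, degen_eps);
      bool ok;
      bases.slice(idx) = observability_basis(fr.A, fr.C, m, ok);
      Acube.slice(idx) = fr.A;
      Ccube.slice(idx) = fr.C;
      means.col(idx) = fr.mean;
      sigma1(idx) = fr.sigma1;
      stabilized(idx) = fr.stabilized ? 1 : 0;
      stab_failed(idx) = fr.stab_converged ? 0 : 1;
      meta(idx, 0) = origins(keep[i], 0);
      meta(idx, 1) = origins(keep[i], 1);
      meta(idx, 2) = d * 90;
      ++idx;
    }
  }
  if (M == 0) {
    bases.reset(); Acube.reset(); Ccube.reset();
    means.reset(); sigma1.reset();
  }
  return Rcpp::List::create(
      Rcpp::Named("bases") = bases, Rcpp::Named("A") = Acube,
      Rcpp::Named("C") = Ccube, Rcpp::Named("mean") = means,
      Rcpp::Named("sigma1") = sigma1, Rcpp::Named("stabilized") = stabilized,
      Rcpp::Named("stab_failed") = stab_failed, Rcpp::Named("meta") = meta,
      Rcpp::Named("n_points") = (int) M,
      Rcpp::Named("n_degenerate") = (int) n_degenerate);
}

// ---------------------------------------------------------------------------
// synthetic trajectory generation (uses R's RNG stream for reproducibility)
// ---------------------------------------------------------------------------

// draw up to max_draws initial states x(1) ~ N(0, scale^2 I) and keep the
// noiseless trajectory with the best conditioning sigma_3/sigma_1 of the
// 3 x n state matrix, early-stopping once it reaches `threshold`
// (persistent-excitation selection)
// [[Rcpp::export]]
arma::mat cpp_best_trajectory(const arma::mat& A, int n, double scale,
                              double threshold, int max_draws) {
  mat best;
  double best_r = -1.0;
  for (int d = 0; d < max_draws; ++d) {
    Rcpp::NumericVector z = Rcpp::rnorm(3);
    vec x1 = {z[0], z[1], z[2]};
    x1 *= scale;
    mat X(3, n);
    X.col(0) = x1;
    for (int i = 1; i < n; ++i) X.col(i) = A * X.col(i - 1);
    vec s = svd(X);
    const double r = s(2) / s(0);
    if (r > best_r) { best_r = r; best = X; }
    if (r >= threshold) break;
  }
  return best;
}

// ---------------------------------------------------------------------------
// Grassmann geometry (batch)
// ---------------------------------------------------------------------------

// geodesic distance through the log map: singular values of Y inv(X'Y) - X
// are tan(theta_i); returns NaN at the cut locus. The cut locus shows up on
// this route as inv(X'Y) blowing up: theta_max >= pi/2 - CUT_LOCUS_EPS
// corresponds to tan(theta_max) >= ~1/CUT_LOCUS_EPS.
static double dist_pair(const mat& X, const mat& Y) {
  mat Mi;
  if (!inv(Mi, X.t() * Y)) return datum::nan;
  mat L = Y * Mi - X;
  vec sl;
  if (!svd(sl, L)) return datum::nan;
  vec th = atan(sl);
  if (th.max() >= datum::pi / 2.0 - CUT_LOCUS_EPS) return datum::nan;
  return norm(th, 2);
}

static bool log_pair(const mat& X, const mat& Y, mat& Delta) {
  mat Mi;
  if (!inv(Mi, X.t() * Y)) return false;
  mat L = Y * Mi - X;
  mat U, V;
  vec s;
  if (!svd_econ(U, s, V, L)) return false;
  vec th = atan(s);
  if (th.max() >= datum::pi / 2.0 - CUT_LOCUS_EPS) return false;
  Delta = U * diagmat(th) * V.t();
  return true;
}

// [[Rcpp::export]]
arma::mat cpp_log_map(const arma::mat& base, const arma::mat& target) {
  mat Delta;
  if (!log_pair(base, target, Delta))
    Rcpp::stop("cut locus: subspaces have a principal angle at pi/2");
  return Delta;
}

// [[Rcpp::export]]
arma::mat cpp_exp_map(const arma::mat& base, const arma::mat& tangent) {
  mat U, V;
  vec s;
  if (norm(tangent, "fro") == 0.0) return base;
  svd_econ(U, s, V, tangent);
  mat Y = base * V * diagmat(cos(s)) * V.t() + U * diagmat(sin(s)) * V.t();
  return qr_pos(Y);
}

// [[Rcpp::export]]
arma::mat cpp_pairwise_dist(const arma::cube& A, const arma::cube& B) {
  mat D(A.n_slices, B.n_slices);
  for (uword i = 0; i < A.n_slices; ++i)
    for (uword j = 0; j < B.n_slices; ++j)
      D(i, j) = dist_pair(A.slice(i), B.slice(j));
  return D;
}

// [[Rcpp::export]]
arma::mat cpp_self_dist(const arma::cube& A) {
  mat D(A.n_slices, A.n_slices, fill::zeros);
  for (uword i = 0; i < A.n_slices; ++i)
    for (uword j = i + 1; j < A.n_slices; ++j) {
      const double d = dist_pair(A.slice(i), A.slice(j));
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// sum of log maps from one base to many targets (Karcher mean inner loop)
// [[Rcpp::export]]
Rcpp::List cpp_log_map_sum(const arma::mat& base, const arma::cube& targets) {
  mat acc(base.n_rows, base.n_cols, fill::zeros);
  mat Delta;
  uword n_cut = 0;
  for (uword i = 0; i < targets.n_slices; ++i) {
    if (log_pair(base, targets.slice(i), Delta)) acc += Delta;
    else ++n_cut;
  }
  return Rcpp::List::create(Rcpp::Named("sum") = acc,
                            Rcpp::Named("n_cut") = (int) n_cut,
                            Rcpp::Named("n") = (int) targets.n_slices);
}

// VLAD accumulation: nearest-word assignment (ties -> lowest index) plus the
// scalar (sum of log-map norms = geodesic distances) or tangent (sum of
// log-map matrices, row-major flattened blocks) raw code. Points with any
// cut-locus word distance are skipped. Summation follows ascending point index.
// [[Rcpp::export]]
Rcpp::List cpp_vlad_raw(const arma::cube& points, const arma::cube& words,
                        bool tangent) {
  const uword n = points.n_slices, k = words.n_slices;
  const uword p = words.n_rows, r = words.n_cols;
  ivec assign(std::max<uword>(n, 1), fill::value(-1));
  if (n == 0) assign.reset();
  vec scalar_raw(k, fill::zeros);
  cube tangent_raw(p, r, k, fill::zeros);
  uword n_skipped = 0;
  vec d(k);
  for (uword i = 0; i < n; ++i) {
    bool bad = false;
    for (uword j = 0; j < k; ++j) {
      d(j) = dist_pair(words.slice(j), points.slice(i));
      if (!std::isfinite(d(j))) { bad = true; break; }
    }
    if (bad) { ++n_skipped; continue; }
    const uword j = d.index_min();        // first minimum -> lowest index
    assign(i) = (sword) j;
    if (tangent) {
      mat Delta;
      log_pair(words.slice(j), points.slice(i), Delta);
      tangent_raw.slice(j) += Delta;
    } else {
      scalar_raw(j) += d(j);
    }
  }
  vec raw;
  if (tangent) {
    raw.set_size(k * p * r);
    uword idx = 0;
    for (uword j = 0; j < k; ++j) {
      mat t = tangent_raw.slice(j).t();   // row-major flatten
      for (uword z = 0; z < p * r; ++z) raw(idx++) = t(z);
    }
  } else {
    raw = scalar_raw;
  }
  return Rcpp::List::create(Rcpp::Named("assign") = assign,
                            Rcpp::Named("raw") = raw,
                            Rcpp::Named("n_skipped") = (int) n_skipped);
}
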