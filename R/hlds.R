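#' Largest singular value of a matrix
#'
#' `sigma_1(A)` upper-bounds the spectral radius, so `sigma_1 <= 1` certifies
#' that all eigenvalue magnitudes of the transition matrix are at most 1
#' (a stable system).
#'
#' @param A A numeric matrix with finite entries.
#' @return The largest singular value, a non-negative scalar.
#' @export
largest_singular_value <- function(A) {
  if (!all(is.finite(A))) {
    abort_grassvlad("`A` contains non-finite values", "grassvlad_numeric_error")
  }
  svd(A, nu = 0, nv = 0)$d[1]
}

#' One-step least-squares transition estimate
#'
#' Estimates the state transition matrix as the ridge-regularized minimizer
#' of `||X_next - A X_prev||_F^2`:
#' `A = X_next X_prev^T (X_prev X_prev^T + ridge I)^{-1}`.
#'
#' @param X_prev,X_next `3 x (n-1)` state matrices (columns are consecutive
#'   states; `X_next` is `X_prev` shifted by one step).
#' @param ridge Non-negative ridge added to the normal matrix diagonal
#'   (default `1e-8`).
#' @return The `3 x 3` transition matrix.
#' @export
least_squares_transition <- function(X_prev, X_next, ridge = 1e-8) {
  if (!is.matrix(X_prev) || !is.matrix(X_next) ||
      !all(dim(X_prev) == dim(X_next))) {
    abort_grassvlad("`X_prev` and `X_next` must be matrices of equal shape",
                    "grassvlad_dimension_error")
  }
  stopifnot(ridge >= 0)
  M <- tcrossprod(X_prev)
  diag(M) <- diag(M) + ridge
  t(solve(M, X_prev %*% t(X_next)))
}

#' Stabilize a transition matrix by constraint generation
#'
#' If `sigma_1(A) <= 1 + tol` the matrix is returned unchanged. Otherwise the
#' least-squares objective `||X_next - A X_prev||_F^2` is re-minimized under
#' accumulated linear constraints `g^T vec(A) <= 1` with
#' `g = vec(u_1 v_1^T)` for the top singular pair of each visited iterate —
#' each constraint caps `u_1^T A v_1`, and iterating until
#' `sigma_1 <= 1 + tol` certifies stability. The returned matrix never has a
#' worse objective than the naive rescaling `A / sigma_1(A)` (which is
#' feasible for every constraint set).
#'
#' @param A The unstable `3 x 3` least-squares transition matrix.
#' @param X_prev,X_next The state matrices defining the objective.
#' @param tol Stability tolerance (default `1e-6`).
#' @param max_iter Maximum constraint-generation iterations (default 50).
#' @param ridge Ridge used in the quadratic form (scale-relative, default `1e-8`).
#' @return The stabilized `3 x 3` matrix with attribute `"stabilization"`, a
#'   list with the QP data (`P`, `q`, `r`), the accumulated constraints, the
#'   solution vector `alpha` and the final `sigma1`.
#' @export
stabilize_transition <- function(A, X_prev, X_next, tol = 1e-6, max_iter = 50L,
                                 ridge = 1e-8) {
  if (!all(is.finite(A))) {
    abort_grassvlad("`A` contains non-finite values", "grassvlad_numeric_error")
  }
  if (largest_singular_value(A) <= 1 + tol) return(A)
  res <- cpp_stabilize(A, X_prev, X_next, tol, max_iter, ridge)
  if (!res$converged) {
    abort_grassvlad(
      sprintf("stabilization did not converge in %d iterations (sigma1 = %.6g)",
              max_iter, res$sigma1),
      "grassvlad_stabilization_error", last_iterate = res$A)
  }
  structure(res$A,
            stabilization = list(P = res$P, q = as.numeric(res$q), r = res$r,
                                 constraints = res$constraints,
                                 alpha = as.numeric(res$A),
                                 sigma1 = res$sigma1,
                                 n_constraints = res$n_constraints))
}

#' Identify a higher-order linear dynamical system for one patch
#'
#' Subtracts the per-channel mean, runs the higher-order SVD, takes the
#' mode-3 factor as the orthonormal mapping matrix `C`, reads the hidden
#' state sequence off the mode-3 unfolding of the remaining factors (pixels
#' in row-major scan order), and fits the state transition matrix `A` by
#' one-step least squares. Because the centered state sequence of a linear
#' system obeys an affine recurrence `x(i+1) = A x(i) + c` (the constant
#' absorbs the difference between the sample mean and the true process
#' mean), the regression includes an intercept and keeps the linear part —
#' this makes identification exact on noiseless data. If the fitted `A` has
#' `sigma_1 > 1 + stab_tol` it is stabilized with [stabilize_transition()].
#'
#' @param patch An `N x N x 3` array in `[0, 1]` (not degenerate; see
#'   [is_degenerate()]).
#' @param ridge Scale-relative ridge for the regression (default `1e-8`).
#' @param stab_tol Stability tolerance (default `1e-6`).
#' @param stab_max_iter Maximum stabilization iterations (default 50).
#' @param direction Direction metadata carried from the patch (degrees).
#' @return An object of class `hlds_model`: list with `A` (3 x 3), `C`
#'   (3 x 3 orthogonal), `mean` (length-3 channel mean), `sigma1`,
#'   `stabilized` flag and `direction`.
#' @examples
#' sys <- make_stable_system(seed = 1)
#' p <- synth_patch(sys, size = 8, seed = 2)
#' m <- fit_hlds(p)
#' m$sigma1
#' @export
fit_hlds <- function(patch, ridge = 1e-8, stab_tol = 1e-6, stab_max_iter = 50L,
                     direction = 0L) {
  check_image(patch)
  if (dim(patch)[1] != dim(patch)[2]) {
    abort_grassvlad("`patch` must be square", "grassvlad_dimension_error")
  }
  res <- cpp_fit_patch(patch, ridge, stab_tol, stab_max_iter, 1e-8)
  if (res$degenerate) {
    abort_grassvlad("patch is degenerate (no identifiable dynamics)",
                    "grassvlad_degenerate_error")
  }
  if (res$stabilized && !res$stab_converged) {
    abort_grassvlad("stabilization did not converge for this patch",
                    "grassvlad_stabilization_error", last_iterate = res$A)
  }
  structure(list(A = res$A, C = res$C, mean = as.numeric(res$mean),
                 sigma1 = res$sigma1, stabilized = res$stabilized,
                 direction = as.integer(direction)),
            class = "hlds_model")
}

#' @export
print.hlds_model <- function(x, ...) {
  cat("<hlds_model> sigma1 =", format(x$sigma1, digits = 4),
      if (x$stabilized) "(stabilized)" else "", "\n")
  invisible(x)
}
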