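#' Construct a Grassmann point from a basis matrix
#'
#' A point on the Grassmann manifold Gr(p, r) is an r-dimensional subspace of
#' R^p, represented (non-uniquely) by a `p x r` matrix with orthonormal
#' columns. Two points are equal iff their geodesic distance is zero.
#'
#' @param basis A `p x r` matrix with orthonormal columns (checked to 1e-8).
#' @param m Optional observability horizon metadata.
#' @return The basis matrix with class `grassmann_point`.
#' @export
grassmann_point <- function(basis, m = NULL) {
  basis <- as.matrix(basis)
  if (max(abs(crossprod(basis) - diag(ncol(basis)))) > 1e-8) {
    abort_grassvlad("`basis` columns are not orthonormal", "grassvlad_data_error")
  }
  structure(basis, class = c("grassmann_point", "matrix"), m = m)
}

#' Observability subspace of an identified system
#'
#' Stacks the finite observability matrix
#' `O = [C; CA; CA^2; ...; CA^(m-1)]` (`3m x 3`) and orthonormalizes its
#' columns by QR with the R-factor diagonal forced positive (equivalent to
#' classical Gram-Schmidt on full-rank input, numerically safer and
#' deterministic). The column span of `O` is invariant to state-basis
#' changes, which is what makes it a canonical signature of the system.
#'
#' @param model An `hlds_model` from [fit_hlds()], or any list with `A`, `C`.
#' @param m Observability horizon (default 3).
#' @return A [grassmann_point()] of shape `3m x 3`.
#' @export
observability_subspace <- function(model, m = 3L) {
  stopifnot(m >= 1L)
  res <- cpp_observability_basis(model$A, model$C, as.integer(m))
  if (!res$full_rank) {
    abort_grassvlad("observability matrix is rank-deficient at this horizon",
                    "grassvlad_rank_error")
  }
  grassmann_point(res$basis, m = as.integer(m))
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    abort_grassvlad("points live on different Grassmannians",
                    "grassvlad_dimension_error")
  }
}

#' Inverse exponential (log) map on the Grassmann manifold
#'
#' Maps `target` into the tangent (horizontal) space at `base`: the returned
#' matrix `Delta` satisfies `exp_base(Delta) = target` and
#' `||Delta||_F = sqrt(sum(theta_i^2))` with `theta_i` the principal angles
#' between the two subspaces. Undefined on the cut locus (any principal
#' angle at pi/2).
#'
#' @param base,target `p x r` orthonormal bases of equal shape.
#' @return A `p x r` tangent matrix with attribute `base`.
#' @export
grassmann_log <- function(base, target) {
  check_same_shape(base, target)
  delta <- tryCatch(cpp_log_map(unclass(base), unclass(target)),
                    error = function(e) {
                      abort_grassvlad(conditionMessage(e), "grassvlad_cut_locus_error")
                    })
  structure(delta, base = unclass(base))
}

#' Exponential map on the Grassmann manifold
#'
#' Follows the geodesic from `base` with initial velocity `tangent` for unit
#' time. Requires `tangent` to be horizontal at `base`
#' (`base^T tangent = 0` within 1e-6).
#'
#' @param base A `p x r` orthonormal basis.
#' @param tangent A `p x r` tangent matrix at `base`.
#' @return The reached point as a `p x r` orthonormal basis.
#' @export
grassmann_exp <- function(base, tangent) {
  check_same_shape(base, tangent)
  if (max(abs(crossprod(unclass(base), unclass(tangent)))) > 1e-6) {
    abort_grassvlad("`tangent` is not horizontal at `base`",
                    "grassvlad_contract_error")
  }
  grassmann_point(cpp_exp_map(unclass(base), unclass(tangent)))
}

#' Geodesic distance between two Grassmann points
#'
#' The arc-length distance `d(a, b) = ||log_b(a)||_F = sqrt(sum(theta_i^2))`,
#' computed through the log map (singular values of
#' `b (a^T b)^{-1} - a` are `tan(theta_i)`). Symmetric; zero iff the two
#' bases span the same subspace; errors at the cut locus.
#'
#' @param a,b `p x r` orthonormal bases of equal shape.
#' @return A non-negative scalar.
#' @export
grassmann_distance <- function(a, b) {
  check_same_shape(a, b)
  d <- cpp_pairwise_dist(array(unclass(a), c(dim(a), 1L)),
                         array(unclass(b), c(dim(b), 1L)))[1L, 1L]
  if (!is.finite(d)) {
    abort_grassvlad("cut locus: subspaces have a principal angle at pi/2",
                    "grassvlad_cut_locus_error")
  }
  d
}

#' Principal angles between two subspaces
#'
#' `theta_i = acos(sigma_i(a^T b))` with singular values clipped to `[0, 1]`;
#' returned in descending order, all in `[0, pi/2]`. This closed form is the
#' standard independent check of the log-map distance
#' (`d = sqrt(sum(theta_i^2))`).
#'
#' @param a,b `p x r` orthonormal bases of equal shape.
#' @return Numeric vector of `r` angles, descending.
#' @export
principal_angles <- function(a, b) {
  check_same_shape(a, b)
  s <- svd(crossprod(unclass(a), unclass(b)), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(s, 0), 1)), decreasing = TRUE)
}

# distance matrix between two clouds (p x r x n arrays); NaN marks cut-locus
cloud_cross_dist <- function(a, b) cpp_pairwise_dist(as_cloud(a), as_cloud(b))

cloud_self_dist <- function(a) cpp_self_dist(as_cloud(a))

#' Karcher mean (Riemannian center of mass) of Grassmann points
#'
#' Iterates `mu <- exp_mu(mean of log_mu(p_i))` from `init` until the mean
#' tangent norm falls below `tol`. The returned point satisfies the
#' first-order condition `||sum log_mu(p_i)||_F <= n * tol`. Convergence is
#' guaranteed for point sets within an injectivity-radius ball, which the
#' codebook clusters satisfy in practice; the step size is the classical 1.
#'
#' @param points A `p x r x n` array or list of bases.
#' @param init Initial point (defaults to the first point).
#' @param tol Stopping tolerance on the mean tangent norm (default `1e-6`).
#' @param max_iter Maximum iterations (default 100).
#' @return A [grassmann_point()] with attributes `iterations` and `residual`.
#' @export
karcher_mean <- function(points, init = NULL, tol = 1e-6, max_iter = 100L) {
  pts <- as_cloud(points)
  n <- cloud_size(pts)
  if (n < 1L) abort_grassvlad("need at least one point", "grassvlad_data_error")
  mu <- matrix(unclass(init %||% pts[, , 1L]), dim(pts)[1L], dim(pts)[2L])
  resid <- Inf
  iter <- 0L
  repeat {
    ls <- cpp_log_map_sum(mu, pts)
    if (ls$n_cut > 0L) {
      abort_grassvlad(
        sprintf("cut-locus pair encountered for %d point(s) during Karcher mean",
                ls$n_cut), "grassvlad_cut_locus_error")
    }
    Tm <- ls$sum / n
    resid <- sqrt(sum(Tm^2))
    if (resid <= tol) break
    if (iter >= max_iter) {
      abort_grassvlad(
        sprintf("Karcher mean did not converge in %d iterations (residual %.3g)",
                max_iter, resid),
        "grassvlad_convergence_error", last_iterate = mu, residual = resid)
    }
    mu <- cpp_exp_map(mu, Tm)
    iter <- iter + 1L
  }
  structure(grassmann_point(mu), iterations = iter, residual = resid)
}

#' K-medoids clustering on the Grassmann manifold
#'
#' Alternating medoid update on the precomputed geodesic-distance matrix,
#' initialized by a seeded farthest-point heuristic. Deterministic given
#' `seed`; the total within-cluster distance is non-increasing across
#' iterations. Cut-locus distances (rare) are replaced by the supremum
#' `pi/2 * sqrt(r)` so the clustering remains defined.
#'
#' @param points A `p x r x n` array or list of bases.
#' @param k Number of medoids (`k <= n`).
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum alternation rounds (default 100).
#' @param dist_matrix Optional precomputed `n x n` distance matrix.
#' @return A list with `medoids` (indices), `assignment` (length-n), and
#'   `objective` (total within-cluster distance).
#' @export
k_medoids <- function(points, k, seed = 1L, max_iter = 100L, dist_matrix = NULL) {
  pts <- as_cloud(points)
  n <- cloud_size(pts)
  if (k > n) {
    abort_grassvlad(sprintf("k = %d exceeds number of points (%d)", k, n),
                    "grassvlad_config_error")
  }
  D <- dist_matrix %||% cloud_self_dist(pts)
  if (any(!is.finite(D))) {
    D[!is.finite(D)] <- pi / 2 * sqrt(dim(pts)[2])
  }
  # farthest-point init: seeded first medoid, then maximin additions
  med <- integer(k)
  med[1L] <- with_seed(seed, sample.int(n, 1L))
  if (k > 1L) {
    mind <- D[, med[1L]]
    for (j in 2:k) {
      med[j] <- which.max(mind)
      mind <- pmin(mind, D[, med[j]])
    }
  }
  assign <- max.col(-t(D[med, , drop = FALSE]), ties.method = "first")
  for (it in seq_len(max_iter)) {
    new_med <- med
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) == 0L) next
      tot <- colSums(D[members, members, drop = FALSE])
      new_med[j] <- members[which.min(tot)]
    }
    new_assign <- max.col(-t(D[new_med, , drop = FALSE]), ties.method = "first")
    if (identical(new_med, med) && identical(new_assign, assign)) break
    med <- new_med
    assign <- new_assign
  }
  objective <- sum(D[cbind(med[assign], seq_len(n))])
  list(medoids = med, assignment = assign, objective = objective)
}
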