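# independent oracles and fixture builders used across the suite

rand_orthonormal <- function(p, r) qr.Q(qr(matrix(rnorm(p * r), p, r)))

# principal-angle distance oracle: sqrt(sum(acos(sv(a'b))^2))
oracle_distance <- function(a, b) {
  s <- svd(crossprod(a, b), nu = 0, nv = 0)$d
  sqrt(sum(acos(pmin(pmax(s, 0), 1))^2))
}

# explicit mode products, written independently of the compiled kernels
r_mode1 <- function(Y, M) {
  out <- array(0, c(nrow(M), dim(Y)[2], dim(Y)[3]))
  for (k in seq_len(dim(Y)[3])) out[, , k] <- M %*% Y[, , k]
  out
}
r_mode2 <- function(Y, M) {
  out <- array(0, c(dim(Y)[1], nrow(M), dim(Y)[3]))
  for (k in seq_len(dim(Y)[3])) out[, , k] <- Y[, , k] %*% t(M)
  out
}
r_mode3 <- function(Y, M) {
  out <- array(0, c(dim(Y)[1], dim(Y)[2], nrow(M)))
  for (k2 in seq_len(nrow(M))) {
    acc <- matrix(0, dim(Y)[1], dim(Y)[2])
    for (k in seq_len(dim(Y)[3])) acc <- acc + M[k2, k] * Y[, , k]
    out[, , k2] <- acc
  }
  out
}
r_tucker_reconstruct <- function(f) r_mode3(r_mode2(r_mode1(f$core, f$U1), f$U2), f$U3)

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# cloud of random 9x3 Grassmann points
random_cloud <- function(n, p = 9, r = 3) {
  out <- array(0, c(p, r, n))
  for (i in seq_len(n)) out[, , i] <- rand_orthonormal(p, r)
  out
}

# a random horizontal tangent at basis X with given Frobenius norm
random_tangent <- function(X, norm = 0.1) {
  Z <- matrix(rnorm(length(X)), nrow(X))
  T <- Z - X %*% crossprod(X, Z)
  T * (norm / sqrt(sum(T^2)))
}

# tight bundle of points around a center, by small tangent perturbations
point_bundle <- function(center, n, spread = 0.05) {
  out <- array(0, c(dim(center), n))
  for (i in seq_len(n)) {
    out[, , i] <- grassmann_exp(grassmann_point(center),
                                random_tangent(center, runif(1, 0, spread)))
  }
  out
}

# ground-truth observability basis of a (A, C) pair
truth_basis <- function(A, C, m = 3) {
  O <- do.call(rbind, lapply(seq_len(m) - 1L, function(i) {
    Ai <- diag(3); for (z in seq_len(i)) Ai <- Ai %*% A
    C %*% Ai
  }))
  qr.Q(qr(O))
}

ls_objective <- function(A, Xp, Xn) sum((Xn - A %*% Xp)^2)

# tiny two-class manifest written to a temp dir (shared across tests)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "grassvlad-tiny-ds")
      spec <- synth_dataset_spec(n_classes = 2, images_per_class = 6,
                                 image_size = 64, patients_per_class = 3,
                                 seed = 11)
      cache <<- list(manifest = make_dataset(spec, d), dir = d, spec = spec)
    }
    cache
  }
})
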