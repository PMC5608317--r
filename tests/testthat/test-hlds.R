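test_that("least-squares transition recovers simple and simulated dynamics", {
  set.seed(20)
  X <- matrix(rnorm(3 * 20), 3)
  expect_equal(least_squares_transition(X, X), diag(3), tolerance = 1e-6)
  expect_equal(least_squares_transition(X, 0 * X), matrix(0, 3, 3),
               tolerance = 1e-10)

  # forward-simulated states from a known rotation (non-decaying, so the
  # design stays well conditioned at the op's fixed absolute ridge)
  A_true <- make_stable_system(seed = 21)$A_true
  A_true <- A_true / largest_singular_value(A_true)
  x <- matrix(0, 3, 64); x[, 1] <- rnorm(3)
  for (i in 2:64) x[, i] <- A_true %*% x[, i - 1]
  A_hat <- least_squares_transition(x[, 1:63], x[, 2:64])
  expect_equal(A_hat, A_true, tolerance = 1e-8)

  expect_error(least_squares_transition(X, X[, 1:5]),
               class = "grassvlad_dimension_error")
})

test_that("largest singular value behaves on closed-form cases", {
  expect_equal(largest_singular_value(diag(3)), 1)
  expect_equal(largest_singular_value(matrix(0, 3, 3)), 0)
  expect_equal(largest_singular_value(diag(c(0.5, 0.2, 0.1))), 0.5)
})

test_that("stabilization certifies sigma1 and never loses to naive rescaling", {
  set.seed(22)
  n_done <- 0
  while (n_done < 30) {
    Xp <- matrix(rnorm(3 * 63), 3)
    A0 <- matrix(rnorm(9), 3); A0 <- A0 * (runif(1, 1.1, 2) / svd(A0)$d[1])
    Xn <- A0 %*% Xp + 0.3 * matrix(rnorm(3 * 63), 3)
    A_ls <- least_squares_transition(Xp, Xn)
    s1 <- largest_singular_value(A_ls)
    if (s1 <= 1 + 1e-6 || s1 > 2) next
    n_done <- n_done + 1
    A_st <- stabilize_transition(A_ls, Xp, Xn)
    expect_lte(largest_singular_value(A_st), 1 + 1e-6)
    expect_lte(ls_objective(A_st, Xp, Xn),
               ls_objective(A_ls / s1, Xp, Xn) + 1e-8)
  }
  # already-stable input returned unchanged
  A <- diag(c(0.9, 0.5, 0.1))
  expect_identical(stabilize_transition(A, Xp, Xn), A)
  # strongly unstable input still certified
  A2 <- stabilize_transition(2 * diag(3), Xp, 2 * Xp)
  expect_lte(largest_singular_value(A2), 1 + 1e-6)
})

test_that("stabilization QP solution matches an independent QP solver", {
  set.seed(23)
  n_checked <- 0
  while (n_checked < 10) {
    Xp <- matrix(rnorm(3 * 63), 3)
    A0 <- matrix(rnorm(9), 3); A0 <- A0 * (1.5 / svd(A0)$d[1])
    Xn <- A0 %*% Xp + 0.3 * matrix(rnorm(3 * 63), 3)
    A_ls <- least_squares_transition(Xp, Xn)
    if (largest_singular_value(A_ls) <= 1 + 1e-6) next
    A_st <- stabilize_transition(A_ls, Xp, Xn)
    sinfo <- attr(A_st, "stabilization")
    expect_gt(sinfo$n_constraints, 0)
    # constraints are vec(u1 v1^T): g' vec(A) must equal u1' A v1 for the
    # final iterate's top singular pair
    sv <- svd(A_st)
    g_new <- as.numeric(sv$u[, 1] %*% t(sv$v[, 1]))
    expect_equal(sum(g_new * as.numeric(A_st)), sv$d[1], tolerance = 1e-8)
    # quadprog on the same accumulated constraint set
    sol <- quadprog::solve.QP(2 * sinfo$P, 2 * sinfo$q,
                              -sinfo$constraints,
                              rep(-1, ncol(sinfo$constraints)))
    obj_mine <- ls_objective(A_st, Xp, Xn)
    obj_qp <- ls_objective(matrix(sol$solution, 3), Xp, Xn)
    expect_equal(obj_mine, obj_qp, tolerance = 1e-3)
    n_checked <- n_checked + 1
  }
})

test_that("fit_hlds recovers a noiseless system's observability subspace", {
  for (s in 1:25) {
    sys <- make_stable_system(seed = 100 + s)
    p <- synth_patch(sys, size = 8, seed = 200 + s)
    m <- fit_hlds(p)
    expect_lt(max(abs(crossprod(m$C) - diag(3))), 1e-10)
    G_fit <- observability_subspace(m)
    G_true <- truth_basis(sys$A_true, sys$C_true)
    expect_lt(grassmann_distance(G_fit, grassmann_point(G_true)), 1e-6)
    expect_false(m$stabilized)
  }
})

test_that("the four rotation variants share C but generally not A", {
  sys <- make_stable_system(seed = 31)
  p <- synth_patch(sys, size = 8, seed = 32)
  fits <- lapply(rotation_variants(p), fit_hlds)
  for (d in 2:4) {
    expect_equal(fits[[d]]$C, fits[[1]]$C, tolerance = 1e-10)
    expect_gt(max(abs(fits[[d]]$A - fits[[1]]$A)), 1e-4)
  }
})

test_that("fit_hlds is deterministic and rejects degenerate patches", {
  sys <- make_stable_system(seed = 33)
  p <- synth_patch(sys, size = 8, seed = 34)
  expect_identical(fit_hlds(p), fit_hlds(p))
  expect_error(fit_hlds(array(0.5, c(8, 8, 3))),
               class = "grassvlad_degenerate_error")
})

test_that("R-level fit path agrees with the fused image kernel", {
  img <- synth_image(make_stable_system(seed = 36), image_size = 32,
                     patch_size = 8, seed = 37)
  f <- file.path(tempdir(), "fused-check.png")
  png::writePNG(img, f)
  emb <- embed_images(tibble::tibble(path = f, label = "a", patient_id = "p",
                                     magnification = NA),
                      patching = patch_config(8, "non_overlapping"))
  cloud <- emb$points[[1]]
  # same patches through the R-level path: extract -> rotate -> fit -> embed
  ps <- extract_patches(png::readPNG(f), patch_config(8, "non_overlapping"))
  idx <- 1L
  for (i in seq_len(nrow(ps))) {
    for (v in rotation_variants(ps$values[[i]])) {
      G <- observability_subspace(fit_hlds(v))
      # same algorithm on both paths; BLAS kernels may differ with memory
      # alignment, so agreement is numerical, not bitwise
      expect_lt(oracle_distance(unclass(G), cloud[, , idx]), 1e-6)
      idx <- idx + 1L
    }
  }
  expect_equal(idx - 1L, dim(cloud)[3])
})
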