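test_that("observability subspaces match closed forms and system invariants", {
  G1 <- observability_subspace(list(A = matrix(0, 3, 3), C = diag(3)))
  expect_equal(unclass(G1), rbind(diag(3), matrix(0, 6, 3)), tolerance = 1e-12,
               ignore_attr = TRUE)

  G2 <- observability_subspace(list(A = diag(3), C = diag(3)))
  expect_equal(unclass(G2), rbind(diag(3), diag(3), diag(3)) / sqrt(3),
               tolerance = 1e-12, ignore_attr = TRUE)

  # similar systems (T' A T, C T) share the subspace exactly
  set.seed(40)
  for (i in 1:10) {
    sys <- make_stable_system(seed = 40 + i)
    Tm <- rand_orthonormal(3, 3)
    Ga <- observability_subspace(list(A = sys$A_true, C = sys$C_true))
    Gb <- observability_subspace(list(A = t(Tm) %*% sys$A_true %*% Tm,
                                      C = sys$C_true %*% Tm))
    expect_lt(grassmann_distance(Ga, Gb), 1e-8)
  }
})

test_that("geodesic distance agrees with the principal-angle oracle", {
  set.seed(41)
  for (i in 1:200) {
    a <- rand_orthonormal(9, 3); b <- rand_orthonormal(9, 3)
    expect_equal(grassmann_distance(grassmann_point(a), grassmann_point(b)),
                 oracle_distance(a, b), tolerance = 1e-6)
  }
  # symmetry and identity
  a <- rand_orthonormal(9, 3); b <- rand_orthonormal(9, 3)
  expect_equal(grassmann_distance(a, b), grassmann_distance(b, a),
               tolerance = 1e-8)
  expect_equal(grassmann_distance(a, a), 0, tolerance = 1e-8)
})

test_that("principal angles handle identical, orthogonal and permuted bases", {
  a <- grassmann_point(rand_orthonormal(9, 3))
  expect_equal(principal_angles(a, a), c(0, 0, 0), tolerance = 1e-7)

  b1 <- rbind(diag(3), matrix(0, 3, 3))
  b2 <- rbind(matrix(0, 3, 3), diag(3))
  expect_equal(principal_angles(grassmann_point(b1), grassmann_point(b2)),
               rep(pi / 2, 3))
  expect_error(grassmann_distance(grassmann_point(b1), grassmann_point(b2)),
               class = "grassvlad_cut_locus_error")

  perm <- unclass(a)[, c(2, 3, 1)]
  b <- grassmann_point(rand_orthonormal(9, 3))
  expect_equal(principal_angles(a, b), principal_angles(grassmann_point(perm), b),
               tolerance = 1e-10)
})

test_that("log and exp maps are mutually consistent", {
  set.seed(42)
  n_done <- 0
  while (n_done < 100) {
    a <- rand_orthonormal(9, 3); b <- rand_orthonormal(9, 3)
    if (max(principal_angles(grassmann_point(a), grassmann_point(b))) >
        pi / 2 - 0.05) next
    n_done <- n_done + 1
    d <- grassmann_log(a, b)
    # horizontality and norm identity
    expect_lt(max(abs(crossprod(a, d))), 1e-8)
    expect_equal(sqrt(sum(d^2)), oracle_distance(a, b), tolerance = 1e-8)
    # round trip
    e <- grassmann_exp(a, d)
    expect_lt(oracle_distance(unclass(e), b), 1e-6)
  }
  base <- grassmann_point(rand_orthonormal(9, 3))
  expect_equal(unclass(grassmann_exp(base, matrix(0, 9, 3))), unclass(base))
  expect_lt(sqrt(sum(grassmann_log(base, base)^2)), 1e-8)
  # geodesic distance equals the tangent norm below the cut locus
  tang <- random_tangent(unclass(base), norm = 0.7)
  reached <- grassmann_exp(base, tang)
  expect_equal(grassmann_distance(base, reached), 0.7, tolerance = 1e-8)
  # non-horizontal tangent rejected
  expect_error(grassmann_exp(base, unclass(base)),
               class = "grassvlad_contract_error")
})

test_that("the lines-in-the-plane closed forms hold", {
  line <- function(t) grassmann_point(matrix(c(cos(t), sin(t)), 2, 1))
  expect_equal(sqrt(sum(grassmann_log(line(0), line(0.3))^2)), 0.3,
               tolerance = 1e-10)
  expect_equal(grassmann_distance(line(0.1), line(0.5)), 0.4, tolerance = 1e-10)
  stepped <- grassmann_exp(line(0), matrix(c(0, 0.3), 2, 1))
  expect_lt(grassmann_distance(stepped, line(0.3)), 1e-10)

  km <- karcher_mean(list(unclass(line(0.2)), unclass(line(0.4))))
  expect_lt(grassmann_distance(km, line(0.3)), 1e-6)
})

test_that("basis invariance: outputs do not depend on the representative", {
  set.seed(43)
  for (i in 1:20) {
    a <- rand_orthonormal(9, 3); b <- rand_orthonormal(9, 3)
    Ra <- rand_orthonormal(3, 3); Rb <- rand_orthonormal(3, 3)
    expect_equal(grassmann_distance(a, b), grassmann_distance(a %*% Ra, b %*% Rb),
                 tolerance = 1e-8)
  }
})

test_that("triangle inequality holds on sampled triples", {
  set.seed(44)
  for (i in 1:200) {
    a <- rand_orthonormal(9, 3); b <- rand_orthonormal(9, 3)
    cc <- rand_orthonormal(9, 3)
    dab <- oracle_distance(a, b); dbc <- oracle_distance(b, cc)
    dac <- oracle_distance(a, cc)
    expect_lte(dac, dab + dbc + 1e-8)
  }
})

test_that("karcher mean satisfies its variance-minimizing contract", {
  set.seed(45)
  p <- rand_orthonormal(9, 3)
  expect_equal(unclass(karcher_mean(array(p, c(9, 3, 1)))), p, ignore_attr = TRUE)
  same <- array(p, c(9, 3, 4))
  km <- karcher_mean(same)
  expect_equal(unclass(km), p, ignore_attr = TRUE)
  expect_equal(attr(km, "iterations"), 0L)

  cloud <- point_bundle(rand_orthonormal(9, 3), 20, spread = 0.4)
  mu <- karcher_mean(cloud)
  # first-order condition
  obj <- function(x) sum(apply(cloud, 3, function(pt) oracle_distance(x, pt))^2)
  expect_lte(obj(unclass(mu)),
             min(apply(cloud, 3, obj)) + 1e-8)
})

test_that("k-medoids separates bundles and honors closed-form cases", {
  set.seed(46)
  c1 <- rand_orthonormal(9, 3)
  c2 <- rand_orthonormal(9, 3)
  cloud <- array(0, c(9, 3, 20))
  cloud[, , 1:10] <- point_bundle(c1, 10, spread = 0.05)
  cloud[, , 11:20] <- point_bundle(c2, 10, spread = 0.05)
  km <- k_medoids(cloud, 2, seed = 1)
  expect_setequal(km$assignment[1:10], km$assignment[1])
  expect_setequal(km$assignment[11:20], km$assignment[11])
  expect_false(km$assignment[1] == km$assignment[11])

  # k = 1 equals the brute-force medoid
  D <- sapply(1:20, function(i)
    sapply(1:20, function(j) oracle_distance(cloud[, , i], cloud[, , j])))
  k1 <- k_medoids(cloud, 1, seed = 2)
  expect_equal(k1$medoids, which.min(colSums(D)))

  # k = n: every point its own medoid
  kn <- k_medoids(cloud[, , 1:5], 5, seed = 3)
  expect_setequal(kn$medoids, 1:5)
  expect_error(k_medoids(cloud, 21), class = "grassvlad_config_error")
})
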