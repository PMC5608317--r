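test_that("l2 normalization and the zero flag", {
  v <- l2_normalize(c(3, 4))
  expect_equal(as.numeric(v), c(0.6, 0.8))
  expect_false(attr(v, "is_zero"))
  z <- l2_normalize(c(0, 0))
  expect_equal(as.numeric(z), c(0, 0))
  expect_true(attr(z, "is_zero"))
  set.seed(50)
  for (i in 1:10) {
    x <- rnorm(sample(2:20, 1))
    expect_equal(sqrt(sum(l2_normalize(x)^2)), 1, tolerance = 1e-12)
  }
})

make_codebook <- function(words) {
  structure(list(words = words, k = dim(words)[3], seed = 0L,
                 meta = list(n_points_pooled = 0L, n_points_used = 0L,
                             subsample_cap = 0L, refine_rounds = 0L,
                             log = character())),
            class = "grassvlad_codebook")
}

test_that("assignment matches an exhaustive distance table", {
  set.seed(51)
  words <- random_cloud(5)
  cb <- make_codebook(words)
  pts <- random_cloud(100)
  a <- assign_points(pts, cb)
  for (i in 1:100) {
    d <- sapply(1:5, function(j) oracle_distance(pts[, , i], words[, , j]))
    expect_equal(a[i], which.min(d))
  }
  # a point equal to a word maps to that word
  expect_equal(assign_points(array(words[, , 3], c(9, 3, 1)), cb), 3L)
  expect_equal(assign_points(words[, , rep(1, 4)], cb), rep(1L, 4))
})

test_that("scalar encoding aggregates geodesic distances per word", {
  set.seed(52)
  words <- random_cloud(2)
  cb <- make_codebook(words)
  # single point at a known distance from word 1, far from word 2's basin
  t1 <- random_tangent(words[, , 1], norm = 0.3)
  p <- grassmann_exp(grassmann_point(words[, , 1]), t1)
  code <- encode_image(array(unclass(p), c(9, 3, 1)), cb, "scalar")
  if (oracle_distance(unclass(p), words[, , 1]) <
      oracle_distance(unclass(p), words[, , 2])) {
    expect_equal(as.numeric(code), c(1, 0))
  }
  # a cloud equal to a word yields a zero code (zero distance to own word)
  z <- encode_image(array(words[, , 2], c(9, 3, 1)), cb, "scalar")
  expect_true(attr(z, "is_zero"))
  # empty cloud
  e <- encode_image(array(0, c(9, 3, 0)), cb, "scalar")
  expect_true(attr(e, "is_zero"))
  expect_equal(length(e), 2L)
})

test_that("codes are permutation invariant, unit norm, variant-consistent", {
  set.seed(53)
  words <- random_cloud(4)
  cb <- make_codebook(words)
  pts <- random_cloud(50)
  sc <- encode_image(pts, cb, "scalar")
  expect_equal(sqrt(sum(sc^2)), 1, tolerance = 1e-12)
  tg <- encode_image(pts, cb, "tangent")
  expect_equal(sqrt(sum(tg^2)), 1, tolerance = 1e-12)
  expect_length(tg, 4 * 9 * 3)
  # permuted cloud gives the same code (summation over a set)
  perm <- pts[, , sample(50)]
  expect_equal(as.numeric(encode_image(perm, cb, "scalar")), as.numeric(sc),
               tolerance = 1e-12)
  expect_equal(as.numeric(encode_image(perm, cb, "tangent")), as.numeric(tg),
               tolerance = 1e-12)
  # assignments do not depend on the variant
  expect_identical(assign_points(pts, cb), assign_points(pts, cb))
})

test_that("codebook learning is deterministic and finds planted bundles", {
  set.seed(54)
  g1 <- rand_orthonormal(9, 3); g2 <- rand_orthonormal(9, 3)
  cloud <- array(0, c(9, 3, 60))
  cloud[, , 1:30] <- point_bundle(g1, 30, spread = 0.04)
  cloud[, , 31:60] <- point_bundle(g2, 30, spread = 0.04)
  cb <- learn_codebook(cloud, k = 2, seed = 7)
  d_to_g <- sapply(list(g1, g2), function(g)
    min(sapply(1:2, function(j) oracle_distance(cb$words[, , j], g))))
  expect_lt(max(d_to_g), 0.05)

  cb2 <- learn_codebook(cloud, k = 2, seed = 7)
  expect_identical(cb$words, cb2$words)

  # k = 1 equals the Karcher mean of the (sub)sample
  cb1 <- learn_codebook(cloud, k = 1, seed = 3)
  mu <- karcher_mean(cloud, init = cloud[, , k_medoids(cloud, 1, seed = 3)$medoids])
  expect_lt(oracle_distance(cb1$words[, , 1], unclass(mu)), 1e-6)
})

test_that("encode_images produces one unit-norm code per image", {
  ds <- tiny_dataset()
  emb <- embed_images(ds$manifest[1:4, ],
                      patching = patch_config(8, "non_overlapping"))
  cb <- learn_codebook(emb, k = 4, seed = 1, subsample_cap = 500)
  codes <- encode_images(emb, cb)
  expect_equal(nrow(codes), 4L)
  expect_false(any(codes$is_zero))
  for (cd in codes$code) expect_equal(sqrt(sum(cd^2)), 1, tolerance = 1e-12)
})
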