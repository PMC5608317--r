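test_that("stable systems are stable, orthogonal and reproducible", {
  for (s in 1:30) {
    sys <- make_stable_system(seed = s)
    expect_lte(largest_singular_value(sys$A_true), 0.97 + 1e-12)
    expect_lt(max(abs(crossprod(sys$C_true) - diag(3))), 1e-10)
    expect_true(all(sys$mean >= 0.2 & sys$mean <= 0.8))
  }
  expect_identical(make_stable_system(seed = 5), make_stable_system(seed = 5))
})

test_that("synthetic patches are seeded, in-gamut and encode the dynamics", {
  sys <- make_stable_system(seed = 70)
  p1 <- synth_patch(sys, size = 8, seed = 71)
  p2 <- synth_patch(sys, size = 8, seed = 71)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_false(is_degenerate(p1))
  # noiseless patch: exact subspace recovery through the estimator
  G <- observability_subspace(fit_hlds(p1))
  expect_lt(grassmann_distance(G, system_subspace(sys)), 1e-6)
})

test_that("identification error grows gracefully with observation noise", {
  errs <- sapply(c(0, 0.01), function(sw) {
    median(sapply(1:20, function(s) {
      sys <- make_stable_system(seed = 700 + s, obs_noise = sw)
      p <- synth_patch(sys, size = 8, seed = 800 + s)
      grassmann_distance(observability_subspace(fit_hlds(p)),
                         system_subspace(sys))
    }))
  })
  expect_lt(errs[1], 1e-6)
  expect_lt(errs[2], 0.15)
  expect_gt(errs[2], errs[1])
})

test_that("synthetic images are mosaics of class-consistent tiles", {
  sys <- make_stable_system(seed = 72)
  img <- synth_image(sys, image_size = 32, patch_size = 8, seed = 73)
  expect_equal(dim(img), c(32, 32, 3))
  expect_true(all(img >= 0 & img <= 1))
  # aligned tiles each recover the same class subspace
  ps <- extract_patches(img, patch_config(8, "non_overlapping"))
  expect_equal(nrow(ps), 16L)
  Gt <- system_subspace(sys)
  d <- sapply(ps$values, function(v)
    grassmann_distance(observability_subspace(fit_hlds(v)), Gt))
  expect_lt(max(d), 1e-6)
  expect_error(synth_image(sys, image_size = 30, patch_size = 8),
               class = "grassvlad_config_error")
})

test_that("make_dataset writes a valid, byte-identical reproducible dataset", {
  d1 <- file.path(tempdir(), "repds1")
  d2 <- file.path(tempdir(), "repds2")
  spec <- synth_dataset_spec(n_classes = 2, images_per_class = 3,
                             image_size = 32, patients_per_class = 2, seed = 9)
  mf1 <- make_dataset(spec, d1)
  mf2 <- make_dataset(spec, d2)
  expect_equal(nrow(mf1), 6L)
  expect_equal(sort(table(mf1$label)), sort(c(class1 = 3L, class2 = 3L)),
               ignore_attr = TRUE)
  # patient round robin within class
  expect_equal(length(unique(mf1$patient_id[mf1$label == "class1"])), 2L)
  # byte-identical images across reruns
  for (i in seq_len(nrow(mf1))) {
    expect_identical(readBin(mf1$path[i], "raw", file.size(mf1$path[i])),
                     readBin(mf2$path[i], "raw", file.size(mf2$path[i])))
  }
  # manifest round trips through read_manifest
  mfr <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(mfr$path, mf1$path)
  # ground truth sidecar records a positive achieved separation
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_gte(gt$achieved_separation, spec$class_separation)
})

test_that("class separation controls downstream bundle separation", {
  ds <- tiny_dataset()
  emb <- embed_images(ds$manifest[c(1, 7), ],
                      patching = patch_config(8, "non_overlapping"))
  # class clouds concentrate around their own subspace: cross-class
  # point-to-point distances dominate within-class ones on average
  d11 <- grassvlad:::cloud_self_dist(emb$points[[1]])
  d12 <- grassvlad:::cloud_cross_dist(emb$points[[1]], emb$points[[2]])
  expect_gt(mean(d12), mean(d11[upper.tri(d11)]))
})
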