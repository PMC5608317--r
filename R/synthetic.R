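#' Draw a random stable linear dynamical system
#'
#' Builds a rotation-like transition matrix `A = s * O R(theta) O^T` with a
#' random rotation frame `O` in SO(3), rotation angle `theta` drawn uniformly
#' from `[0.3, pi - 0.3]` (bounding the angle away from 0 and pi keeps the
#' state trajectory well-excited in all three directions, so the system is
#' identifiable from a single patch), and overall scale
#' `s = rho * u, u ~ U(0.7, 1)`, so `sigma_1(A) <= rho < 1`. The mapping
#' matrix `C` is a random orthogonal matrix (QR of a Gaussian matrix) and the
#' channel mean is drawn uniformly from `[0.2, 0.8]` per channel.
#' Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param rho Stability margin: upper bound on `sigma_1(A)` (default 0.97).
#' @param state_scale Standard deviation of the initial state draw in
#'   [synth_patch()] (default 0.25).
#' @param process_noise,obs_noise Noise standard deviations `sigma_v`
#'   (state) and `sigma_w` (pixel), both default 0.
#' @return An object of class `lds_system_spec`: list with `A_true`,
#'   `C_true`, `mean`, `state_scale`, `process_noise`, `obs_noise`, `seed`.
#' @export
make_stable_system <- function(seed, rho = 0.97, state_scale = 0.25,
                               process_noise = 0, obs_noise = 0) {
  stopifnot(rho > 0, rho <= 1)
  with_seed(seed, {
    O <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(O) < 0) O[, 1] <- -O[, 1]
    theta <- runif(1, 0.3, pi - 0.3)
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta),  cos(theta), 0),
               c(0, 0, 1))
    A <- (rho * runif(1, 0.7, 1)) * (O %*% R %*% t(O))
    C <- qr.Q(qr(matrix(rnorm(9), 3)))
    # deterministic column signs, same rule as the identification side
    for (j in 1:3) if (C[which.max(abs(C[, j])), j] < 0) C[, j] <- -C[, j]
    mu <- runif(3, 0.2, 0.8)
    structure(list(A_true = A, C_true = C, mean = mu,
                   state_scale = state_scale,
                   process_noise = process_noise, obs_noise = obs_noise,
                   seed = as.integer(seed)),
              class = "lds_system_spec")
  })
}

#' Ground-truth observability subspace of a system spec
#'
#' @param spec An `lds_system_spec`.
#' @param m Observability horizon (default 3).
#' @return A [grassmann_point()].
#' @export
system_subspace <- function(spec, m = 3L) {
  observability_subspace(list(A = spec$A_true, C = spec$C_true), m = m)
}

#' Generate one patch from a linear dynamical system
#'
#' Runs the state recurrence `x(i+1) = A x(i) + sigma_v v(i)` over pixels in
#' row-major scan order and emits `pixel(i) = mean + C x(i) + sigma_w w(i)`,
#' clipped to `[0, 1]`. The initial state is drawn as
#' `x(1) ~ N(0, state_scale^2 I)`; among up to 100 seeded draws the one with
#' the best-conditioned noiseless trajectory (largest `sigma_3/sigma_1` of
#' the state matrix, early-stopped at 0.12) is kept — a persistent-excitation
#' condition that makes the system identifiable from the single patch. The
#' noiseless signal is then rescaled (one constant for all states, which
#' preserves the recurrence exactly) when needed so it stays inside
#' `[0.02, 0.98]`; clipping therefore only acts on the added noise.
#'
#' @param spec An `lds_system_spec`.
#' @param size Patch side length (at least 4; default 8).
#' @param seed Integer seed (defaults to the spec's seed).
#' @return A `size x size x 3` array in `[0, 1]`.
#' @export
synth_patch <- function(spec, size = 8L, seed = spec$seed) {
  stopifnot(size >= 4L)
  A <- spec$A_true; C <- spec$C_true; mu <- spec$mean
  n <- as.integer(size)^2
  with_seed(seed, {
    x <- cpp_best_trajectory(A, n, spec$state_scale, 0.12, 100L)
    if (spec$process_noise > 0) {
      for (i in 2:n) x[, i] <- A %*% x[, i - 1] + spec$process_noise * rnorm(3)
    }
    V <- C %*% x
    s <- 1
    for (k in 1:3) {
      vmax <- max(abs(V[k, ]))
      lim <- min(mu[k] - 0.02, 0.98 - mu[k])
      if (vmax > lim && vmax > 0) s <- min(s, lim / vmax)
    }
    V <- V * s
    if (spec$obs_noise > 0) V <- V + spec$obs_noise * matrix(rnorm(3 * n), 3)
    P <- array(0, c(size, size, 3))
    for (k in 1:3) {
      P[, , k] <- matrix(pmin(pmax(mu[k] + V[k, ], 0), 1), size, size, byrow = TRUE)
    }
    P
  })
}

#' Synthetic dataset specification
#'
#' Study conditions for the synthetic benchmark: LDS-generated RGB textures
#' with known class-conditional dynamics, at configurable resolution, noise
#' level and class separation.
#'
#' @param n_classes Number of classes (default 3).
#' @param images_per_class Images per class (default 30).
#' @param image_size Square image side (default 128; must be divisible by
#'   `patch_size`).
#' @param patch_size Tile side used by the generator mosaic (default 8).
#' @param class_separation Minimal pairwise geodesic distance between class
#'   observability subspaces, enforced by seeded rejection (default 0.5).
#' @param patients_per_class Synthetic patients per class, assigned
#'   round-robin (default 5).
#' @param obs_noise Pixel noise sd added by the generator (default 0.02).
#' @param process_noise State noise sd (default 0).
#' @param rho Stability margin of the class systems (default 0.97).
#' @param seed Master seed.
#' @return An object of class `synth_dataset_spec`.
#' @export
synth_dataset_spec <- function(n_classes = 3L, images_per_class = 30L,
                               image_size = 128L, patch_size = 8L,
                               class_separation = 0.5, patients_per_class = 5L,
                               obs_noise = 0.02, process_noise = 0,
                               rho = 0.97, seed = 1L) {
  if (image_size %% patch_size != 0L) {
    abort_grassvlad("`image_size` must be divisible by `patch_size`",
                    "grassvlad_config_error")
  }
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 class_separation = class_separation,
                 patients_per_class = as.integer(patients_per_class),
                 obs_noise = obs_noise, process_noise = process_noise,
                 rho = rho, seed = as.integer(seed)),
            class = "synth_dataset_spec")
}

# draw class systems whose observability subspaces are pairwise at least
# `separation` apart (seeded rejection); records the achieved separation
draw_class_systems <- function(dspec) {
  seeds <- derive_seeds(dspec$seed, 10000L)
  systems <- list()
  si <- 1L
  while (length(systems) < dspec$n_classes) {
    if (si > length(seeds)) {
      abort_grassvlad("could not achieve requested class separation",
                      "grassvlad_config_error")
    }
    cand <- make_stable_system(seeds[si], rho = dspec$rho,
                               process_noise = dspec$process_noise,
                               obs_noise = dspec$obs_noise)
    si <- si + 1L
    Gc <- system_subspace(cand)
    ok <- all(vapply(systems, function(s) {
      grassmann_distance(system_subspace(s), Gc) >= dspec$class_separation
    }, logical(1)))
    if (ok) systems[[length(systems) + 1L]] <- cand
  }
  seps <- c()
  for (i in seq_along(systems)) for (j in seq_len(i - 1L)) {
    seps <- c(seps, grassmann_distance(system_subspace(systems[[i]]),
                                       system_subspace(systems[[j]])))
  }
  attr(systems, "achieved_separation") <- if (length(seps)) min(seps) else NA_real_
  systems
}

#' Generate one synthetic image as a mosaic of LDS tiles
#'
#' Tiles the image with independently seeded patches of the class system —
#' each tile gets a fresh initial state, making tiles i.i.d. realizations of
#' the class dynamics, which is the structure the per-patch pipeline assumes.
#'
#' @param class_spec An `lds_system_spec` for the image's class.
#' @param image_size,patch_size Mosaic geometry (size divisible by patch).
#' @param seed Integer seed.
#' @return An `image_size x image_size x 3` array in `[0, 1]`.
#' @export
synth_image <- function(class_spec, image_size = 128L, patch_size = 8L,
                        seed = 1L) {
  if (image_size %% patch_size != 0L) {
    abort_grassvlad("`image_size` must be divisible by `patch_size`",
                    "grassvlad_config_error")
  }
  ntile <- image_size %/% patch_size
  tile_seeds <- derive_seeds(seed, ntile * ntile)
  img <- array(0, c(image_size, image_size, 3))
  idx <- 1L
  for (tr in seq_len(ntile)) {
    for (tc in seq_len(ntile)) {
      P <- synth_patch(class_spec, size = patch_size, seed = tile_seeds[idx])
      rows <- (tr - 1L) * patch_size + seq_len(patch_size)
      cols <- (tc - 1L) * patch_size + seq_len(patch_size)
      img[rows, cols, ] <- P
      idx <- idx + 1L
    }
  }
  img
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_classes * images_per_class` PNG images plus a
#' `manifest.csv` (columns `path,label,patient_id,magnification`) and a
#' `ground_truth.json` sidecar holding the class systems and the achieved
#' class separation. The sidecar is stored separately from the manifest so
#' the pipeline cannot accidentally consume it. Fully reproducible from the
#' spec: a rerun writes byte-identical files.
#'
#' @param dspec A [synth_dataset_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
make_dataset <- function(dspec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  systems <- draw_class_systems(dspec)
  n_img <- dspec$n_classes * dspec$images_per_class
  img_seeds <- derive_seeds(dspec$seed + 1L, n_img)
  rows <- list()
  idx <- 1L
  for (cl in seq_len(dspec$n_classes)) {
    for (i in seq_len(dspec$images_per_class)) {
      img <- synth_image(systems[[cl]], dspec$image_size, dspec$patch_size,
                         seed = img_seeds[idx])
      fname <- sprintf("class%d_img%03d.png", cl, i)
      png::writePNG(img, file.path(out_dir, fname))
      patient <- ((i - 1L) %% dspec$patients_per_class) + 1L
      rows[[idx]] <- tibble::tibble(
        path = file.path(out_dir, fname),
        label = sprintf("class%d", cl),
        patient_id = sprintf("c%d_p%d", cl, patient),
        magnification = "x40")
      idx <- idx + 1L
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- list(
    achieved_separation = attr(systems, "achieved_separation"),
    spec = unclass(dspec),
    systems = lapply(systems, function(s) {
      list(A_true = s$A_true, C_true = s$C_true, mean = s$mean, seed = s$seed)
    }))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
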