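#' Patch sampling configuration
#'
#' Describes how an image is cut into square patches before dynamical
#' modeling: the patch side length, the sampling strategy, and (for the
#' overlapping strategy) the fraction of overlap between neighbouring
#' patches.
#'
#' @param size Patch side length in pixels (at least 4; identification of a
#'   3-state system needs more pixels than states).
#' @param strategy One of `"overlapping"` (regular grid with stride
#'   `round(size * (1 - overlap_fraction))`), `"non_overlapping"` (stride =
#'   `size`) or `"random"` (`n_random` origins drawn uniformly with
#'   replacement from the valid origin set).
#' @param overlap_fraction Fraction of overlap between neighbouring patches
#'   for the overlapping strategy, in `[0, 1)`. Default 0.5.
#' @param n_random Number of random patches for the random strategy
#'   (default 10000, the count used with 8-pixel patches on full-size
#'   histological images; scale down for small images).
#' @param seed Integer seed used by the random strategy.
#' @return An object of class `patch_config`.
#' @examples
#' cfg <- patch_config(size = 8, strategy = "overlapping", overlap_fraction = 0.5)
#' cfg$stride
#' @export
patch_config <- function(size = 8L,
                         strategy = c("overlapping", "non_overlapping", "random"),
                         overlap_fraction = 0.5,
                         n_random = 10000L,
                         seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot_scalar_number(size, "size")
  size <- as.integer(size)
  if (size < 4L) {
    abort_grassvlad("patch size must be >= 4 pixels", "grassvlad_config_error")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort_grassvlad("`overlap_fraction` must lie in [0, 1)", "grassvlad_config_error")
  }
  stride <- switch(strategy,
    overlapping = as.integer(round(size * (1 - overlap_fraction))),
    non_overlapping = size,
    random = size)
  if (stride < 1L) {
    abort_grassvlad("stride rounds to zero; decrease `overlap_fraction`",
                    "grassvlad_config_error")
  }
  structure(
    list(size = size, strategy = strategy, overlap_fraction = overlap_fraction,
         n_random = as.integer(n_random), seed = as.integer(seed),
         stride = stride),
    class = "patch_config")
}

# 0-based (row, col) origins of all patches fully inside an H x W image
patch_origins <- function(H, W, cfg) {
  size <- cfg$size
  if (H < size || W < size) {
    abort_grassvlad(
      sprintf("image (%d x %d) smaller than patch size %d", H, W, size),
      "grassvlad_dimension_error")
  }
  if (cfg$strategy == "random") {
    rows <- 0:(H - size)
    cols <- 0:(W - size)
    return(with_seed(cfg$seed, cbind(
      row = sample(rows, cfg$n_random, replace = TRUE),
      col = sample(cols, cfg$n_random, replace = TRUE))))
  }
  stride <- cfg$stride
  rows <- seq.int(0L, H - size, by = stride)
  cols <- seq.int(0L, W - size, by = stride)
  cbind(row = rep(rows, times = length(cols)),
        col = rep(cols, each = length(rows)))
}

#' Cut an image into square patch tensors
#'
#' Cuts an `H x W x 3` image (values in `[0, 1]`) into `size x size x 3`
#' patch tensors under the configured sampling strategy. Grid origins are
#' anchored at pixel (0, 0); trailing pixels that do not fit a full patch are
#' discarded. All returned patches have direction 0 (unrotated).
#'
#' @param image `H x W x 3` numeric array scaled to `[0, 1]`.
#' @param cfg A [patch_config()].
#' @return A tibble with one row per patch and columns `row`, `col` (0-based
#'   origin), `direction` (degrees clockwise, always 0 here) and `values`
#'   (list column of `size x size x 3` arrays).
#' @examples
#' img <- array(runif(16 * 16 * 3), c(16, 16, 3))
#' extract_patches(img, patch_config(8, "non_overlapping"))
#' @export
extract_patches <- function(image, cfg = patch_config()) {
  check_image(image)
  og <- patch_origins(dim(image)[1], dim(image)[2], cfg)
  size <- cfg$size
  vals <- lapply(seq_len(nrow(og)), function(i) {
    r <- og[i, 1]; c <- og[i, 2]
    image[(r + 1):(r + size), (c + 1):(c + size), , drop = FALSE]
  })
  tibble::tibble(row = as.integer(og[, 1]), col = as.integer(og[, 2]),
                 direction = 0L, values = vals)
}

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort_grassvlad("`image` must be an H x W x 3 array", "grassvlad_data_error")
  }
  rng <- range(image)
  if (!all(is.finite(rng)) || rng[1] < -1e-8 || rng[2] > 1 + 1e-8) {
    abort_grassvlad("image values must be finite and scaled to [0, 1]",
                    "grassvlad_data_error")
  }
  invisible(image)
}

# rotate an N x N (or N x M) matrix 90 degrees clockwise
rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Rotate a patch tensor clockwise
#'
#' @param values An `N x N x 3` array.
#' @param turns Number of 90-degree clockwise quarter turns (0-3).
#' @return The rotated array (rotation applied identically to all channels).
#' @export
rotate_patch <- function(values, turns = 1L) {
  turns <- as.integer(turns) %% 4L
  for (t in seq_len(turns)) {
    values <- array(apply(values, 3, rot90_cw), dim(values)[c(2, 1, 3)])
  }
  values
}

#' Four directional variants of a patch
#'
#' Returns the patch together with its 90, 180 and 270 degree clockwise
#' rotations, modeling the spatial signal's evolution towards the four
#' scan directions.
#'
#' @param values An `N x N x 3` array with direction 0.
#' @return A named list of four arrays (`"0"`, `"90"`, `"180"`, `"270"`).
#' @export
rotation_variants <- function(values) {
  out <- vector("list", 4L)
  names(out) <- c("0", "90", "180", "270")
  out[[1L]] <- values
  for (d in 2:4) out[[d]] <- rotate_patch(out[[d - 1L]], 1L)
  out
}

#' Test whether a patch carries identifiable dynamics
#'
#' A patch is degenerate when its per-channel-mean-subtracted tensor has
#' Frobenius norm below `eps * N`: a (near-)constant patch yields a rank-zero
#' observation matrix with no identifiable dynamics, and is excluded from the
#' downstream point cloud.
#'
#' @param values An `N x N x 3` array.
#' @param eps Positive tolerance (default `1e-8`).
#' @return `TRUE` if the patch is degenerate.
#' @export
is_degenerate <- function(values, eps = 1e-8) {
  stopifnot(eps > 0)
  N <- dim(values)[1]
  centered <- sweep(values, 3, apply(values, 3, mean))
  sqrt(sum(centered^2)) < eps * N
}
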