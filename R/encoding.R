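#' L2-normalize a vector
#'
#' Returns `v / ||v||_2`; a zero vector is returned unchanged with the
#' `is_zero` attribute set.
#'
#' @param v Numeric vector.
#' @return The normalized vector with attribute `is_zero`.
#' @export
l2_normalize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv > 0) structure(v / nv, is_zero = FALSE)
  else structure(v, is_zero = TRUE)
}

resolve_variant <- function(variant) {
  v <- match.arg(variant, c("scalar", "tangent", "scalar_as_printed", "tangent_vlad"))
  if (v %in% c("scalar", "scalar_as_printed")) "scalar" else "tangent"
}

#' Learn a Grassmannian codebook of Karcher means
#'
#' Pools training points, uniformly subsamples to at most `subsample_cap`
#' (seeded), initializes with [k_medoids()], replaces each medoid by the
#' Karcher mean of its cluster, then runs up to `refine_iters` rounds of
#' {reassign by geodesic distance, recompute Karcher means}, stopping early
#' when assignments are unchanged. An emptied cluster is re-seeded to the
#' point farthest from its nearest word. Deterministic given `seed`.
#'
#' @param points A `p x r x n` array, list of bases, or an embedded tibble
#'   from [embed_images()] (its `points` column is pooled).
#' @param k Number of visual words (default 16).
#' @param seed Integer seed.
#' @param subsample_cap Maximum number of points used for learning
#'   (default 3000; pairwise-distance cost grows quadratically).
#' @param refine_iters Reassignment/re-estimation rounds (default 10).
#' @param karcher_tol,karcher_max_iter Karcher mean controls.
#' @return An object of class `grassvlad_codebook`: list with `words`
#'   (`p x r x k` array), `k`, `seed` and `meta` (training counts and logs).
#' @export
learn_codebook <- function(points, k = 16L, seed = 1L, subsample_cap = 3000L,
                           refine_iters = 10L, karcher_tol = 1e-6,
                           karcher_max_iter = 100L) {
  if (is.data.frame(points)) points <- pool_points(points)
  pts <- as_cloud(points)
  n_total <- cloud_size(pts)
  if (n_total > subsample_cap) {
    idx <- sort(with_seed(seed, sample.int(n_total, subsample_cap)))
    pts <- pts[, , idx, drop = FALSE]
  }
  n <- cloud_size(pts)
  if (k > n) {
    abort_grassvlad(sprintf("k = %d exceeds available points (%d)", k, n),
                    "grassvlad_config_error")
  }
  D <- cloud_self_dist(pts)
  km <- k_medoids(pts, k, seed = seed, dist_matrix = D)
  words <- array(NA_real_, c(dim(pts)[1:2], k))
  for (j in seq_len(k)) {
    members <- which(km$assignment == j)
    if (length(members) == 0L) members <- km$medoids[j]
    words[, , j] <- karcher_mean(pts[, , members, drop = FALSE],
                                 init = pts[, , km$medoids[j]],
                                 tol = karcher_tol, max_iter = karcher_max_iter)
  }
  assign <- km$assignment
  log_lines <- character()
  n_rounds <- 0L
  for (it in seq_len(refine_iters)) {
    Dw <- cloud_cross_dist(words, pts)          # k x n
    Dw[!is.finite(Dw)] <- pi / 2 * sqrt(dim(pts)[2])
    new_assign <- max.col(-t(Dw), ties.method = "first")
    # re-seed emptied clusters to the point farthest from its nearest word
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(apply(Dw, 2, min))
        words[, , j] <- pts[, , far]
        new_assign[far] <- j
        log_lines <- c(log_lines,
                       sprintf("round %d: word %d re-seeded to point %d", it, j, far))
      }
    }
    n_rounds <- it
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      members <- which(assign == j)
      words[, , j] <- karcher_mean(pts[, , members, drop = FALSE],
                                   init = words[, , j],
                                   tol = karcher_tol, max_iter = karcher_max_iter)
    }
  }
  structure(list(words = words, k = as.integer(k), seed = as.integer(seed),
                 meta = list(n_points_pooled = n_total, n_points_used = n,
                             subsample_cap = as.integer(subsample_cap),
                             refine_rounds = n_rounds, log = log_lines)),
            class = "grassvlad_codebook")
}

#' @export
print.grassvlad_codebook <- function(x, ...) {
  cat(sprintf("<grassvlad_codebook> k = %d words on Gr(%d, %d); trained on %d/%d points\n",
              x$k, dim(x$words)[1], dim(x$words)[2],
              x$meta$n_points_used, x$meta$n_points_pooled))
  invisible(x)
}

#' Assign points to their nearest codebook word
#'
#' Argmin of geodesic distance over words; ties broken by the lowest word
#' index. Points whose distance to any word is undefined (cut locus) are
#' skipped and returned as `NA`.
#'
#' @param points A `p x r x n` array or list of bases.
#' @param codebook A `grassvlad_codebook`.
#' @return Integer vector of word indices (1-based; `NA` = skipped).
#' @export
assign_points <- function(points, codebook) {
  res <- cpp_vlad_raw(as_cloud(points), codebook$words, FALSE)
  a <- as.integer(res$assign)
  a[a < 0L] <- NA_integer_
  a + 1L
}

#' VLAD-encode one image's cloud of Grassmann points
#'
#' The scalar variant aggregates, per word, the Frobenius norms of the log
#' maps of the assigned points (their geodesic distances to the word),
#' giving a length-`k` vector; the tangent variant aggregates the log-map
#' matrices themselves (row-major flattened, blocks concatenated), giving a
#' length `k*p*r` vector. Either raw vector is then L2-normalized. An empty
#' cloud (or one whose aggregate is all zero) yields a zero code with the
#' `is_zero` flag set; empty clusters contribute zeros.
#'
#' @param points The image's `p x r x n` cloud (may be empty).
#' @param codebook A `grassvlad_codebook`.
#' @param variant `"scalar"` (default; the literal aggregation of tangent
#'   norms) or `"tangent"` (classical VLAD-style vector aggregation).
#' @return An object of class `vlad_code`: the normalized numeric vector
#'   with attributes `variant`, `is_zero` and `n_skipped`.
#' @export
encode_image <- function(points, codebook, variant = "scalar") {
  variant <- resolve_variant(variant)
  k <- codebook$k
  pdim <- dim(codebook$words)[1:2]
  if (is.null(points) || (is.array(points) && length(dim(points)) == 3L &&
                          dim(points)[3] == 0L)) {
    len <- if (variant == "scalar") k else k * prod(pdim)
    return(structure(rep(0, len), variant = variant, is_zero = TRUE,
                     n_skipped = 0L, class = "vlad_code"))
  }
  res <- cpp_vlad_raw(as_cloud(points), codebook$words, variant == "tangent")
  raw <- as.numeric(res$raw)
  # aggregate indistinguishable from zero at double precision (e.g. a cloud
  # sitting exactly on its words) is flagged rather than blown up by the norm
  if (sqrt(sum(raw^2)) < 1e-12) raw <- rep(0, length(raw))
  code <- l2_normalize(raw)
  structure(as.numeric(code), variant = variant,
            is_zero = attr(code, "is_zero"), n_skipped = res$n_skipped,
            class = "vlad_code")
}

# pool the `points` list-column of an embedded tibble into one cloud
pool_points <- function(embedded) {
  pts <- embedded$points
  pts <- pts[!vapply(pts, is.null, logical(1))]
  pts <- pts[vapply(pts, function(p) dim(p)[3] > 0L, logical(1))]
  if (length(pts) == 0L) {
    abort_grassvlad("no points to pool", "grassvlad_data_error")
  }
  d <- dim(pts[[1L]])[1:2]
  total <- sum(vapply(pts, function(p) dim(p)[3], integer(1)))
  out <- array(NA_real_, c(d, total))
  at <- 0L
  for (p in pts) {
    np <- dim(p)[3]
    out[, , at + seq_len(np)] <- p
    at <- at + np
  }
  out
}

#' Encode every image of an embedded dataset
#'
#' @param embedded A tibble from [embed_images()].
#' @param codebook A `grassvlad_codebook`.
#' @param variant See [encode_image()].
#' @return The input tibble with `points` replaced by a `code` list column
#'   plus `is_zero` and `n_skipped` columns.
#' @export
encode_images <- function(embedded, codebook, variant = "scalar") {
  codes <- lapply(embedded$points, encode_image, codebook = codebook,
                  variant = variant)
  out <- dplyr::select(embedded, -"points")
  out$code <- lapply(codes, as.numeric)
  out$is_zero <- vapply(codes, function(cd) isTRUE(attr(cd, "is_zero")), logical(1))
  out$n_skipped <- vapply(codes, function(cd) attr(cd, "n_skipped") %||% 0L, integer(1))
  out
}
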