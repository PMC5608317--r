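`%||%` <- function(x, y) if (is.null(x)) y else x

# run code under a local, seeded RNG state and restore it afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# derive n reproducible sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

abort_grassvlad <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "grassvlad_error"), ...)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_grassvlad(sprintf("`%s` must be a single finite number", name),
                    "grassvlad_config_error")
  }
}

# stack a list of p x r matrices into a p x r x n array
as_cloud <- function(points) {
  if (is.array(points) && length(dim(points)) == 3L) return(points)
  if (is.matrix(points)) return(array(points, c(dim(points), 1L)))
  if (is.list(points)) {
    if (length(points) == 0L) {
      abort_grassvlad("empty point list", "grassvlad_data_error")
    }
    d <- dim(points[[1L]])
    out <- array(NA_real_, c(d, length(points)))
    for (i in seq_along(points)) out[, , i] <- points[[i]]
    return(out)
  }
  abort_grassvlad("cannot interpret `points` as a cloud of subspace bases",
                  "grassvlad_data_error")
}

cloud_size <- function(points) dim(points)[3L]

md5_of_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}
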