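#' Higher-order SVD (Tucker decomposition) of a third-order tensor
#'
#' Factorizes an `N1 x N2 x 3` tensor `Y` as `core x1 U1 x2 U2 x3 U3` with
#' orthogonal factor matrices, where `U_j` holds the left singular vectors of
#' the mode-`j` unfolding of `Y` and the core is `Y` multiplied by the
#' transposed factors along each mode. The sign of every singular vector is
#' fixed so that its largest-magnitude entry is positive, which makes the
#' output deterministic; a zero tensor returns identity factors.
#'
#' Mode-3 unfolding columns are pixels in row-major scan order (left to right
#' within a row, rows top to bottom) — the convention that defines the
#' spatial evolution of the state sequence in [fit_hlds()].
#'
#' @param Y A numeric `N1 x N2 x K` array with finite entries.
#' @return An object of class `tucker_factors`: a list with `core` (array of
#'   the same shape as `Y`), `U1`, `U2`, `U3` (orthogonal matrices).
#' @examples
#' Y <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
#' f <- hosvd(Y)
#' max(abs(crossprod(f$U1) - diag(8)))
#' @export
hosvd <- function(Y) {
  if (!is.array(Y) || length(dim(Y)) != 3L) {
    abort_grassvlad("`Y` must be a third-order array", "grassvlad_data_error")
  }
  if (!all(is.finite(Y))) {
    abort_grassvlad("`Y` contains non-finite values", "grassvlad_numeric_error")
  }
  out <- cpp_hosvd(Y)
  out$core <- array(out$core, dim(Y))
  structure(out, class = "tucker_factors")
}

#' Reconstruct a tensor from its Tucker factors
#'
#' @param factors A `tucker_factors` object from [hosvd()].
#' @return The reconstructed array `core x1 U1 x2 U2 x3 U3`.
#' @export
tucker_reconstruct <- function(factors) {
  stopifnot(inherits(factors, "tucker_factors"))
  array(cpp_tucker_reconstruct(factors$core, factors$U1, factors$U2, factors$U3),
        dim(factors$core))
}
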