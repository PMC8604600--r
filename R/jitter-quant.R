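#' Build a jitter quantization matrix
#'
#' Combines a positive base quantization matrix `M^q` with a keyed
#' \eqn{\pm 1} dither matrix `M^d` scaled by the jitter factor
#' \eqn{\beta}: \eqn{Q^d = M^q (1 + \beta M^d)} elementwise. Because
#' \eqn{\beta < 1}, every step stays strictly positive; entries lie in
#' `[base * (1 - beta), base * (1 + beta)]`. With `beta = 0` the
#' mechanism reduces to plain uniform quantization by the base matrix.
#'
#' @param base Positive numeric matrix of quantization steps.
#' @param dither Integer matrix of the same shape with entries in
#'   \{-1, +1\} (see [sequence_to_dither()]).
#' @param beta Jitter factor in `[0, 1)`.
#' @return Object of class `jitter_quant_matrix` with fields `base`,
#'   `dither`, `beta` and the resulting step matrix `q_matrix`.
#' @export
build_jitter_quant_matrix <- function(base, dither, beta) {
  if (!identical(dim(base), dim(dither))) stop("base and dither shapes differ")
  if (!(beta >= 0 && beta < 1)) stop("beta must lie in [0, 1): beta >= 1 would create non-positive steps")
  if (any(base <= 0)) stop("base quantization steps must be strictly positive")
  if (!all(dither == 1L | dither == -1L)) stop("dither entries must be -1 or +1")
  q <- base * (1 + beta * dither)
  structure(
    list(base = base, dither = dither, beta = beta, q_matrix = q),
    class = "jitter_quant_matrix"
  )
}

# round half away from zero, so the quantization error bound is symmetric
# and does not depend on the platform's banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Dither-quantize a coefficient matrix
#'
#' Snaps each coefficient to the nearest integer multiple of its (keyed)
#' quantization step: `E0 = round(L / Q^d) * Q^d`, rounding ties half
#' away from zero. The operation is idempotent and its error is bounded
#' by half a step: `|L - E0| <= Q^d / 2` elementwise.
#'
#' @param coeffs Real matrix of wavelet coefficients, same shape as the
#'   quantizer.
#' @param qm A `jitter_quant_matrix`.
#' @return Quantized matrix of the same shape.
#' @export
dither_quantize <- function(coeffs, qm) {
  stopifnot(inherits(qm, "jitter_quant_matrix"))
  if (!identical(dim(coeffs), dim(qm$q_matrix))) stop("coefficient and quantizer shapes differ")
  round_half_away(coeffs / qm$q_matrix) * qm$q_matrix
}

# keyed quantizer for an arbitrary shape: constant base step delta, dither
# matrix drawn from the key's logistic orbit
keyed_quant_matrix <- function(key, rows, cols) {
  orbit <- logistic_iterate(key$lambda, key$x0, n = rows * cols,
                            burn_in = key$burn_in)
  dm <- sequence_to_dither(orbit, rows, cols)
  build_jitter_quant_matrix(matrix(key$delta, rows, cols), dm, key$beta)
}
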