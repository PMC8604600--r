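#' Radial lens distortion model
#'
#' A single-coefficient radial model in pixel coordinates: with
#' \eqn{r = \sqrt{(x_\mu - x_c)^2 + (y_\mu - y_c)^2}} the distortion
#' factor is \eqn{T(r) = 1 + k_1 r^2}, and an ideal point maps to
#' \eqn{x_d = x_c + (x_\mu - x_c) T(r)} (likewise for y). `T(0) = 1` by
#' construction, so the distortion center is a fixed point, and
#' `k1 = 0` gives the identity mapping. The model is radially
#' symmetric: rotating the ideal point about the center rotates the
#' distorted point identically.
#'
#' @param center Numeric length-2 vector `(x_c, y_c)` in pixels.
#' @param k1 Radial distortion coefficient (per squared pixel radius).
#' @return Object of class `distortion_model`.
#' @export
distortion_model <- function(center = c(0, 0), k1 = 0) {
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(k1), length(k1) == 1L, is.finite(k1))
  structure(list(center = as.numeric(center), k1 = as.numeric(k1)),
            class = "distortion_model")
}

#' @rdname distortion_model
#' @param p Ideal point `(x, y)` (numeric length-2, or an n x 2 matrix
#'   of points).
#' @param model A `distortion_model`.
#' @return `distort_point` returns the distorted point(s) in the same
#'   shape as `p`.
#' @examples
#' m <- distortion_model(center = c(0, 0), k1 = 0.5)
#' distort_point(c(1, 0), m)  # (1.5, 0): T(1) = 1.5
#' @export
distort_point <- function(p, model) {
  stopifnot(inherits(model, "distortion_model"))
  vec <- !is.matrix(p)
  if (vec) p <- matrix(p, ncol = 2L)
  if (!all(is.finite(p))) stop("coordinates must be finite")
  dx <- p[, 1L] - model$center[1L]
  dy <- p[, 2L] - model$center[2L]
  tr <- 1 + model$k1 * (dx^2 + dy^2)
  out <- cbind(model$center[1L] + dx * tr, model$center[2L] + dy * tr)
  if (vec) as.numeric(out) else out
}

# two's-complement 64-bit fixed-point encoding of k1 at scale 2^-32,
# as a bit vector (MSB first); exact for |k1 * 2^32| < 2^53
encode_k1_bits <- function(k1) {
  v <- round(k1 * 2^32)
  if (abs(v) >= 2^53) stop("k1 too large for exact fixed-point encoding")
  neg <- v < 0
  v <- abs(v)
  bits <- integer(64L)
  for (i in 64:1) {
    bits[i] <- v %% 2
    v <- v %/% 2
  }
  if (neg) {
    # two's complement: invert then add one, LSB first
    bits <- 1L - bits
    carry <- 1L
    for (i in 64:1) {
      s <- bits[i] + carry
      bits[i] <- s %% 2L
      carry <- s %/% 2L
      if (carry == 0L) break
    }
  }
  as.integer(bits)
}

#' Derive the optical key
#'
#' Binds a base bit key to the optical characteristics of the imaging
#' system: the radial distortion coefficient `k1` is encoded as 64-bit
#' fixed point (scale \eqn{2^{-32}}, two's complement), repeated or
#' truncated to the base key length, and XORed with the base key. XOR
#' makes the derivation an involution (deriving twice restores the
#' base), and the key depends only on `(base, k1)` — never on pixel
#' data — so ordinary image signal processing cannot change it, while a
#' change in the optical parameter flips key bits.
#'
#' @param base Non-empty 0/1 integer vector (the base key bits).
#' @param model A `distortion_model` carrying `k1`.
#' @return List of class `optical_key` with `base_key`, `k1_code` (the
#'   64 encoding bits) and `derived` (same length as `base`).
#' @export
derive_optical_key <- function(base, model) {
  stopifnot(inherits(model, "distortion_model"))
  base <- as.integer(base)
  if (length(base) == 0L) stop("base key must be non-empty")
  if (!all(base %in% c(0L, 1L))) stop("base key bits must be 0 or 1")
  code <- encode_k1_bits(model$k1)
  pad <- rep_len(code, length(base))
  structure(
    list(base_key = base, k1_code = code, derived = xor_bits(base, pad)),
    class = "optical_key"
  )
}

xor_bits <- function(a, b) as.integer(a != b)
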