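#' Content-level feature
#'
#' The lowest-frequency carrier of image content is the level-2
#' approximation subband `LL2`; dither-quantizing it with the keyed
#' jitter quantizer gives the content-level feature matrix. Every entry
#' of the result is an integer multiple of its quantization step.
#'
#' @param LL2 Level-2 approximation matrix.
#' @param qm A `jitter_quant_matrix` of matching shape.
#' @return Quantized content feature matrix.
#' @export
content_feature <- function(LL2, qm) {
  dither_quantize(LL2, qm)
}

#' Per-level subband energy features
#'
#' High-frequency wavelet coefficients shrink toward zero and become
#' noise-sensitive, so instead of using them directly each detail
#' subband is dither-quantized and the per-position energy (sum of
#' squares over the three orientations) is taken as the feature:
#' `E2 = HL2^2 + LH2^2 + HH2^2` (the robust level) and `E1` analogously
#' from the level-1 subbands (the detailed level). Energies are
#' invariant to coefficient sign flips and always non-negative.
#'
#' @param s A `subband_set` from [decompose()].
#' @param qm2 Jitter quantizer shaped like the level-2 subbands.
#' @param qm1 Jitter quantizer shaped like the level-1 subbands.
#' @return List with matrices `e1` and `e2`.
#' @export
energy_features <- function(s, qm2, qm1) {
  stopifnot(inherits(s, "subband_set"))
  q2 <- lapply(s[c("HL2", "LH2", "HH2")], dither_quantize, qm = qm2)
  q1 <- lapply(s[c("HL1", "LH1", "HH1")], dither_quantize, qm = qm1)
  list(
    e2 = q2$HL2^2 + q2$LH2^2 + q2$HH2^2,
    e1 = q1$HL1^2 + q1$LH1^2 + q1$HH1^2
  )
}

#' Robust order statistics: median, p-quantile, trimean, quartile spread
#'
#' These statistics summarize a feature matrix robustly. `p_quantile`
#' follows the averaging (type-2) rule on sorted values
#' \eqn{x_{(1)} \le \dots \le x_{(n)}}: if \eqn{np} is not an integer
#' the result is \eqn{x_{(\lfloor np \rfloor + 1)}}; if \eqn{np} is an
#' integer it is \eqn{(x_{(np)} + x_{(np+1)})/2}. The median is the
#' `p = 0.5` case. The trimean weights the quartiles and median
#' \eqn{\hat M = \tfrac14 M_{0.25} + \tfrac12 M + \tfrac14 M_{0.75}},
#' trading a little efficiency for strong outlier resistance.
#' `quartile_sd` is the interquartile range divided by 1.349, which
#' makes it a consistent estimate of the standard deviation under
#' normality.
#'
#' @param values Non-empty numeric vector (matrices are flattened).
#' @param p Quantile level in `[0, 1]`.
#' @return A single numeric value.
#' @examples
#' robust_median(c(1, 2, 3, 4))      # 2.5
#' p_quantile(c(1, 2, 3, 4), 0.25)   # 1.5
#' trimean(1:7)                      # 4
#' @export
p_quantile <- function(values, p) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("values must be non-empty")
  if (!(p >= 0 && p <= 1)) stop("p must lie in [0, 1]")
  x <- sort(values)
  np <- n * p
  if (np < 1) return(x[1L])
  if (np > n - 1) {
    # np = n (p = 1) has no upper neighbour to average with
    if (abs(np - n) < 1e-9) return(x[n])
  }
  if (abs(np - round(np)) < 1e-9) {
    k <- as.integer(round(np))
    (x[k] + x[k + 1L]) / 2
  } else {
    x[floor(np) + 1L]
  }
}

#' @rdname p_quantile
#' @export
robust_median <- function(values) {
  p_quantile(values, 0.5)
}

#' @rdname p_quantile
#' @export
trimean <- function(values) {
  if (length(values) < 4L) stop("trimean needs at least 4 values")
  0.25 * p_quantile(values, 0.25) +
    0.5 * robust_median(values) +
    0.25 * p_quantile(values, 0.75)
}

#' @rdname p_quantile
#' @export
quartile_sd <- function(values) {
  if (length(values) < 4L) stop("quartile_sd needs at least 4 values")
  (p_quantile(values, 0.75) - p_quantile(values, 0.25)) / 1.349
}

#' Binarize a feature matrix against its trimean
#'
#' A cell becomes 1 when it strictly exceeds the trimean of the whole
#' matrix, else 0. The strict inequality makes constant matrices map to
#' all zeros deterministically.
#'
#' @param feature Numeric matrix.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize_feature <- function(feature) {
  thr <- trimean(as.numeric(feature))
  out <- matrix(as.integer(feature > thr), nrow(feature), ncol(feature))
  out
}

#' Full feature stack for one image
#'
#' Runs the whole feature front end: canonical preprocessing, two-level
#' Haar decomposition, keyed dither quantization of `LL2` (content
#' level) and of the detail subbands (energy levels `E2`, `E1`). The
#' quartile spread of each feature is recorded as diagnostic metadata;
#' it does not enter the hash bits.
#'
#' @param image Anything [preprocess_image()] accepts.
#' @param key A `chaos_key`.
#' @return Object of class `feature_stack` with `content`, `e2`, `e1`
#'   matrices and a `quartile_sd` vector.
#' @export
feature_stack <- function(image, key) {
  img <- preprocess_image(image)
  s <- decompose(img)
  n2 <- nrow(s$LL2)
  n1 <- nrow(s$HL1)
  qm2 <- keyed_quant_matrix(key, n2, n2)
  qm1 <- keyed_quant_matrix(key, n1, n1)
  en <- energy_features(s, qm2, qm1)
  fs <- list(
    content = content_feature(s$LL2, qm2),
    e2 = en$e2,
    e1 = en$e1
  )
  fs$quartile_sd <- vapply(fs[c("content", "e2", "e1")],
                           function(m) quartile_sd(as.numeric(m)), numeric(1))
  structure(fs, class = "feature_stack")
}
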