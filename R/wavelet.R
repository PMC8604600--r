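#' Read and canonicalize an image
#'
#' All hashing operates on a canonical raster: grayscale, 512 x 512,
#' double precision in `[0, 255]`. RGB input is converted to luminance
#' with the Rec. 601 weights (0.299, 0.587, 0.114) and any other size is
#' bilinearly resized. PNG, TIFF and JPEG are decoded through EBImage;
#' 8-bit and 16-bit grayscale are both accepted.
#'
#' @param image Path to a PNG/TIFF/JPEG file, an `EBImage::Image`, or a
#'   numeric matrix already holding gray values.
#' @param size Canonical side length (default 512).
#' @return `size` x `size` numeric matrix in `[0, 255]`.
#' @export
preprocess_image <- function(image, size = 512L) {
  if (is.character(image)) image <- EBImage::readImage(image)
  if (inherits(image, "Image")) {
    dat <- EBImage::imageData(image)
    if (length(dim(dat)) == 3L) {
      nch <- dim(dat)[3L]
      dat <- if (nch >= 3L) {
        0.299 * dat[, , 1L] + 0.587 * dat[, , 2L] + 0.114 * dat[, , 3L]
      } else {
        dat[, , 1L]
      }
    }
    image <- dat * 255
  }
  if (!is.matrix(image)) stop("image must be a file path, Image, or matrix")
  m <- image
  if (nrow(m) != size || ncol(m) != size) {
    m <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size, h = size))
  }
  storage.mode(m) <- "double"
  pmin(pmax(m, 0), 255)
}

# one level of the separable orthonormal Haar transform along rows:
# pairs (a, b) -> ((a+b)/sqrt(2), (a-b)/sqrt(2))
haar_step_rows <- function(m) {
  n <- nrow(m)
  odd <- m[seq(1L, n, by = 2L), , drop = FALSE]
  even <- m[seq(2L, n, by = 2L), , drop = FALSE]
  rbind((odd + even) / sqrt(2), (odd - even) / sqrt(2))
}

haar_unstep_rows <- function(m) {
  n <- nrow(m)
  lo <- m[seq_len(n / 2L), , drop = FALSE]
  hi <- m[(n / 2L + 1L):n, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  out[seq(1L, n, by = 2L), ] <- (lo + hi) / sqrt(2)
  out[seq(2L, n, by = 2L), ] <- (lo - hi) / sqrt(2)
  out
}

haar_dwt2_level <- function(m) {
  t1 <- t(haar_step_rows(t(haar_step_rows(m))))
  h <- nrow(m) / 2L
  w <- ncol(m) / 2L
  list(
    LL = t1[seq_len(h), seq_len(w), drop = FALSE],
    HL = t1[(h + 1L):(2L * h), seq_len(w), drop = FALSE],
    LH = t1[seq_len(h), (w + 1L):(2L * w), drop = FALSE],
    HH = t1[(h + 1L):(2L * h), (w + 1L):(2L * w), drop = FALSE]
  )
}

haar_idwt2_level <- function(LL, HL, LH, HH) {
  m <- rbind(cbind(LL, LH), cbind(HL, HH))
  t(haar_unstep_rows(t(haar_unstep_rows(m))))
}

#' Two-level Haar wavelet decomposition
#'
#' Decomposes the canonical image into the level-2 approximation `LL2`
#' (the low-frequency content carrier), the level-2 detail subbands
#' `HL2`, `LH2`, `HH2`, and the level-1 detail subbands `HL1`, `LH1`,
#' `HH1`. The Haar basis is orthonormal, so decomposition followed by
#' [reconstruct()] returns the input to machine precision, and all
#' subband shapes halve dyadically (512 input gives 256 level-1 and 128
#' level-2 subbands).
#'
#' @param image Canonical square grayscale matrix with dyadic side
#'   length divisible by 4 (normally the 512 x 512 output of
#'   [preprocess_image()]).
#' @return Object of class `subband_set` with the seven subband matrices.
#' @export
decompose <- function(image) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop("decompose() expects a square matrix (canonical preprocessed image)")
  }
  if (nrow(image) %% 4L != 0L) stop("side length must be divisible by 4 for two dyadic levels")
  l1 <- haar_dwt2_level(image)
  l2 <- haar_dwt2_level(l1$LL)
  structure(
    list(LL2 = l2$LL, HL2 = l2$HL, LH2 = l2$LH, HH2 = l2$HH,
         HL1 = l1$HL, LH1 = l1$LH, HH1 = l1$HH),
    class = "subband_set"
  )
}

#' @rdname decompose
#' @param s A `subband_set`.
#' @export
reconstruct <- function(s) {
  stopifnot(inherits(s, "subband_set"))
  LL1 <- haar_idwt2_level(s$LL2, s$HL2, s$LH2, s$HH2)
  haar_idwt2_level(LL1, s$HL1, s$LH1, s$HH1)
}
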