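#' Iterate the logistic map
#'
#' The logistic recurrence \eqn{x_{k+1} = \lambda x_k (1 - x_k)} is the
#' keyed pseudorandom source for the whole pipeline: dither matrices, bit
#' scrambling permutations and passphrase key derivation all consume its
#' orbit. For \eqn{0 < \lambda \le 4} and \eqn{x_0 \in (0, 1)} the orbit
#' stays in \eqn{[0, 1]}; near \eqn{\lambda = 4} it is chaotic.
#'
#' @param lam Map parameter \eqn{\lambda}, in \eqn{(0, 4]}.
#' @param x0 Initial value (the key), strictly inside \eqn{(0, 1)}.
#' @param n Number of orbit values to return.
#' @param burn_in Number of leading iterates to discard before collecting
#'   (default 100, enough to escape transients).
#' @return Numeric vector of `n` orbit values, all in \eqn{[0, 1]}.
#' @examples
#' logistic_iterate(4, 0.3, n = 1)   # 4 * 0.3 * 0.7 = 0.84
#' logistic_iterate(3.9, 0.123456, n = 5)
#' @export
logistic_iterate <- function(lam, x0, n, burn_in = 100L) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.numeric(x0), length(x0) == 1L)
  if (!(x0 > 0 && x0 < 1)) stop("x0 must lie strictly inside (0, 1)")
  if (!(lam > 0 && lam <= 4)) stop("lambda must lie in (0, 4]")
  if (burn_in < 0) stop("burn_in must be non-negative")
  if (n < 1) stop("n must be at least 1")
  total <- burn_in + n
  x <- x0
  out <- numeric(n)
  for (k in seq_len(total)) {
    x <- lam * x * (1 - x)
    if (k > burn_in) out[k - burn_in] <- x
  }
  out
}

#' Convert a chaotic sequence to a +/-1 dither matrix
#'
#' Thresholds the sequence at 0.5 (values >= 0.5 map to +1, below to -1)
#' and fills an integer matrix row-major. The result perturbs the base
#' quantization matrix in [build_jitter_quant_matrix()].
#'
#' @param seq Numeric vector, typically a logistic orbit; must supply at
#'   least `rows * cols` values.
#' @param rows,cols Target matrix shape.
#' @return Integer matrix with entries in \{-1, +1\}.
#' @export
sequence_to_dither <- function(seq, rows, cols) {
  if (length(seq) < rows * cols) {
    stop("sequence too short: need ", rows * cols, " values, got ", length(seq))
  }
  vals <- ifelse(seq[seq_len(rows * cols)] >= 0.5, 1L, -1L)
  matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Derive scrambling keys from a text passphrase
#'
#' Maps a passphrase to the chaotic key material: ASCII codes are averaged
#' and scaled into an initial value `x0` of the logistic map; after
#' `n_iter` iterations two successive orbit values are linearly expanded,
#' reduced modulo `N - 1` and shifted to give the cat-map integers
#' `a`, `b` in `[1, N - 1]`. Deterministic: the same passphrase always
#' yields the same key.
#'
#' The derivation uses \eqn{\lambda = 3.99} so the orbit never collapses
#' onto the fixed point at 0 (which \eqn{\lambda = 4} reaches from
#' \eqn{x_0 = 0.5}, e.g. for the passphrase `"@"`).
#'
#' @param passphrase Non-empty printable-ASCII string.
#' @param n_iter Iterations of the map before key material is read off
#'   (default 50, minimum 10).
#' @param N Side length of the square matrix the keys will scramble.
#' @return List with `x0` (the seed), and integers `a`, `b` in `[1, N-1]`.
#' @export
passphrase_to_key <- function(passphrase, n_iter = 50L, N = 128L) {
  if (!is.character(passphrase) || length(passphrase) != 1L || !nzchar(passphrase)) {
    stop("passphrase must be a single non-empty string")
  }
  codes <- utf8ToInt(passphrase)
  if (any(codes < 32L | codes > 126L)) stop("passphrase must be printable ASCII")
  if (n_iter < 10L) stop("n_iter must be at least 10")
  if (N < 2L) stop("N must be at least 2")
  x0 <- mean(codes) / 128
  orbit <- logistic_iterate(3.99, x0, n = 2L, burn_in = as.integer(n_iter))
  expand <- function(x) 1L + as.integer(floor(x * 1e6) %% (N - 1L))
  list(x0 = x0, a = expand(orbit[1L]), b = expand(orbit[2L]))
}

cat_map_matrix <- function(a, b) {
  matrix(c(1, a, b, a * b + 1), nrow = 2L, byrow = TRUE)
}

#' Scramble a square matrix with the Arnold cat map
#'
#' Moves the element at 0-based position `(i, j)` to
#' `((i + a j) mod N, (b i + (a b + 1) j) mod N)`, `iterations` times.
#' The map matrix has determinant 1, so this is a bijection on the index
#' grid: the output is an exact permutation of the input entries, and
#' `cat_map_permute(..., inverse = TRUE)` undoes it exactly.
#'
#' @param m Square numeric/integer matrix of side `N`.
#' @param a,b Positive integers below `N` (the scrambling key).
#' @param iterations Number of applications of the map, `>= 1`.
#' @param inverse If `TRUE`, apply the inverse permutation instead.
#' @return Matrix of the same shape with the entries permuted.
#' @examples
#' m <- matrix(1:16, 4, 4)
#' s <- cat_map_permute(m, a = 1, b = 1, iterations = 2)
#' identical(cat_map_permute(s, 1, 1, 2, inverse = TRUE), m)
#' @export
cat_map_permute <- function(m, a, b, iterations = 1L, inverse = FALSE) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  N <- nrow(m)
  if (a <= 0 || b <= 0 || a >= N || b >= N) stop("need 0 < a < N and 0 < b < N")
  if (iterations < 1L) stop("iterations must be at least 1")
  ij <- cbind(
    i = rep(0:(N - 1L), times = N),
    j = rep(0:(N - 1L), each = N)
  )
  A <- if (inverse) {
    # inverse of [[1, a], [b, ab+1]] mod N (det = 1): [[ab+1, -a], [-b, 1]]
    matrix(c(a * b + 1, -a, -b, 1), nrow = 2L, byrow = TRUE)
  } else {
    cat_map_matrix(a, b)
  }
  dest <- ij
  for (k in seq_len(iterations)) {
    dest <- cbind(
      (A[1L, 1L] * dest[, 1L] + A[1L, 2L] * dest[, 2L]) %% N,
      (A[2L, 1L] * dest[, 1L] + A[2L, 2L] * dest[, 2L]) %% N
    )
  }
  out <- m
  out[dest[, 1L] + 1L + N * dest[, 2L]] <- m[ij[, 1L] + 1L + N * ij[, 2L]]
  out
}

#' Size of the scrambling key space
#'
#' With both cat-map integers drawn from `[1, N-1]` and `q` successive
#' mappings, the key space has \eqn{K = (N-1)^{2q}} elements. Returned as
#' a double; exact as long as it does not exceed 2^53.
#'
#' @param N Side length of the scrambled matrix, `>= 2`.
#' @param q Number of mappings, `>= 1`.
#' @return The key-space size as a numeric scalar.
#' @export
key_space_size <- function(N, q) {
  if (N < 2) stop("N must be at least 2")
  if (q < 1) stop("q must be at least 1")
  (N - 1)^(2 * q)
}

#' Assemble the full chaotic key for hashing
#'
#' Bundles everything the hashing pipeline needs: the logistic parameters
#' seeded from the passphrase, the cat-map integers for each feature-level
#' side length, and the quantizer configuration. The `params_digest` field
#' is a short MD5 digest of all parameters; two hashes are only comparable
#' when their digests match.
#'
#' @param passphrase Non-empty printable-ASCII string.
#' @param lambda Logistic parameter used for dither/scramble orbits.
#' @param q Cat-map iteration count (default 3).
#' @param beta Jitter factor in `[0, 1)`.
#' @param delta Base quantization step, `> 0`.
#' @param burn_in Orbit burn-in.
#' @return Object of class `chaos_key`.
#' @export
chaos_key <- function(passphrase, lambda = 3.99, q = 3L, beta = 0.1,
                      delta = 20, burn_in = 100L) {
  pk <- passphrase_to_key(passphrase)
  if (!(beta >= 0 && beta < 1)) stop("beta must lie in [0, 1)")
  if (delta <= 0) stop("delta must be positive")
  if (q < 1L) stop("q must be at least 1")
  key <- list(
    passphrase_digest = digest::digest(passphrase, algo = "md5", serialize = FALSE),
    lambda = lambda, x0 = pk$x0, q = as.integer(q),
    beta = beta, delta = delta, burn_in = as.integer(burn_in)
  )
  key$params_digest <- substr(digest::digest(
    paste(
      key$passphrase_digest,
      formatC(c(lambda, pk$x0, beta, delta), digits = 17, format = "g"),
      q, burn_in,
      collapse = "|"
    ),
    algo = "md5", serialize = FALSE
  ), 1L, 16L)
  structure(key, class = "chaos_key")
}

# cat-map integers for a given side length, derived from the key's orbit
key_ab_for_N <- function(key, N) {
  orbit <- logistic_iterate(3.99, key$x0, n = 2L, burn_in = 50L)
  expand <- function(x) 1L + as.integer(floor(x * 1e6) %% (N - 1L))
  list(a = expand(orbit[1L]), b = expand(orbit[2L]))
}

#' @export
print.chaos_key <- function(x, ...) {
  cat("<chaos_key>\n")
  cat("  lambda:", x$lambda, " x0:", format(x$x0, digits = 6),
      " q:", x$q, "\n")
  cat("  beta:", x$beta, " delta:", x$delta, " burn_in:", x$burn_in, "\n")
  cat("  params_digest:", x$params_digest, "\n")
  invisible(x)
}

#' Serialize / deserialize key material as JSON
#'
#' The passphrase itself is never stored, only its digest; the JSON holds
#' the derived parameters needed to audit (not reproduce) a key. This is
#' chaotic, not cryptographic, key material: it offers keyed determinism
#' and a large combinatorial key space, not cryptographic-strength
#' secrecy.
#'
#' @param key A `chaos_key`.
#' @param path File to write / read.
#' @param N Side length used to report the cat-map integers.
#' @return `write_key_json` returns `path` invisibly; `read_key_json`
#'   returns the parsed list.
#' @export
write_key_json <- function(key, path, N = 128L) {
  ab <- key_ab_for_N(key, N)
  doc <- list(
    passphrase_digest = key$passphrase_digest,
    lambda = key$lambda, x0 = key$x0,
    a = ab$a, b = ab$b, q = key$q, N = as.integer(N),
    burn_in = key$burn_in,
    beta = key$beta, delta = key$delta,
    params_digest = key$params_digest
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_key_json
#' @export
read_key_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
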