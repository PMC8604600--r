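#' Block-majority level hash (scheme 2)
#'
#' Compresses one binarized feature matrix to 40 bits by partitioning it
#' into 40 near-equal rectangular blocks (a 5-row by 8-column grid) and
#' emitting, per block, 0 when zeros are at least as frequent as ones
#' (`N0 >= N1`) and 1 otherwise. When the matrix tiles exactly into
#' forty 20 x 20 blocks, that tiling is used instead of the grid.
#' Blocks are read row-major, so the bit order is deterministic.
#'
#' @param bitmat 0/1 integer matrix, at least 5 x 8.
#' @return Integer vector of 40 bits.
#' @export
scheme2_level_hash <- function(bitmat) {
  if (!is.matrix(bitmat)) stop("bitmat must be a matrix")
  if (!all(bitmat %in% c(0L, 1L))) stop("bitmat entries must be 0 or 1")
  nr <- nrow(bitmat)
  nc <- ncol(bitmat)
  if (nr %% 20L == 0L && nc %% 20L == 0L && (nr / 20L) * (nc / 20L) == 40L) {
    brows <- nr / 20L
    bcols <- nc / 20L
  } else {
    brows <- 5L
    bcols <- 8L
  }
  if (nr < brows || nc < bcols) stop("matrix smaller than the block grid")
  rb <- floor(seq(0L, nr, length.out = brows + 1L))
  cb <- floor(seq(0L, nc, length.out = bcols + 1L))
  bits <- integer(brows * bcols)
  k <- 0L
  for (i in seq_len(brows)) {
    for (j in seq_len(bcols)) {
      block <- bitmat[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      n1 <- sum(block)
      n0 <- length(block) - n1
      k <- k + 1L
      bits[k] <- if (n0 >= n1) 0L else 1L
    }
  }
  bits
}

# canonical serialization: row-major, fixed 6-decimal formatting, with
# negative zero normalized so the digest is platform-stable
canonical_serialize <- function(feature) {
  v <- round(as.numeric(t(feature)), 6)
  v[v == 0] <- 0
  paste(sprintf("%.6f", v), collapse = ",")
}

hex_to_bits <- function(hex, nbits) {
  nib <- strtoi(strsplit(hex, "")[[1L]], base = 16L)
  bits <- unlist(lapply(nib, function(x) as.integer(intToBits(x)[4:1])))
  bits[seq_len(nbits)]
}

#' MD5-based level hash (scheme 1)
#'
#' The "robust feature plus exact hash" route: the feature matrix is
#' serialized canonically (row-major, fixed 6-decimal formatting), the
#' 128-bit MD5 digest is computed, and the first 40 digest bits become
#' the level hash. Any change that survives quantization flips about
#' half the bits (avalanche), which is what makes this scheme fragile to
#' content changes while the robust feature absorbs benign processing.
#'
#' @param feature Numeric matrix (in the pipeline, a scrambled binarized
#'   feature).
#' @param nbits Number of leading digest bits to keep (default 40).
#' @return Integer vector of `nbits` bits.
#' @export
scheme1_level_hash <- function(feature, nbits = 40L) {
  hex <- digest::digest(canonical_serialize(feature), algo = "md5",
                        serialize = FALSE)
  hex_to_bits(hex, nbits)
}

# key-seeded permutation of 1..n: indices drawn from the logistic orbit
# (duplicates skipped); `offset` lets each level consume a different
# stretch of the orbit
key_permutation <- function(key, n, offset = 0L) {
  draw <- logistic_iterate(key$lambda, key$x0, n = 200L * n,
                           burn_in = key$burn_in + offset)
  idx <- floor(draw * n) + 1L
  idx[idx > n] <- n
  perm <- unique(idx)
  if (length(perm) < n) perm <- c(perm, setdiff(seq_len(n), perm))
  perm[seq_len(n)]
}

#' Scramble and assemble level hashes into the final hash
#'
#' Each level's 40 bits are permuted by a key-seeded deterministic
#' permutation (positions drawn from the logistic orbit, duplicates
#' skipped), then concatenated in the order content, E2, E1 into the
#' 120-bit authentication hash. Scrambling permutes, so each level's
#' popcount is preserved, and [unscramble_bits()] inverts it exactly.
#'
#' @param level_hashes List of exactly three 40-bit integer vectors, in
#'   the order content, E2, E1.
#' @param key A `chaos_key`.
#' @param scheme Scheme tag, 1 or 2.
#' @return Object of class `perceptual_hash`: fields `bits` (length
#'   120), `scheme`, `levels`, `bits_per_level`, `params_digest`.
#' @export
scramble_and_assemble <- function(level_hashes, key, scheme = 2L) {
  if (length(level_hashes) != 3L) stop("need exactly 3 level hashes")
  npl <- unique(lengths(level_hashes))
  if (length(npl) != 1L) stop("level hashes must share one length")
  scrambled <- lapply(seq_along(level_hashes), function(l) {
    perm <- key_permutation(key, npl, offset = (l - 1L) * 1000L)
    level_hashes[[l]][perm]
  })
  structure(
    list(
      bits = as.integer(unlist(scrambled)),
      scheme = as.integer(scheme),
      levels = 3L,
      bits_per_level = as.integer(npl),
      params_digest = key$params_digest
    ),
    class = "perceptual_hash"
  )
}

#' @rdname scramble_and_assemble
#' @param hash A `perceptual_hash` produced by [scramble_and_assemble()].
#' @return `unscramble_bits` returns the list of three unscrambled
#'   level-hash bit vectors.
#' @export
unscramble_bits <- function(hash, key) {
  npl <- hash$bits_per_level
  lapply(seq_len(hash$levels), function(l) {
    perm <- key_permutation(key, npl, offset = (l - 1L) * 1000L)
    chunk <- hash$bits[((l - 1L) * npl + 1L):(l * npl)]
    out <- integer(npl)
    out[perm] <- chunk
    out
  })
}

#' Hash an image with the full keyed pipeline
#'
#' Runs preprocessing, two-level Haar decomposition, keyed dither
#' quantization, trimean binarization, cat-map scrambling of each
#' binarized feature matrix, per-level compression by the chosen scheme,
#' and key-seeded bit scrambling. For the canonical 512 x 512 input the
#' result is always 120 bits, 40 per feature level, under either scheme.
#'
#' @param image Anything [preprocess_image()] accepts.
#' @param key A `chaos_key` (or a passphrase string, from which a
#'   default key is built).
#' @param scheme 1 (MD5-based) or 2 (block majority).
#' @return A `perceptual_hash`.
#' @examples
#' img <- generate_test_image(seed = 1)
#' h <- perceptual_hash(img, chaos_key("swordfish"), scheme = 2)
#' length(h$bits)  # 120
#' @export
perceptual_hash <- function(image, key, scheme = 2L) {
  if (is.character(key)) key <- chaos_key(key)
  stopifnot(inherits(key, "chaos_key"))
  if (!scheme %in% c(1L, 2L)) stop("scheme must be 1 or 2")
  fs <- feature_stack(image, key)
  level_hashes <- lapply(fs[c("content", "e2", "e1")], function(f) {
    b <- binarize_feature(f)
    ab <- key_ab_for_N(key, nrow(b))
    b <- cat_map_permute(b, ab$a, ab$b, iterations = key$q)
    if (scheme == 2L) scheme2_level_hash(b) else scheme1_level_hash(b)
  })
  h <- scramble_and_assemble(level_hashes, key, scheme = scheme)
  h$quartile_sd <- fs$quartile_sd
  h
}

#' @export
print.perceptual_hash <- function(x, ...) {
  cat("<perceptual_hash> scheme", x$scheme, ":",
      length(x$bits), "bits (", x$levels, "levels x",
      x$bits_per_level, ")\n")
  cat(" ", bits_to_hex(x$bits), "\n")
  invisible(x)
}

#' Compare two hashes for authentication
#'
#' Computes the normalized Hamming distance (fraction of differing
#' bits). The pair is `incomparable` when lengths, schemes or parameter
#' digests disagree; otherwise the decision is `authentic` when the
#' distance is at or below the threshold and `tampered` above it. The
#' default threshold of 0.15 separates content-preserving processing
#' from tampering on the synthetic corpus; it is a configurable
#' operating point, not a universal constant.
#'
#' @param h1,h2 `perceptual_hash` objects.
#' @param threshold Decision threshold on the normalized distance.
#' @return List with `normalized_hamming`, `threshold`, `decision`.
#' @export
hamming_verify <- function(h1, h2, threshold = 0.15) {
  stopifnot(inherits(h1, "perceptual_hash"), inherits(h2, "perceptual_hash"))
  if (length(h1$bits) != length(h2$bits) ||
      !identical(h1$params_digest, h2$params_digest) ||
      h1$scheme != h2$scheme) {
    return(list(normalized_hamming = NA_real_, threshold = threshold,
                decision = "incomparable"))
  }
  d <- mean(h1$bits != h2$bits)
  list(
    normalized_hamming = d,
    threshold = threshold,
    decision = if (d <= threshold) "authentic" else "tampered"
  )
}

bits_to_hex <- function(bits) {
  stopifnot(length(bits) %% 4L == 0L)
  nib <- vapply(seq_len(length(bits) / 4L), function(k) {
    b <- bits[(4L * k - 3L):(4L * k)]
    sum(b * c(8L, 4L, 2L, 1L))
  }, integer(1))
  paste(sprintf("%x", nib), collapse = "")
}

#' Write / read a hash file
#'
#' The hash file holds a single line of lowercase hex (30 characters for
#' 120 bits); a JSON sidecar `<path>.json` records the scheme, the key
#' parameter digest, and a creation timestamp.
#'
#' @param hash A `perceptual_hash`.
#' @param path Output file path.
#' @return `write_hash` returns `path` invisibly; `read_hash` returns
#'   the reconstructed `perceptual_hash`.
#' @export
write_hash <- function(hash, path) {
  stopifnot(inherits(hash, "perceptual_hash"))
  writeLines(bits_to_hex(hash$bits), path)
  jsonlite::write_json(
    list(scheme = hash$scheme, params_digest = hash$params_digest,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_hash
#' @export
read_hash <- function(path) {
  hex <- trimws(readLines(path, n = 1L))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bits <- hex_to_bits(hex, nchar(hex) * 4L)
  structure(
    list(bits = bits, scheme = as.integer(meta$scheme), levels = 3L,
         bits_per_level = length(bits) %/% 3L,
         params_digest = meta$params_digest),
    class = "perceptual_hash"
  )
}
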