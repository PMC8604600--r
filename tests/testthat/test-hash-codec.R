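test_that("block-majority compression counts zeros and ones per block", {
  expect_identical(scheme2_level_hash(matrix(1L, 40, 40)), rep(1L, 40))
  expect_identical(scheme2_level_hash(matrix(0L, 40, 40)), rep(0L, 40))

  # a tied block emits 0 (N0 >= N1 rule): blocks here are 2x2
  m <- matrix(0L, 10, 16)
  m[1, 1] <- 1L
  m[2, 2] <- 1L
  expect_equal(scheme2_level_hash(m)[1], 0L)

  # random matrices vs an independent counting oracle over the same grid
  set.seed(43)
  for (rep in 1:10) {
    nr <- sample(c(40, 100, 128), 1)
    nc <- sample(c(40, 128, 160), 1)
    bm <- matrix(sample(0:1, nr * nc, replace = TRUE, prob = c(0.45, 0.55)),
                 nr, nc)
    got <- scheme2_level_hash(bm)
    expect_length(got, 40)
    if (nr %% 20 == 0 && nc %% 20 == 0 && (nr / 20) * (nc / 20) == 40) {
      brows <- nr / 20; bcols <- nc / 20
    } else {
      brows <- 5; bcols <- 8
    }
    rb <- floor(seq(0, nr, length.out = brows + 1))
    cb <- floor(seq(0, nc, length.out = bcols + 1))
    oracle <- integer(0)
    for (i in seq_len(brows)) {
      for (j in seq_len(bcols)) {
        blk <- bm[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
        oracle <- c(oracle, if (sum(blk == 0) >= sum(blk == 1)) 0L else 1L)
      }
    }
    expect_identical(got, oracle)
  }
})

test_that("a 160x100 matrix tiles into exactly forty 20x20 blocks", {
  bm <- matrix(0L, 160, 100)
  bm[1:20, 1:20] <- 1L  # exactly one all-ones 20x20 tile
  bits <- scheme2_level_hash(bm)
  expect_equal(sum(bits), 1)
  expect_equal(bits[1], 1L)
})

test_that("MD5 level hash is deterministic and matches an independent digest", {
  m <- matrix(c(1.25, -0.5, 0, 3), 2, 2)
  h <- scheme1_level_hash(m)
  expect_length(h, 40)
  expect_true(all(h %in% 0:1))
  expect_identical(scheme1_level_hash(m), h)

  # independent oracle: serialize by hand (row-major, 6 decimals), MD5,
  # expand hex digits to bits
  # row-major walk of matrix(c(1.25, -0.5, 0, 3), 2, 2)
  ser <- paste(sprintf("%.6f", c(1.25, 0, -0.5, 3)), collapse = ",")
  hex <- digest::digest(ser, algo = "md5", serialize = FALSE)
  oracle <- unlist(lapply(strtoi(strsplit(hex, "")[[1]][1:10], 16L),
                          function(v) as.integer(intToBits(v)[4:1])))
  expect_identical(h, oracle)

  # negative zero must serialize like positive zero
  expect_identical(scheme1_level_hash(matrix(c(0, -1e-9), 1, 2)),
                   scheme1_level_hash(matrix(c(0, 0), 1, 2)))
})

test_that("MD5 level hash avalanches under single-entry perturbations", {
  set.seed(47)
  base <- matrix(runif(100), 10, 10)
  h0 <- scheme1_level_hash(base)
  flips <- replicate(200, {
    m <- base
    m[sample(100, 1)] <- runif(1)
    sum(scheme1_level_hash(m) != h0)
  })
  expect_gt(mean(flips), 17)
  expect_lt(mean(flips), 23)
})

test_that("bit scrambling permutes within levels and inverts exactly", {
  set.seed(53)
  levels <- replicate(3, sample(0:1, 40, replace = TRUE), simplify = FALSE)
  h <- scramble_and_assemble(levels, test_key, scheme = 2)
  expect_length(h$bits, 120)
  expect_equal(h$bits_per_level, 40)
  # per-level popcount is preserved by any permutation
  for (l in 1:3) {
    expect_equal(sum(h$bits[((l - 1) * 40 + 1):(l * 40)]), sum(levels[[l]]))
  }
  # unscrambling restores each level in the content, E2, E1 order
  expect_identical(unscramble_bits(h, test_key), levels)
  # a different key scrambles differently (same bits, other positions)
  other <- scramble_and_assemble(levels, chaos_key("other-pass"), scheme = 2)
  expect_false(identical(other$bits, h$bits))
  expect_error(scramble_and_assemble(levels[1:2], test_key), "3 level")
})

test_that("hamming verification classifies authentic, tampered, incomparable", {
  mkhash <- function(bits, digest = "d") {
    structure(list(bits = bits, scheme = 2L, levels = 3L, bits_per_level = 40L,
                   params_digest = digest), class = "perceptual_hash")
  }
  set.seed(59)
  h <- mkhash(sample(0:1, 120, replace = TRUE))
  expect_equal(hamming_verify(h, h)$normalized_hamming, 0)
  expect_equal(hamming_verify(h, h)$decision, "authentic")
  comp <- mkhash(1L - h$bits)
  expect_equal(hamming_verify(h, comp)$normalized_hamming, 1)
  expect_equal(hamming_verify(h, comp)$decision, "tampered")
  # 12 of 120 differing bits at threshold 0.15 is authentic
  h12 <- mkhash(h$bits)
  h12$bits[1:12] <- 1L - h12$bits[1:12]
  v <- hamming_verify(h, h12, threshold = 0.15)
  expect_equal(v$normalized_hamming, 0.1)
  expect_equal(v$decision, "authentic")
  expect_equal(hamming_verify(h, mkhash(h$bits, "other"))$decision,
               "incomparable")
})

test_that("the full pipeline meets the 120-bit contract for both schemes", {
  img <- generate_test_image(seed = 2)
  for (scheme in 1:2) {
    h <- perceptual_hash(img, test_key, scheme = scheme)
    expect_length(h$bits, 120)
    expect_equal(h$levels * h$bits_per_level, 120)
    expect_true(all(h$bits %in% 0:1))
    expect_equal(h$scheme, scheme)
  }
  expect_error(perceptual_hash(img, test_key, scheme = 3), "scheme")
})

test_that("hash files round-trip through hex plus JSON sidecar", {
  img <- generate_test_image(seed = 3)
  h <- perceptual_hash(img, test_key, scheme = 2)
  f <- tempfile(fileext = ".hash")
  write_hash(h, f)
  line <- readLines(f, n = 1)
  expect_match(line, "^[0-9a-f]{30}$")
  back <- read_hash(f)
  expect_identical(back$bits, h$bits)
  expect_equal(back$scheme, h$scheme)
  expect_identical(back$params_digest, h$params_digest)
  expect_equal(hamming_verify(h, back)$decision, "authentic")
  unlink(c(f, paste0(f, ".json")))
})

test_that("different passphrases decorrelate scheme-1 hashes and alter scheme-2", {
  img <- generate_test_image(seed = 4)
  # scheme 1: MD5 diffusion pushes key-mismatch distances to ~0.5
  set.seed(61)
  d1 <- vapply(1:100, function(i) {
    a <- perceptual_hash(img, chaos_key(sprintf("pw-a-%03d", i)), scheme = 1)
    b <- perceptual_hash(img, chaos_key(sprintf("pw-b-%03d", i)), scheme = 1)
    mean(a$bits != b$bits)
  }, numeric(1))
  expect_gt(mean(d1), 0.35)
  expect_lt(mean(d1), 0.65)
  # scheme 2's statistical compression is much less key-sensitive; the
  # key still matters (hashes change), which is all it guarantees
  d2 <- vapply(1:10, function(i) {
    a <- perceptual_hash(img, chaos_key(sprintf("pw-a-%03d", i)), scheme = 2)
    b <- perceptual_hash(img, chaos_key(sprintf("pw-b-%03d", i)), scheme = 2)
    mean(a$bits != b$bits)
  }, numeric(1))
  expect_gt(mean(d2), 0)
})
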