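# one key shared across tests; derivation is deterministic so this is a
# fixed fixture, not hidden state
test_key <- chaos_key("wavehash-test-passphrase")

random_matrix <- function(n, m = n, lo = -50, hi = 50) {
  matrix(stats::runif(n * m, lo, hi), n, m)
}

# independent quantizer for oracles: plain elementwise formula written
# out long-hand, no shared code with the implementation
oracle_quantize <- function(L, Q) {
  out <- L
  for (i in seq_len(nrow(L))) {
    for (j in seq_len(ncol(L))) {
      ratio <- L[i, j] / Q[i, j]
      k <- if (ratio >= 0) floor(ratio + 0.5) else -floor(-ratio + 0.5)
      out[i, j] <- k * Q[i, j]
    }
  }
  out
}
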