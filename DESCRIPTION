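Package: wavehash
Title: Keyed Perceptual Wavelet Hashing for Diagnostic Image Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and verifies keyed perceptual hashes of diagnostic
    raster images. Features are taken from a two-level Haar wavelet
    decomposition: the quantized low-frequency content level and per-level
    subband energies, quantized with a chaos-keyed jitter (dither)
    quantizer, binarized against the trimean, scrambled with an Arnold
    cat map, and compressed to a 120-bit authentication hash by either an
    MD5-based scheme or a block-majority scheme. Keys derive from a text
    passphrase through a logistic map and can be bound to the imaging
    optics through a radial-distortion (k1) optical key. Ships seeded
    synthetic image and attack generators for offline testing, plus two
    transcribed clinical tables (gastrointestinal bleeding volume and
    recovery scores) with robust descriptive statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
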