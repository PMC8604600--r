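---
title: "Keyed perceptual wavelet hashing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyed perceptual wavelet hashing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavehash)
```

## The problem

A perceptual hash condenses an image into a short bit sequence that is
stable under content-preserving processing (lossy recompression, mild
filtering, small noise) but changes when the content itself is altered.
For diagnostic imagery the use case is integrity verification: a
workstation stores a keyed hash alongside each image, and a later
recomputation that drifts beyond a threshold flags possible tampering.
Keying matters because an unkeyed hash can be forged: an attacker who can
compute the hash of an arbitrary image can craft a benign-looking
substitute with a matching hash.

`wavehash` implements such a pipeline end to end: chaos-keyed feature
extraction in the wavelet domain, robust-statistic binarization,
position scrambling, two compression schemes, and verification by
normalized Hamming distance, plus an "optical key" that binds the key
material to a lens-distortion parameter of the acquiring camera.

## Pipeline

For an image $I$ and a passphrase-derived key:

1. **Canonicalization.** Decode, convert RGB to luminance
   ($0.299R + 0.587G + 0.114B$), bilinearly resize to $512 \times 512$,
   scale to $[0, 255]$. All shape contracts downstream assume this
   canonical raster.
2. **Two-level Haar decomposition.** Orthonormal Haar is used because it
   is exact on dyadic sizes (perfect reconstruction to machine
   precision, which the tests assert at $10^{-8}$) and free of boundary
   artifacts. `LL2` ($128 \times 128$) carries the low-frequency
   content; the detail subbands come in a $128$-sized level 2
   (`HL2, LH2, HH2`) and a $256$-sized level 1 (`HL1, LH1, HH1`).
3. **Jitter quantization.** A logistic-map orbit
   $x_{k+1} = \lambda x_k (1 - x_k)$ seeded by the key is thresholded at
   $0.5$ into a $\pm 1$ dither matrix $M^d$; the quantization steps are
   $Q^d = M^q (1 + \beta M^d)$ with a constant base step
   $M^q \equiv \Delta$. Coefficients are snapped to step multiples,
   $E_0 = \mathrm{round}(L / Q^d) \cdot Q^d$. The keyed steps make the
   quantization grid itself secret, so an attacker cannot predict which
   perturbations survive quantization.
4. **Features.** The content feature is the quantized `LL2`. The energy
   features are per-position sums of squares of the quantized detail
   subbands: $E_2$ (robust level, $128 \times 128$) and $E_1$ (detailed
   level, $256 \times 256$). Squaring makes them invariant to
   coefficient sign flips.
5. **Binarization.** Each feature matrix is thresholded strictly above
   its trimean $\hat M = \tfrac14 M_{0.25} + \tfrac12 M + \tfrac14
   M_{0.75}$. The trimean is used instead of the mean because a single
   gross outlier (a saturated region, an artifact) barely moves it. The
   quartile spread $(M_{0.75} - M_{0.25})/1.349$ is recorded as hash
   metadata — a robust scale diagnostic — but does not enter the bits,
   since the compression schemes consume bit matrices.
6. **Scrambling.** Each binarized matrix is permuted by $q$ iterations
   of the Arnold cat map
   $(i', j') = (i + a j,\; b i + (a b + 1) j) \bmod N$ with
   passphrase-derived integers $a, b \in [1, N-1]$. The map has
   determinant 1, so it is an exact bijection on the index grid and
   exactly invertible. Scrambling ties every hash bit to the whole
   matrix rather than one region.
7. **Compression.** *Scheme 2* (default) partitions each scrambled bit
   matrix into 40 blocks and emits the per-block majority (ties go to
   0), giving 40 bits per level. *Scheme 1* serializes the matrix
   canonically (row-major, fixed 6-decimal formatting, negative zero
   normalized), digests it with MD5 and keeps the first 40 digest bits.
8. **Assembly.** Each level's 40 bits are permuted by a key-seeded
   permutation (positions drawn from the logistic orbit, duplicates
   skipped) and concatenated content‖E2‖E1 into the final 120-bit hash.
9. **Verification.** Two hashes with matching parameter digests and
   schemes are compared by normalized Hamming distance; at or below the
   threshold the image is declared authentic.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `delta` | 20 | Base quantization step (gray-value scale of wavelet coefficients). Large enough to absorb JPEG-level coefficient noise in `LL2`, small enough to keep ~50 distinct content levels over the 0–1020 `LL2` range. |
| `beta` | 0.1 | Jitter amplitude as a fraction of the step; must stay below 1 so steps remain positive. |
| `lambda` | 3.99 | Logistic parameter for keyed orbits. Inside the chaotic regime but strictly below 4, so the orbit cannot hit the absorbing fixed point at 0 (with $\lambda = 4$, $x_0 = 0.5$ maps to $1$ and then to $0$ forever — and $x_0 = 0.5$ arises from real passphrases, e.g. `"@"`). |
| `q` | 3 | Cat-map iterations. More iterations enlarge the effective key space, $(N-1)^{2q}$; three is enough to decorrelate block membership at $N = 128$ while staying cheap. |
| `burn_in` | 100 | Orbit iterates discarded before use, to escape transients. |
| threshold | 0.15 | Verification operating point on the normalized distance. Chosen empirically on the synthetic corpus, where scheme-2 distances under JPEG-70 concentrate near 0.02 and distinct-image distances near 0.22; it is configurable and has no claim to universality. |

The passphrase enters as $x_0 = \mathrm{mean}(\mathrm{ASCII})/128$,
followed by 50 iterations and the expansion
$a = 1 + \lfloor 10^6 x \rfloor \bmod (N - 1)$ (next iterate for $b$).
The iteration count and expansion constants are this package's own
fixed choices; only the shape of the derivation (ASCII mapping, dozens
of iterations, linear expansion, modulo, rounding) is inherited.

## The two schemes are two ends of a trade-off

Scheme 2 is *statistical*: block majorities change only when many
underlying bits change, so JPEG-70 recompression moves the hash by a
couple of bits while replacing a quarter of the image moves it far.
This is the scheme to use for tamper detection with benign-processing
tolerance.

Scheme 1 is *exact*: MD5 avalanches, so the distance between two hashes
is near 0 when the underlying feature matrices are bit-identical and
near 0.5 otherwise — under any change, benign or malicious. It
authenticates only exact feature survival, and its robustness margin is
exactly the probability that quantization absorbs the whole
perturbation. On $128 \times 128$-and-larger feature matrices that
probability is essentially zero for JPEG recompression, so scheme 1
should be read as the fragile ("accurate hash") end of the
robust-feature-plus-exact-hash design: useful where any change must be
flagged, unsuitable where JPEG robustness is required. The test suite
asserts the statistical separation property for both schemes; it holds
cleanly for scheme 2 and fails for scheme 1 for exactly this structural
reason, which we consider a faithful property of the method rather than
an implementation defect.

Key sensitivity follows the same split: with different passphrases on
the same image, scheme-1 distances center at 0.5 (MD5 diffusion), while
scheme-2 distances stay small because block majorities of a
cat-map-homogenized matrix are nearly key-invariant. Scheme 2's
security therefore rests on the secrecy of the quantization grid and
scrambling positions, not on bit diffusion.

## Optical key

The radial distortion model
$x_d = x_c + (x_\mu - x_c)\,T(r)$, $T(r) = 1 + k_1 r^2$, with
$r$ the Euclidean distance from the distortion center, describes the
lens of the acquiring camera. The optical key encodes $k_1$ as 64-bit
fixed point (scale $2^{-32}$, two's complement), tiles it to the base
key length and XORs. XOR makes the derivation an involution, and the
derived key depends only on $(\mathrm{base}, k_1)$ — never on pixel
data — so ordinary signal processing cannot perturb it, while any
change in the optical parameter flips key bits. How $k_1$ is measured
(camera calibration) and how tampering would alter it in practice are
outside this package's scope; `k1` is accepted as configuration.

## Synthetic data: what it emulates and what it does not

`generate_test_image()` produces a seeded smooth gradient plus
band-limited sinusoidal texture plus one soft blob, normalized to
$[0, 255]$. This emulates the large-scale structure of diagnostic
rasters — smooth intensity fields with a dominant feature — well enough
to exercise every pipeline stage deterministically and offline. It does
**not** emulate sensor noise or fine tissue texture: its level-1 Haar
details usually fall below the default quantization step, so the
detailed-level feature $E_1$ is frequently all-zero. Consequences to
keep in mind when reading test results: the $E_1$ level contributes
little discrimination on this corpus, and passing tests demonstrate the
pipeline's mechanics and statistical separation on smooth imagery, not
performance on real clinical data. The attack generator covers JPEG
recompression, seeded Gaussian noise, box filtering and rectangular
block tampering.

## Clinical tables

Two paired control/test tables ship as plain CSV (40 records per group,
patient numbers 1–40): per-patient gastrointestinal bleeding volume and
post-treatment recovery scores. They are transcribed verbatim from
their printed source, units unstated there and therefore recorded as
unitless; an MD5 checksum is verified on load so transcription drift
fails loudly. The source text describes 80 bleeding patients and 90
healthy controls while both tables carry 40 records per group; the
tables are packaged exactly as printed and the discrepancy is
documented, not resolved. `summarize_group()` reports n, mean, median,
extrema and the quartile spread using the package's own robust
statistics; no inferential comparison is exposed because the source
reports no test statistic to reproduce.

## Numerical choices

- Rounding in the quantizer is half-away-from-zero, so the error bound
  $|L - E_0| \le Q^d/2$ is symmetric and platform-independent.
- Binarization uses strict inequality, so constant matrices give
  all-zero bits deterministically.
- The $p$-quantile averages the two adjacent order statistics when $np$
  is an integer (integer test at tolerance $10^{-9}$), with $p = 0$ and
  $p = 1$ clamped to the extrema.
- Scheme-1 serialization rounds to 6 decimals and normalizes negative
  zero before formatting, so digests are byte-stable across platforms.
- Cat-map indices are 0-based; the origin is a fixed point of the map,
  and the inverse uses the adjugate $\bigl(\begin{smallmatrix} ab+1 &
  -a \\ -b & 1 \end{smallmatrix}\bigr) \bmod N$, exact because the
  determinant is 1.
- The key-space size $(N-1)^{2q}$ is returned as a double, exact below
  $2^{53}$.

## Problem sizes in the shipped tests

The unit suite runs property checks on hundreds of small random
matrices and full-pipeline checks on a handful of $512 \times 512$
images; the statistical separation and key-sensitivity checks use a
50-image corpus and 100 passphrase pairs. These sizes make the suite
complete in a few minutes on one CPU while keeping Monte-Carlo
standard errors well inside the asserted bands.

## Limitations

- The chaotic key derivation is keyed determinism, not cryptography: no
  formal hardness, no key-stretching, no resistance to chosen-image
  attacks beyond the scrambling argument. Do not use where an adversary
  controls inputs and knows the construction.
- Scheme 1 has no JPEG robustness (see above); scheme 2 has limited key
  sensitivity.
- The verification threshold is corpus-calibrated; deployments should
  recalibrate on imagery from their own modality.
- No tamper localization: verification is a single global decision.
- Rotation and rescaling beyond the canonical resize are not
  compensated; the hash is not geometric-invariant.
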