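---
title: "Models and methods behind fractalkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fractalkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

fractalkit estimates scaling and complexity measures on three kinds of
input: 1D sequences, 2D grey images and 3D grey volumes. This vignette
explains the models the package implements, the parameters that matter,
the numerical choices made where the design was genuinely open, and what
the synthetic generators do and do not emulate.

## The exponent bookkeeping

Everything fractal in the package is tied together by one convention. For
an object embedded in E dimensions (a signal graph has E = 1, a grey
surface E = 2, a grey volume E = 3) with Hurst exponent H in (0, 1):

- fractal dimension: D = E + 1 − H, so D lies in (E, E + 1);
- power-spectral exponent: β = 2H + E = 3E + 2 − 2D.

The three canonical self-tests — a 1D signal with D = 1.5, a surface with
D = 2.5, a volume with D = 3.5 — all correspond to H = 0.5 and to β = 2,
3 and 4 respectively. The generators synthesize data *to* this convention
and the estimators read dimensions back *from* it, so recovery of the
target dimension is a genuine round-trip through two independent code
paths (e.g. a surface synthesized in the Fourier domain is estimated
either spectrally, via `fft_dim_grid()`, or in the pixel domain, via
`higuchi_dim_grid()`).

## Generators

**Weierstrass–Mandelbrot signals** (`generate_sequence("wm")`) sum
lacunary sinusoids x(t) = Σ γ^(−nH) sin(γⁿ t + φₙ) with H = 2 − D,
γ = 1.5 and phases φₙ uniform on [0, 2π). The user-facing parameter is
only the target dimension; the base γ and the n-range are implementation
choices. γ = 1.5 gives a dense frequency ladder, and n runs over the
symmetric range for which γⁿ spans one cycle per record up to one cycle
per sample — outside that range terms are either constant offsets or
unresolvable.

**Fractional Gaussian noise** (`"fgn_dhm"`) uses exact circulant
(Davies–Harte) embedding of the fGn autocovariance
ρ(k) = ½(|k+1|^2H − 2|k|^2H + |k−1|^2H); the embedding eigenvalues are
checked for nonnegativity and the first row carries ρ(n) at the midpoint,
so the sampled covariance is exact, not approximate. **Fractional
Brownian motion** (`"fbm_ssm"`) is synthesized spectrally: the Fourier
transform of white Gaussian noise is shaped by the amplitude
f^(−(2H+1)/2) and inverse-transformed. The real part of that transform
already *is* the fBm-like path with spectral exponent β = 2H + 1; no
integration step follows. (Appending a cumulative sum here would double
the spectral exponent and break the package's own spectral-recovery
checks, which is why the generator does not do it.)

**Fractal surfaces and volumes** (`"surface_fft"`, `"volume_fft"`) apply
the same spectral shaping in 2 and 3 dimensions with β = 8 − 2D and
β = 11 − 2D. Filtering the transform of real white noise keeps Hermitian
symmetry automatically for any grid shape, which avoids explicit
conjugate-pair bookkeeping for odd sizes. The field is then min–max
scaled to [0, 255] and rounded half-up: quantization is applied *before*
estimation on purpose, because that is what an 8-bit image pipeline sees.
The midpoint-displacement surface (`"surface_mpd"`) is the diamond–square
construction with per-level displacement SD multiplied by 2^(−H),
H = 3 − D.

**IFS sets.** The Menger carpet/cube masks are computed by base-3 digit
tests (a cell is removed at level l when its l-th ternary digit is 1 in
at least two axes — in 2D that means both axes), which gives the exact
recursive foreground counts 8^L and 20^L. The Sierpinski triangle uses
the chaos game. Cantor dust keeps two end intervals of relative width r
per level (D = ln 2 / ln(1/r)) and rasterizes half-open intervals onto
round((1/r)^levels) cells; cell centres are offset half a cell from
interval endpoints, so float rounding cannot flip membership.

**Chaotic maps** (logistic a = 4, Hénon a = 1.4/b = 0.3, cubic a = 3,
Spence x ← |ln x|) discard a 100-step transient and draw the initial
condition uniformly from each map's basin.

What the generators do **not** emulate: measurement noise floors,
anisotropy, nonstationary trends, illumination gradients, or the mixed
texture of real micrographs. A passing recovery test shows the estimator
chain is calibrated for homogeneous, isotropic, stationary fractals; it
does not promise unbiased dimensions on arbitrary real data.

## The shared regression engine

Every regression-based estimator reduces to ordinary least squares of
ln(measure) on ln(scale) (`loglog_fit()`). Regression window indices are
1-based and inclusive, mirroring the "Regression Min/Max" convention of
interactive tools. Non-positive measures are an error unless
`skip_zero = TRUE` drops them; silent dropping is never the default.
R² is computed on the fitted points only.

Scale ladders: dyadic (1, 2, 4, …, extent/2) by default. For dyadic
ladders the default window drops the smallest and largest scale (the
central scaling region; finite-size effects concentrate at the ends).
`box_counting_dim()` switches to a triadic ladder (1, 3, 9, …) when the
smallest side is an exact power of 3: origin-anchored boxes then align
with base-3 self-similar sets, whose counts become exact — on a shallow
Menger cube (level 3, 27³) dyadic boxes saturate at both ends of the
ladder (over 70% occupancy at ε = 2, all boxes occupied at ε = 8) and no
dyadic window can reach the analytic dimension, while the triadic ladder
reproduces it with R² = 1. Triadic ladders use the full window.

**Radial spectrum averaging** (`radial_power_average()`) bins FFT power
by the integer wavenumber k = round(|f|) ("circular" in 2D, "spherical"
in 3D) and reports mean power per bin for k = 1..min(side)/2, excluding
DC. The Hann window option subtracts the grid mean first, then applies
the separable per-axis window; mean removal keeps spectral leakage from
the DC pedestal out of the low-frequency bins that dominate the fit. Full
bin sums are exposed so that, without a window, Parseval's identity (Σ
bin sums + DC = Σ|F|²) can be asserted exactly.

## Estimators: conventions and degenerate inputs

- **Higuchi (1D)**: the genuine algorithm, averaging curve lengths over
  all k offsets; window indices refer to k = 1..kmax. Constant sequences
  produce all-zero lengths and raise a degenerate-regression error rather
  than returning a sentinel.
- **Higuchi (2D/3D), direct differences**: the mean absolute k-spaced
  grey difference per axis defines L(k) = mean|Δₖ| · k^−(E+1). The
  normalization is fixed by a calibration constraint: a plane ramp gives
  mean|Δₖ| ∝ k and hence slope −E exactly, so smooth surfaces report
  D = E; iid noise gives mean|Δₖ| constant and D = E + 1; a surface of
  Hurst h gives mean|Δₖ| ∝ k^h and D = E + 1 − h. The `profiles_1d`
  variant runs 1D Higuchi over every row and column and reports the mean
  profile dimension + 1.
- **DFA**: order-1 detrending, non-overlapping windows, 20 log-spaced
  sizes from 4 to N/4, no reverse-direction pooling.
- **PSD Hurst**: Hann-windowed periodogram, fit over the lowest half of
  frequency indices by default (the scaling regime of interest for
  long-memory classification); β < 1 classifies fGn with H = (β+1)/2,
  β ≥ 1 (boundary inclusive) classifies fBm with H = (β−1)/2.
- **Katz / Petrosian / Sevcik**: closed-form rough estimates. Two
  consequences of the formulas worth knowing: a constant sequence is a
  horizontal line for Katz (D = 1, not an error), and Sevcik converges
  towards its limits only at ln-speed (a diagonal line at N = 10⁴ still
  reads ≈ 1.035; Gaussian noise at N = 4096 reads ≈ 1.7, approaching 2
  slowly as the normalized range grows like √log N).
- **Correlation dimension**: pair counting over log-spaced radii from
  1.5 px to a quarter of the maximum pairwise distance — below that,
  lattice discreteness staircases the correlation sum; above it, C(r)
  saturates towards 1 and flattens the slope. Foregrounds larger than
  `max_points` (default 5000) are subsampled with a seeded RNG.
- **Generalized dimensions**: box masses from grey sums; empty boxes are
  excluded from Σμ^q; D₁ uses the Σμ ln μ form directly.
- **Lacunarity**: Λ(r) = ⟨M²⟩/⟨M⟩² over raster tiles or gliding windows
  (computed with an integral image); gliding is the default (smoother in
  r; raster is kept for strict tile semantics and is exactly invariant
  under reflections).
- **FFI**: box dimension of the mask minus box dimension of its boundary,
  the boundary being the foreground minus its 4-connected erosion
  (4-connectivity gives the thinnest boundary). Single-pixel foregrounds
  are rejected.
- **ApEn/SampEn**: Chebyshev metric, tolerance r = 0.2 × sample SD by
  default (the field-standard convention); ApEn includes self-matches
  (Pincus), SampEn excludes them (Richman–Moorman) and errors when no
  matches exist rather than returning infinity.
- **Permutation entropy**: Bandt–Pompe patterns with ties broken by
  earlier index; patterns are encoded by their pairwise comparison bits,
  which is a bijection onto ordinal patterns and avoids per-template
  sorting.
- **Generalized entropies**: the q-families return the Shannon limit at
  q = 1 (and κ = 0) explicitly instead of evaluating 0/0.
- **Kolmogorov complexity**: DEFLATE length of a canonical serialization
  (8-byte IEEE doubles for sequences, row-major 8-bit grey for grids).
  Logical depth (median decompression wall time) is reported with a
  hardware-dependence flag and is deliberately excluded from any
  recovery claim.

## Surrogates and noise

Spectral surrogates multiply the n-dimensional Fourier transform by
unit-modulus factors taken from the transform of white Gaussian noise of
the same shape: conjugate symmetry (hence a real result) holds by
construction for any dimensionality and odd sizes, with no padding.
Self-conjugate bins (DC and Nyquist combinations) are forced to +1, so
the mean is preserved exactly. AAFT is Theiler's single-pass scheme:
Gaussianize by rank, phase-randomize, restore the original amplitudes by
rank — the value multiset is preserved exactly and the spectrum
approximately; the iterated refinement (IAAFT) is out of scope. The
"gaussian" surrogate is defined as iid normal draws matched to the
sample mean and SD — the natural baseline that destroys both the
amplitude distribution and all correlation. Surrogates of 8-bit grids
are clamped back to [0, 255], so exact spectral conservation laws are
stated (and tested) on sequences.

Noise levels mean: SD (gaussian), half-width (uniform), scale with the
distribution mean subtracted (rayleigh, exponential), corrupted fraction
(salt & pepper, extremes 0/255 for grids and the per-sequence min/max
otherwise), and detector gain for shot noise (v → gain · Poisson(v/gain);
negative inputs are treated as zero intensity). Level 0 is the identity.

Surrogate ensembles derive one child seed per surrogate from the base
seed, evaluate the statistic on the original and each surrogate, and
report all individual values plus their mean and sample SD (n − 1), so
the summary is exactly recomputable from the reported values.

## Problem sizes and reproducibility

The bundled tests run the full recovery suite at the sizes the methods
are specified at — sequences of 1024–8192 samples, surfaces up to 512²,
volumes at 128³ (the acceptance script additionally runs the 256³
volume) — chosen as the smallest sizes at which the estimators' own
tolerances are meaningful. Every stochastic routine takes an integer
seed; the same seed gives bit-identical output, and the CLI writes
byte-identical files under identical seeds. All internal computation is
double precision regardless of the 8-bit storage convention.

## Known limitations

- Estimators assume isotropy; no directional variants are provided.
- Grey-scale (mass) box counting is not implemented — `binarize()` is the
  only route from grey grids to set-based estimators.
- The Minkowski estimator uses square structuring elements only (no
  blanket/variation methods).
- Sevcik and Katz are rough ln-speed estimates and should not be used
  where Higuchi or DFA applies.
- Logical depth is a wall-clock proxy and not comparable across machines.
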