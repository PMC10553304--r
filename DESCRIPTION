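Package: fractalkit
Title: Fractal Dimension, Entropy and Surrogate Analysis for Signals, Images and Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generators of synthetic fractal and chaotic test data
    (Weierstrass-Mandelbrot signals, fractional Gaussian noise and motion,
    spectral-synthesis fractal surfaces and volumes, iterated function
    system sets, discrete chaotic maps), surrogate data methods (shuffle,
    Gaussian, random phase, AAFT) and noise injection in one, two and
    three dimensions, and a uniform set of nonlinear estimators: fractal
    dimensions (Higuchi, Katz, Petrosian, Sevcik, box counting, pyramid,
    Minkowski, correlation, generalized, FFT/spectral), detrended
    fluctuation analysis, Hurst exponents, lacunarity, the fractal
    fragmentation index, sample/approximate/permutation entropy, a family
    of generalized entropies, and compression-based Kolmogorov complexity.
    Sequences are read and written as comma-separated text tables; images
    and volumes as 8-bit PNG or (multi-page) TIFF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
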