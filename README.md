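# kcfdo

Contrast enhancement of low-contrast grayscale radiographs (X-ray, CT,
panoramic dental images) with a **k-Caputo fractional differential
operator**, plus the k-symbol special-function and fractional-calculus
machinery behind it.

Raw radiographs often have a compact intensity histogram: soft tissue
occupies a narrow band, fine structure is hard to see, and global
histogram equalization can over-amplify noise. The operator implemented
here rescales each pixel by a fractional power of its *probability* under
the image's global histogram, which stretches the populated part of the
histogram while leaving the gray-level ordering intact.

## The operator

For an input image \(I(i,j)\) with intensities in \([0,1]\), let
\(r(i,j) \in (0,1)\) be the empirical probability of pixel \((i,j)\)'s
quantized intensity under the global 256-bin histogram. The enhanced
image is

```
In(i,j) = I(i,j) · r(i,j)^(1 − ρ/k) / Γₖ(2 − ρ/k)
```

where \(\rho \in (0,1)\) is the fractional order (default 0.4), \(k \ge 1\)
is the k-symbol deformation parameter (default 2), and \(\Gamma_k\) is the
k-gamma function, \(\Gamma_k(\xi) = k^{\xi/k-1}\Gamma(\xi/k)\), satisfying
\(\Gamma_k(\xi + k) = \xi\,\Gamma_k(\xi)\). The raw output is mapped back
to display range by a min–max stretch (configurable).

The form of the gain comes from the k-Caputo fractional derivative

```
ᶜₖD^ρ φ(ξ) = 1/(k Γₖ(m − ρ/k)) ∫₀^ξ φ⁽ᵐ⁾(ζ) (ξ − ζ)^(m − ρ/k − 1) dζ ,   m − 1 < ρ < m
```

whose magnitude, for convex φ on the unit disk, is bounded by
\(r^{1-\rho/k}\,\Xi_k^{1,1-\rho/k}(r)\) with the K-Mittag-Leffler series
\(\Xi_k^{\alpha,\beta}(\xi) = \sum_n \xi^n / (n!\,\Gamma_k(n\alpha+\beta))\).
All of these are exported: `k_gamma()`, `k_pochhammer()`,
`k_mittag_leffler()`, `k_caputo_derivative()`, `k_fractional_integral()`,
`caputo_bound()`.

## Worked example

```r
library(kcfdo)

img      <- generate_phantom(phantom_spec(seed = 42))  # 256x256 low-contrast phantom
params   <- enhance_params()                           # rho = 0.4, k = 2
enhanced <- enhance_image(img, params)
histogram_report(img, enhanced)
#> histogram report (256 bins)
#>   spread:  input 0.05511 -> enhanced 0.24665
#>   entropy: input 5.7579 -> enhanced 5.9870 bits
```

The spread line is the standard deviation of the pixel intensities: the
phantom's histogram occupies a narrow band (spread 0.055) and the enhanced
histogram is roughly 4.5× wider, with a modest entropy gain — the
signature of a successful contrast stretch on a low-contrast radiograph.

The special functions are directly usable:

```r
k_gamma(4, 2)                               # 2
k_mittag_leffler(1, alpha = 1, beta = 1, k = 1)
#> K-Mittag-Leffler value: 2.27958530233607 (11 terms, last |term| = 7.594e-14)
caputo_bound(0.5, rho = 0.4, k = 2)         # 0.7489538
```

## Command line

A thin shell entry point is installed at `inst/cli/kcfdo`
(`system.file("cli", "kcfdo", package = "kcfdo")`):

```sh
kcfdo phantom --seed 3 --out phantom.png
kcfdo enhance phantom.png --out enhanced.png --rho 0.4 --k 2
kcfdo sweep phantom.png --out sweep.csv --rho-min 0.1 --rho-max 0.9 --step 0.1
kcfdo report phantom.png enhanced.png --out report.json
```

Every run logs the effective parameter set to stderr; outputs are written
atomically. Flags override a `--config` JSON file, which overrides the
built-in defaults.

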