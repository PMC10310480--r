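# Independent oracles used across the suite. These deliberately share no
# code path with the package implementation: direct term-by-term sums with
# explicit factorial/gamma ratios, no log-space tricks.

# brute-force K-Mittag-Leffler partial sum (direct double summation)
ml_brute_force <- function(xi, alpha, beta, k, n_terms = 80L) {
  kg <- function(z) k^(z / k - 1) * gamma(z / k)
  total <- 0
  for (n in seq.int(0L, n_terms)) {
    total <- total + xi^n / (factorial(n) * kg(n * alpha + beta))
  }
  total
}

# closed-form k-Caputo derivative of the monomial phi(x) = x^p for
# non-integer order rho with m = ceiling(rho) <= p:
#   (p!/(p-m)!) * B(p - m + 1, m - rho/k) * xi^(p - rho/k) /
#   (k * Gamma_k(m - rho/k))
monomial_caputo <- function(p, rho, k, xi) {
  m <- ceiling(rho)
  kg <- function(z) k^(z / k - 1) * gamma(z / k)
  fall <- factorial(p) / factorial(p - m)
  fall * beta(p - m + 1, m - rho / k) * xi^(p - rho / k) /
    (k * kg(m - rho / k))
}

# a tiny deterministic test image away from degenerate histograms
fixture_image <- function() {
  matrix(c(0, 0, 0.5, 1, 0.25, 0.5, 0.75, 0.5, 0.125,
           0.25, 0.5, 0.625), nrow = 3)
}
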