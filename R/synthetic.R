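#' Phantom recipe for low-contrast radiograph emulation
#'
#' A seeded specification of a synthetic test image emulating the features
#' of real low-contrast radiographs that the enhancement operator targets:
#' a compact intensity histogram (soft-tissue background confined to a
#' narrow band), a handful of brighter bone-like elliptical structures, a
#' mild radial vignette, and additive sensor noise. Everything is
#' determined by `seed`: the same spec always yields a bit-identical
#' phantom.
#'
#' Random structure placement draws from documented ranges (uniform unless
#' stated): ellipse centers inside the central 80% of the field; semi-major
#' axis 5–15% and semi-minor axis 1.5–6% of the shorter image side (so
#' structures range from blobs to elongated rods); orientation on
#' \eqn{[0, \pi)}. The background is a linear ramp in a random direction
#' plus a low-frequency sinusoidal modulation, affinely confined to
#' `background_band`.
#'
#' @param seed Integer seed; drives a Mersenne-Twister stream with
#'   inversion normals, fixed explicitly so phantoms are stable across
#'   platforms and R sessions.
#' @param height,width Image dimensions in pixels.
#' @param background_band Numeric `(low, high)` with `low < high`: the
#'   intensity band confining the soft-tissue background.
#' @param n_structures Number of bright bone-like structures.
#' @param structure_contrast Additive intensity of a structure above the
#'   background.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param vignette_strength Strength in `[0, 1)` of the radial
#'   multiplicative vignette (0 disables it).
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(seed = 0L, height = 256L, width = 256L,
                         background_band = c(0.35, 0.55),
                         n_structures = 5L, structure_contrast = 0.12,
                         noise_sigma = 0.01, vignette_strength = 0.15) {
  stopifnot(length(seed) == 1L, is.numeric(seed), seed == round(seed),
            height >= 1, width >= 1,
            length(background_band) == 2L,
            background_band[1] < background_band[2],
            background_band[1] >= 0, background_band[2] <= 1,
            n_structures >= 0, n_structures == round(n_structures),
            noise_sigma >= 0,
            vignette_strength >= 0, vignette_strength < 1)
  structure(list(seed = as.integer(seed), height = as.integer(height),
                 width = as.integer(width),
                 background_band = as.numeric(background_band),
                 n_structures = as.integer(n_structures),
                 structure_contrast = structure_contrast,
                 noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength),
            class = "phantom_spec")
}

#' Generate a low-contrast radiograph phantom
#'
#' Renders the [phantom_spec()] recipe: background ramp confined to the
#' background band, multiplied by the radial vignette, with bright
#' elliptical structures added at `structure_contrast`, plus additive
#' Gaussian noise, finally clipped to \[0, 1\]. Structures pushing above 1
#' are clipped, never an error.
#'
#' @param spec A `"phantom_spec"`.
#' @return Numeric matrix (`height` x `width`) with values in \[0, 1\].
#' @examples
#' img <- generate_phantom(phantom_spec(seed = 1))
#' range(img)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  h <- spec$height
  w <- spec$width
  lo <- spec$background_band[1]
  hi <- spec$background_band[2]

  # normalized coordinates in [0,1]; row-major grid, origin top-left
  y <- matrix(seq(0, 1, length.out = h), h, w)
  x <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)

  # linear ramp in a random direction + low-frequency sinusoid,
  # affinely mapped into the central 90% of the background band
  theta <- stats::runif(1, 0, 2 * pi)
  phase <- stats::runif(2, 0, 2 * pi)
  field <- cos(theta) * x + sin(theta) * y +
    0.25 * sin(2 * pi * x + phase[1]) * sin(2 * pi * y + phase[2])
  frng <- range(field)
  s <- if (frng[2] > frng[1]) (field - frng[1]) / (frng[2] - frng[1])
       else matrix(0.5, h, w)
  img <- lo + (hi - lo) * (0.05 + 0.9 * s)

  # radial vignette: multiplicative falloff toward the corners
  if (spec$vignette_strength > 0) {
    d2 <- ((x - 0.5)^2 + (y - 0.5)^2) / 0.5
    img <- img * (1 - spec$vignette_strength * d2)
  }

  # bright bone-like ellipses / rods
  if (spec$n_structures > 0) {
    side <- min(h, w)
    for (i in seq_len(spec$n_structures)) {
      cx <- stats::runif(1, 0.1, 0.9)
      cy <- stats::runif(1, 0.1, 0.9)
      a <- stats::runif(1, 0.05, 0.15) * side / max(h, w)
      b <- stats::runif(1, 0.015, 0.06) * side / max(h, w)
      ang <- stats::runif(1, 0, pi)
      dx <- x - cx
      dy <- y - cy
      u <- cos(ang) * dx + sin(ang) * dy
      v <- -sin(ang) * dx + cos(ang) * dy
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[inside] <- img[inside] + spec$structure_contrast
    }
  }

  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a suite of phantoms with consecutive seeds
#'
#' @param base_spec A `"phantom_spec"`; element `i` of the suite uses seed
#'   `base_spec$seed + i - 1` with all other fields unchanged.
#' @param n Number of phantoms (`>= 1`).
#' @return List of `n` image matrices.
#' @export
generate_suite <- function(base_spec = phantom_spec(), n) {
  stopifnot(inherits(base_spec, "phantom_spec"),
            length(n) == 1L, n >= 1, n == round(n))
  lapply(seq_len(n) - 1L, function(i) {
    s <- base_spec
    s$seed <- base_spec$seed + i
    generate_phantom(s)
  })
}
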