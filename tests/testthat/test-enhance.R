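test_that("pixel probabilities come from the global histogram", {
  img <- matrix(c(0, 0, 0.5, 1), 2, 2)
  pm <- pixel_probability_map(img, n_bins = 256L)
  expect_equal(pm$r[img == 0], c(0.5, 0.5))
  expect_equal(pm$r[img == 0.5], 0.25)
  expect_equal(pm$r[img == 1], 0.25)
  expect_equal(sum(pm$bin_probs), 1)

  # constant image: single occupied bin, raw probability 1 clamps down
  const <- matrix(0.4, 4, 5)
  pmc <- pixel_probability_map(const, epsilon = 1e-6)
  expect_true(all(pmc$r == 1 - 1e-6))
  expect_equal(sum(pmc$bin_probs), 1)

  expect_error(pixel_probability_map(matrix(numeric(0), 0, 0)),
               "non-empty")
})

test_that("the fractional gain matches an independent log-space recomputation", {
  params <- enhance_params()            # rho = 0.4, k = 2
  expect_equal(1 - params$rho / params$k, 0.8)

  img <- fixture_image()
  pm <- pixel_probability_map(img)
  g <- kcfdo_gain(pm, params)
  ref <- exp(0.8 * log(pm$r)) / (2^(-0.1) * gamma(0.9))
  expect_equal(g, ref, tolerance = 1e-12)

  # gain at r ~ 1 is 1 / Gamma_2(1.8) ~ 1.0029
  g1 <- kcfdo_gain(matrix(1 - 1e-6, 1, 1), params)
  expect_equal(g1[1], 1 / (2^(-0.1) * gamma(0.9)), tolerance = 1e-4)
  expect_equal(g1[1], 1.0029, tolerance = 1e-3)

  # strictly increasing in r
  r <- matrix(seq(0.01, 0.99, length.out = 50), 1)
  expect_true(all(diff(kcfdo_gain(r, params)[1, ]) > 0))
})

test_that("enhancement reproduces the worked 2x2 example by hand", {
  img <- matrix(c(0, 0, 0.5, 1), 2, 2)
  params <- enhance_params(rescale = "none")
  out <- enhance_image(img, params)
  gamma_k <- 2^(-0.1) * gamma(0.9)      # Gamma_2(1.8)
  expect_equal(out[img == 0], c(0, 0), tolerance = 1e-12)
  expect_equal(out[img == 0.5], 0.5 * 0.25^0.8 / gamma_k,
               tolerance = 1e-12)
  expect_equal(out[img == 1], 0.25^0.8 / gamma_k, tolerance = 1e-12)
})

test_that("enhancement honors its output contracts", {
  img <- generate_phantom(phantom_spec(seed = 7))

  # constant images pass through untouched
  const <- matrix(0.3, 8, 8)
  expect_identical(enhance_image(const), const)

  # range contract and shape preservation
  for (rescale in c("minmax", "clip")) {
    out <- enhance_image(img, enhance_params(rescale = rescale))
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 1))
  }

  # determinism
  expect_identical(enhance_image(img), enhance_image(img))

  # equal input intensities map to equal outputs
  out <- enhance_image(img)
  groups <- tapply(as.vector(out), as.vector(img),
                   function(v) diff(range(v)))
  expect_true(all(groups == 0))

  # permuting pixels permutes outputs identically (histogram is global)
  perm <- sample(length(img))
  shuffled <- matrix(as.vector(img)[perm], nrow(img), ncol(img))
  out_shuffled <- enhance_image(shuffled)
  expect_equal(as.vector(out_shuffled), as.vector(out)[perm],
               tolerance = 1e-15)
})

test_that("raw rescale mode warns when intensities leave the display range", {
  # a nearly-constant bright image: r ~ 1 so gain > 1 pushes values past 1
  img <- matrix(1, 32, 32)
  img[1] <- 0.5
  expect_warning(enhance_image(img, enhance_params(rescale = "none")),
                 "exceed 1")
})

test_that("histogram reports capture the contrast spread", {
  img <- fixture_image()
  rep_id <- histogram_report(img, img)
  expect_equal(rep_id$spread_input, rep_id$spread_enhanced)
  expect_equal(sum(rep_id$counts_input), length(img))
  expect_equal(sum(rep_id$counts_enhanced), length(img))

  const <- matrix(0.25, 4, 4)
  rep_c <- histogram_report(const, const)
  expect_equal(rep_c$spread_input, 0)
  expect_equal(rep_c$entropy_input, 0)

  phantom <- generate_phantom(phantom_spec(seed = 3))
  rep_p <- histogram_report(phantom, enhance_image(phantom))
  expect_gt(rep_p$spread_enhanced, rep_p$spread_input)

  expect_error(histogram_report(img, matrix(0.5, 2, 2)), "shape")
})

test_that("low-contrast phantoms gain spread in every seeded case", {
  suite <- generate_suite(phantom_spec(seed = 0), n = 20)
  gains <- vapply(suite, function(img) {
    rep <- histogram_report(img, enhance_image(img))
    rep$spread_enhanced > rep$spread_input
  }, logical(1))
  expect_true(all(gains))
})

test_that("fractional-order sweeps are deterministic and well-formed", {
  img <- generate_phantom(phantom_spec(seed = 11, height = 64, width = 64))
  rhos <- seq(0.1, 0.9, by = 0.1)
  sw <- rho_sweep(img, rhos, metric = "entropy")
  expect_s3_class(sw, "rho_sweep")
  expect_equal(nrow(sw), 9L)
  expect_equal(sw$rho, rhos)
  expect_true(all(is.finite(sw$score)))
  expect_true(attr(sw, "best_rho") %in% rhos)
  expect_identical(attr(sw, "polarity"), "higher_better")

  # two runs agree bit for bit (no randomness in the pipeline)
  expect_identical(sw, rho_sweep(img, rhos, metric = "entropy"))

  # singleton sweep
  single <- rho_sweep(img, 0.4)
  expect_equal(nrow(single), 1L)
  expect_equal(attr(single, "best_rho"), 0.4)

  # lower-is-better polarity flips the argbest
  swn <- rho_sweep(img, rhos, metric = "neg_entropy")
  expect_equal(attr(swn, "best_rho"), attr(sw, "best_rho"))

  expect_error(rho_sweep(img, rhos, metric = "brisque"), "unknown metric")
  expect_error(rho_sweep(img, c(0.5, 0.2)), "strictly increasing")
  expect_error(rho_sweep(img, c(0.2, 1.5)), "inside")
})

test_that("sweep and report serialization round-trip through disk", {
  img <- generate_phantom(phantom_spec(seed = 2, height = 32, width = 32))
  sw <- rho_sweep(img, c(0.2, 0.4, 0.6))
  csv <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$rho, sw$rho)
  expect_equal(back$score, sw$score, tolerance = 1e-12)

  rep <- histogram_report(img, enhance_image(img))
  js <- tempfile(fileext = ".json")
  write_report_json(rep, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$spread_enhanced, rep$spread_enhanced,
               tolerance = 1e-12)
  expect_equal(sum(parsed$counts_input), length(img))
  unlink(c(csv, js))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(enhance_params(rho = 1.5), "inside")
  expect_error(enhance_params(rho = 0), "inside")
  expect_error(enhance_params(k = 0.5), ">= 1")
  expect_error(enhance_params(n_bins = 1), ">= 2")
  expect_error(enhance_params(epsilon = 0.7), "epsilon")
  expect_error(enhance_params(rescale = "stretch"))
})
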