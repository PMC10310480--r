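Package: kcfdo
Title: X-Ray Image Contrast Enhancement with the k-Caputo Fractional
    Differential Operator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contrast enhancement of low-contrast grayscale radiographs
    using a k-symbol fractional calculus operator. Provides the k-gamma
    function, k-Pochhammer symbol and K-Mittag-Leffler series; numerical
    evaluation of the k-Caputo fractional derivative and the k-fractional
    integral of smooth one-dimensional functions; the associated
    Mittag-Leffler upper bound on the derivative of convex functions; a
    pixel-probability enhancement operator driven by the global intensity
    histogram; no-reference quality metrics with a pluggable registry;
    a seeded generator of low-contrast radiograph-like phantoms; and
    grayscale PNG/TIFF/JPEG input/output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
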