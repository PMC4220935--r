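Package: ivuscalc
Title: Detection of Calcified Plaque with Acoustic Shadowing in
    Intravascular Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine detection of calcified plaque with acoustic
    shadowing in intravascular ultrasound (IVUS) frames. Pixels are
    clustered with a Rayleigh mixture model fitted by an EM algorithm
    whose priors encode neighbourhood structure; the angular location of
    the plaque is found by sum-product belief propagation on a one
    dimensional Markov random field over polar-image columns; candidate
    arcs are screened by five anatomical constraints; and the leading and
    trailing plaque borders are traced by free-endpoint minimal-cost path
    search on gradient cost grids. Ships a seeded synthetic speckle
    phantom generator and the full evaluation stack (plaque measurements,
    sensitivity/specificity, linear regression, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
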