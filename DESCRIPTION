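Package: dognorm
Title: Divisively Normalized Difference-of-Gaussians Model of ON/OFF
    Contrast Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements a spatial contrast-encoding model of early visual
    ON/OFF responses: a difference-of-Gaussians (center-surround) linear
    filter divided by a broader Gaussian estimate of local luminance, with
    half-wave rectification splitting the signed output into ON (bright)
    and OFF (dark) channels.  Provides stimulus rasterization (disks and
    squares in Weber contrast on uniform backgrounds), closed-form
    continuous-limit oracles for both stimulus classes, population sweeps
    over a canonical 42-unit parameter family with derived statistics
    (contrast response functions, nonlinearity indices, OFF/ON response
    ratios, luminance half-saturation L50 and maximal response Rmax across
    background levels), a Naka-Rushton-style cone adaptation model
    re-expressed in temporal Weber contrast, and reproducible CSV/JSON
    report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
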