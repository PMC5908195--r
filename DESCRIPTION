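Package: cytocascade
Title: Bulk-Surface Reaction-Diffusion Models of Membrane-Cytosolic Signaling Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models protein-kinase signaling cascades whose components are
    split between the cell membrane and the cytosol, as bulk-surface
    reaction-diffusion systems. Provides closed-form steady states on
    spherical cells (modified spherical Bessel solutions for the mixed
    membrane-cytosolic cascade, exponential-polynomial expansions for the
    pure cytosolic cascade, and spherical-harmonic mode solutions for graded
    stimuli), surface-to-volume scale diagnostics (gradient length, Thiele
    modulus, the membrane-source/cytosolic-sink average-concentration
    estimator, variance-propagation constants), well-mixed ODE reductions
    for spatial averages with signaling-time and Goodwin-type instability
    analysis, a radial method-of-lines solver for spheres and discs with
    Robin membrane coupling, local accumulation times, and FFT-based
    oscillation metrics including cell-size extinction sweeps for
    negative-feedback cascades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
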