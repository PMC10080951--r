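Package: perisum
Title: Spatiotemporal Summation Modeling for Perimetric Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models differential light sensitivity for perimetric (white-on-white)
    stimuli as a function of stimulus size, duration, retinal ganglion cell (RGC)
    mosaic density and cone-to-RGC convergence. Implements a simulated retinal
    front end (hexagonal cone and parasol-OFF RGC mosaics, difference-of-Gaussians
    receptive fields, mean human optical modulation transfer function applied in
    the Fourier domain), a capacitor-style spatiotemporal pooler that predicts
    sensitivity from the total retinal input, fitting of the integration constant
    by Nelder-Mead on RMSE, and the critical-size (Ricco's area) and critical-
    duration machinery based on the slope-0.5 criterion. Also provides simulators
    and fitting for the supporting psychophysical procedures: ZEST and QUEST+
    Bayesian adaptive strategies, method-of-constant-stimuli designs, hierarchical
    frequency-of-seeing curve fitting, and synthetic observers for end-to-end
    validation without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rjags
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
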