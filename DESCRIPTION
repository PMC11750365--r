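Package: herbcomp
Title: Two-Species Plant Competition with a Shared Herbivore
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling two competing plant species that share a
    single herbivore, in the style of the duckweed-algae-snail freshwater
    system. Implements the Lotka-Volterra competition model with a constant
    herbivore consumption term, an event-aware adaptive Runge-Kutta
    integrator, zero-growth isoclines, invasion growth rates and the
    analytic condition under which herbivory raises the focal species'
    fitness, outcome classification by mutual invasibility, estimation of
    all competition and consumption coefficients from density-gradient and
    feeding assays with percentile bootstrap confidence intervals, an
    optical-density calibration helper, a synthetic-data generator with a
    controlled noise model for end-to-end validation, and a command-line
    pipeline tying generation, estimation and prediction together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
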