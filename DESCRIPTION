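Package: raospace
Title: Rao's Spacing Test for Continuous and Rounded Circular Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests of circular uniformity based on Rao's spacing statistic.
    Provides the traditional test against the Russell & Levitin critical-value
    table, a Monte Carlo test for continuously measured angles, and a
    perturbation-based randomization test for angles that have been rounded or
    grouped into a finite number of equal divisions of the circle (for example
    to the nearest degree), where the traditional critical values no longer
    control the type I error rate. Includes seedable circular samplers
    (uniform, von Mises, wrapped skew-normal), a simulation harness for type I
    error and power studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
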