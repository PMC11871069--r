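Package: distrem
Title: Hybrid Distance-Sampling and Time-Removal Models for Avian Point Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian inference for avian
    point-count surveys that record both the distance class and the
    time-removal interval of every detection. Provides a synthetic-data
    generator with a superpopulation / presence / availability /
    perceptibility hierarchy, a single-season model combining half-normal
    distance sampling with geometric time-removal availability, a multi-year
    extension with a stationary AR(p) abundance process and refuge random
    effects, a scenario harness for bias and coverage assessment, and a
    coefficient-of-variation based calculator for the number of point counts
    a survey requires.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    rjags,
    coda,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
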