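Package: layerlux
Title: Radiative Transport in Layered Turbid and Fluorescent Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models for photon migration in layered turbid and
    fluorescent media. Provides a spherical-harmonics (PN) solution of the
    radiative transport equation for plane-parallel layered media with
    Fresnel index-mismatched boundary and interface conditions, formulated
    in the spatial-frequency/Laplace domain and numerically transformed to
    the spatial steady-state, temporal-frequency, and time domains; a
    layered diffusion-equation comparator sharing the same transform stack;
    coupled excitation/emission solutions for fluorescence; and an analog
    (unweighted) Monte Carlo photon-transport simulator with exact photon
    accounting that serves as the internal validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
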