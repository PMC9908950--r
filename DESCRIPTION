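Package: heliscat
Title: Helicity-Resolved Backscattering Polarimetry of Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for polarization-resolved light scattering in turbid
    microsphere suspensions. Computes exact Mie single-sphere Mueller
    matrices, scattering efficiencies and anisotropy factors; transports
    circularly polarized Gaussian beams through non-absorbing scattering
    media with a compiled Stokes-vector Monte Carlo engine using
    meridian-plane polarization bookkeeping; separates backscattered light
    into helicity-flipped and helicity-preserved images; and derives
    radial-profile statistics and the spatial helicity response metric
    (SHRM) that jointly quantifies average scatterer size and scattering
    coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    tiff
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
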