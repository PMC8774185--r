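Package: bundlesans
Title: Small-Angle Neutron Scattering Analysis of Helix-Bundle Protein Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solution-structure analysis of 1D small-angle neutron scattering
    (SANS) curves aimed at helix-bundle proteins and their unfolding
    intermediates. Provides model-free analyses (Guinier fits, Debye
    random-coil fits, Kratky transforms with fold-state classification,
    I(0)-based molecular-weight ratios, and a two-population aggregate
    estimate), a regularized indirect Fourier transform to the pair-distance
    distribution P(r), theoretical neutron curves from atomic coordinates via
    a contrast-weighted Debye sum, helix-axis geometry, a Monte-Carlo
    "joint-clubs" form factor of jointed rigid cylinders with least-squares
    fitting, a synthetic-data generator with realistic counting noise, and a
    per-condition pipeline that assigns solution states from the combined
    evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
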