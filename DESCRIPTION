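Package: oligomind
Title: Monoisotopic Mass Prediction for Oligonucleotides from the
    Most-Abundant Isotopic Peak
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the monoisotopic mass of DNA and RNA oligonucleotides
    from the mass of the most-abundant peak of their aggregated isotopic
    distribution, as observed in deconvoluted high-resolution mass spectra.
    Implements a polynomial-recurrence isotope engine for aggregated isotope
    probabilities and center masses, exhaustive enumeration of the
    oligonucleotide composition universe, a two-stage piecewise-linear
    predictor with optimal-Bayes branch boundaries, an average-mass-based
    correction for mispicked most-abundant peaks, and in-silico validation
    tools including uniform intensity noise and finite ion-count simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
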