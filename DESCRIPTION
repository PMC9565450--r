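Package: sizecycle
Title: Stochastic Gene Expression Coupled to Cell Growth, Division and
    Size Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the fluctuations of gene product numbers and
    concentrations in growing and dividing cells.  Cell cycle progression
    is described by N effective stages with volume-dependent transition
    rates (power-law size control that may change at gene replication),
    gene expression by volume-dependent bursty synthesis with gene dosage
    compensation, and division by binomial partitioning.  Provides an
    exact event-driven simulator of the full model, a piecewise mean-field
    reduced model with closed-form factorial-moment recursions, gamma and
    negative-binomial mixture approximations of the concentration and
    copy-number distributions for lineage and population measurements,
    analytic autocorrelation functions and power spectra of concentration
    fluctuations, concentration-homeostasis metrics, and estimators for
    single-cell lineage time series.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
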