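Package: sfsmix
Title: Subclonal Deconvolution from the Site Frequency Spectrum with
    Beta-Pareto Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based subclonal deconvolution of bulk tumour whole-genome
    sequencing data. Fits the site frequency spectrum of somatic mutations with
    a finite mixture of one optional Pareto Type-I tail, capturing within-clone
    neutral evolutionary dynamics, and k >= 1 Beta components, capturing clonal
    and subclonal expansions under positive selection. Model selection over the
    number of Beta components and the presence of the tail uses
    entropy-regularised information criteria (ICL and reduced ICL). Includes
    parametric and non-parametric bootstrap for model confidence, parameter
    confidence intervals and pairwise co-clustering stability; post-clustering
    estimation of evolutionary parameters (mutation rate, subclone age in
    tumour doublings, selection coefficient); a stochastic branching-process
    tumour simulator with sequencing noise for synthetic benchmarking; and
    plotting utilities for fits, scores, entropy profiles, latent variables and
    bootstrap output.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    ggplot2,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
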