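Package: bayberry
Title: Coalescent Simulation and Demographic Inference for Chinese Bayberry
    Domestication
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the domestication history of Chinese bayberry
    (Morella rubra) from sparse RAD-seq style SNP panels. Implements a
    multi-population structured coalescent simulator with divergence and
    admixture-pulse events, site-frequency-spectrum (SFS) construction with
    hypergeometric projection and folding, composite-likelihood demographic
    inference with multi-start Nelder-Mead optimisation and parametric
    bootstrap confidence intervals, Weir-Cockerham and Hudson F_ST,
    nucleotide diversity, LD pruning, ancestry-coefficient estimation under
    the ADMIXTURE model via EM, neighbor-joining distance trees, and an
    end-to-end seeded analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
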