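Package: altiscan
Title: Comparative Selection Scans for High-Altitude Adaptation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative molecular-evolution and population-genetic
    selection scans of the kind used to study parallel adaptation to high
    altitude. Implements reciprocal-best-hit ortholog inference with a small
    built-in translated aligner, codon-alignment quality control (stop-codon
    and length checks, gap trimming, NG86 synonymous-saturation filtering),
    Goldman-Yang codon substitution models with Felsenstein pruning
    likelihoods, branch and branch-site model fits and likelihood ratio tests
    for positive selection, bootstrap comparison of branch-specific dN/dS,
    gene-category rate statistics and over-representation tests, SNP calling
    from read counts with tag-SNP selection, and a hierarchical Bayesian
    FST outlier scan (beta-binomial island model with reversible-jump MCMC,
    posterior-based q-values and selection-type classification). Synthetic
    data generators with known truth make every stage testable without
    sequencing data, and a pipeline driver runs the full analysis
    reproducibly from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
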