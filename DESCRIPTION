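Package: coevoscan
Title: Intramolecular Coevolution Scans for Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects networks of coevolving sites around a focal residue in a
    protein-coding gene by combining three independent lines of phylogenetic
    evidence: codon site-class models of dN/dS (M-series and Clade Model C)
    fitted by maximum likelihood with likelihood-ratio and AIC comparison and
    empirical-Bayes site classification; weighted, average-product-corrected
    mutual information between alignment columns with a randomized-dataset
    significance cutoff; and Pagel-type tests of correlated evolution between
    binary residue traits with Monte-Carlo p-values. Also provides codon-based
    marginal ancestral reconstruction, inter-residue distance filtering on a
    protein structure, visual-pigment absorbance template fitting, and
    retinal-release kinetics fitting, together with simulators for every input
    so the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
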