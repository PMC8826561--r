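Package: polyorigins
Title: Coalescent Simulation and Approximate Bayesian Inference of Polyploid Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the mode and history of polyploid origin from
    multilocus phased sequence data, motivated by mixed-ploidy anuran complexes
    such as the gray treefrogs. Provides polyploid-aware data processing (ploidy
    classification from phased-allele distances, MIN/MAX subgenome assignment,
    flank-filtered SNP extraction), a structured-coalescent simulator of
    autopolyploid and allopolyploid speciation scenarios with tetrasomic,
    disomic or heterosomic inheritance and interploid migration, mscalc-style
    multilocus summary statistics, approximate Bayesian computation model
    choice and parameter estimation with neural-network regression adjustment,
    Bayes-factor model probabilities from log-marginal likelihoods, and a
    site-frequency-spectrum diagnostic of chromosomal inheritance mode. A
    synthetic-study generator produces truth-labelled phased alignments so the
    whole pipeline is testable without sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    nnet,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
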