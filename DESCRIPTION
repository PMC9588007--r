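Package: phylopotts
Title: Potts Model Sequence Simulation, Coupling Inference and
    Phylogeny-Aware Contact Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how phylogenetic correlations in protein
    multiple sequence alignments (MSAs) affect coevolution-based contact
    inference.  Provides Potts (direct coupling analysis) models with exact
    Boltzmann distributions on small instances, Metropolis-Hastings sampling
    of synthetic MSAs either independently at equilibrium or along
    phylogenetic trees, pseudo-likelihood inference of fields and couplings,
    zero-sum gauge fixing, Frobenius-norm coupling scores with the average
    product correction, and ROC-AUC based evaluation of contact recovery
    including the relative performance drop caused by phylogeny.  Also
    implements fractional-logit (quasi-likelihood) regression of pairwise
    Hamming distances on column-attention features from MSA language models,
    together with synthetic attention-tensor generators that allow the whole
    pipeline to be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
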