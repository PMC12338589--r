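Package: epocr
Title: Ancestry Inference for Eukaryotic Protein Families from Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the most likely prokaryotic sister clade of eukaryotic
    protein families from labelled gene trees using constrained-topology
    hypothesis testing scored by Expected Likelihood Weights (RELL
    bootstrap over per-site log-likelihoods), with taxonomy-aware
    preprocessing (soft-core pangenome filtering, information-content
    alignment trimming, log-normal long-branch pruning, weighted midpoint
    rooting, soft-LCA clade detection), average-ELW aggregation over
    functional categories, and normalized stem-length statistics for
    relative-timing analysis. Includes a seeded synthetic-data generator
    that plants a eukaryotic clade with a known prokaryotic sister so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
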