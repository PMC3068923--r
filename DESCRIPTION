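Package: consensusOR
Title: Consensus-Phenotype Inter-Omic Pathway Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates transcriptomic and metabolomic profiles with
    drug-sensitivity phenotypes at the pathway level. Features are
    correlated to per-drug -log(GI50) phenotypes, significant panels are
    selected by Benjamini-Hochberg false discovery rate, per-pathway
    over-representation is tested with the hypergeometric distribution
    against effective pathway sizes in each omic namespace, and the
    gene- and metabolite-based p-values are combined into a joint
    inter-omic probability. Pathways associated with a majority of
    phenotypes in a drug class form the consensus set; two null models
    (resampled feature lists and analytic Poisson-binomial pathway
    selection) and a permutation test quantify false-discovery behaviour.
    Includes a global drug-by-pathway binary association profile with
    complete-linkage Hamming clustering, and a synthetic multi-omic
    panel generator with planted pathway signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
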