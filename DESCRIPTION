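Package: mhbcircuit
Title: Boolean Regulatory Circuits from Tripartite Mycorrhizal Community Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Turns root RNA-seq alignments from plant-fungus-bacterium
    laboratory communities into a Boolean regulatory-circuit model of
    mycorrhiza-helper-bacteria activity. Provides bootstrapped RPKM
    quantification of multi-mapped metatranscriptome reads with
    expression-significance calls and quantile normalization, two-factor
    permutation ANOVA over the 2x2 community design, K-means co-expression
    clustering with silhouette model selection, cumulative hypergeometric
    GO enrichment, constrained greedy Bayesian-network structure learning
    with transitive pruning, Boolean logic-gate fitting (including XOR
    detection), per-organism read-attribution summaries, and a synthetic
    tripartite-experiment generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    limma,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
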