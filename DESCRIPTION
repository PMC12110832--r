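Package: icplnc
Title: Network-Based Identification of Immune-Checkpoint-Related lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies long non-coding RNAs (lncRNAs) associated with immune
    checkpoint (ICP) genes from bulk expression profiles using a four-stage
    network framework: ICP-anchored Pearson co-expression network construction
    with Benjamini-Hochberg control, personalized PageRank propagation seeded
    at ICP genes, tumor-purity-adjusted partial correlation ranking, and a
    pre-ranked GSEA enrichment score converted to a signed significance score
    (lncRES) with permutation p-values and FDR filtering. Includes downstream
    utilities (Spearman association with immune infiltration scores, linear
    risk scoring with median split and log-rank evaluation, RECIST response
    labeling), a synthetic-data generator with planted ground truth for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
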