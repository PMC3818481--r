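Package: phyllopart
Title: Replicate-Aware Partitioning of Phyllosphere Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions bacterial OTUs from replicated phyllosphere
    amplicon surveys into transient, resident, core and plant
    line-specific categories from presence/absence across biological
    replicates, and provides the supporting community statistics:
    Jaccard and Euclidean distances, rank-based analysis of similarity
    (ANOSIM) and Mantel permutation tests, nonmetric multidimensional
    scaling with Kruskal stress-1 and isotonic regression, UPGMA and
    complete-linkage clustering with Newick export, rarefaction and
    alpha-diversity estimators (Shannon, Simpson, Pielou, Chao1, ACE),
    plus a synthetic community generator with planted ground truth for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
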