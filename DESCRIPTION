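Package: gutcatkit
Title: Gut Metagenome Gene-Catalog Construction, Profiling and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for shotgun gut-metagenome analysis built around a
    non-redundant gene catalog: greedy dereplication of predicted genes at
    95% identity / 90% overlap, length-normalized relative-abundance
    profiling with aggregation to genus and KEGG-orthology (KO) profiles,
    incidence-based Chao1 rarefaction, enterotype-like clustering of genus
    profiles by Jensen-Shannon distance and partitioning around medoids,
    Wilcoxon/Benjamini-Hochberg differential abundance, reporter-score
    pathway enrichment with a random-set background null, and cross-host
    catalog comparison. Ships a synthetic-community simulator with planted
    ground truth (gene sharing between hosts, redundant sequence variants,
    diet effects, enterotype structure) so every stage is testable end to
    end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
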