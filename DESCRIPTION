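Package: treebard
Title: Tree-Based Amplicon Read Diet Analysis from Fecal Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for diet analysis from COI minibarcode
    metabarcoding of fecal samples. Covers read trimming and length
    filtering, greedy abundance-aware clustering, de novo (bimera) chimera
    detection on pooled samples, maximum-likelihood placement of query
    clusters on a fixed reference phylogeny with jplace input/output,
    pendant-branch-length outlier filtering for taxonomic identification,
    concordance scoring of tree-based against database identifications,
    and read-count-based diet quantification (OTU tables, Shannon
    diversity, Jaccard beta diversity, group comparisons). Includes a
    seed-deterministic simulator of reference databases and fecal-sample
    read sets with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    phangorn,
    optparse
Config/testthat/edition: 3
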