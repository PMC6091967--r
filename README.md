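# treebard

Tree-based amplicon read diet analysis from fecal COI metabarcoding.

`treebard` is an R package for diet analysis from fecal samples
sequenced with COI minibarcodes (~130 bp fragments of the standard
barcode, amplifiable from degraded DNA). It was developed around the
diet of a small semi-aquatic insectivore preying on freshwater
macroinvertebrates, but the pipeline is generic. It takes demultiplexed
single-end reads (FASTQ, one file per sample) and a reference database
(alignment + species-level taxonomy + phylogeny of candidate prey) and
produces per-sample OTU read-count tables and diversity statistics.

## The method

Fecal amplicons mix true prey with decomposers, gut flora and
environmental DNA. Instead of relying on database similarity searches
alone, `treebard` identifies query clusters *phylogenetically*:

1. Reads are primer-trimmed (one mismatch allowed), length-filtered
   (≥ 124 bp), clustered greedily per sample at ≤ 3 mismatches with
   abundance tracking, and clusters of ≤ 10 reads are discarded.
   De novo bimera (two-parent chimera) detection runs on the pooled
   clusters of all samples.
2. Each surviving cluster representative is aligned into the fixed
   reference alignment columns and attached to **every** edge of the
   reference tree (evolutionary-placement style). Under a substitution
   model (JC69 by default) the per-edge log-likelihood
   ℓₑ is computed by Felsenstein pruning, the pendant branch length
   *p* is optimized by 1-D likelihood maximization, and per-edge
   like-weight ratios LWRₑ = exp(ℓₑ − ℓ*) / Σ exp(ℓₑ − ℓ*) are
   reported in jplace format.
3. A query is **identified** iff the best placement's pendant length is
   strictly shorter than a threshold τ taken from the reference tree
   itself: τ = the 99.9% quantile of its terminal branch-length
   distribution. Long-pendant queries are non-target outliers. The OTU
   label is the species of the nearest leaf (patristic distance from
   the attachment point, ties lexicographic).
4. Identified read counts feed OTU×sample tables, Shannon diversity
   H′ = −Σ pᵢ ln pᵢ, Jaccard beta diversity J = |A∩B|/|A∪B|, per-group
   taxon composition (Chironomidae split out of Diptera), and
   fresh-vs-old style group comparisons (rank-sum test).
5. Tree-based identifications can be scored against two external
   database identifications with a 0–18 concordance score (per pair:
   6 same species / 5 same genus / 3 same order / 1 same phylum).

A seed-deterministic simulator (`simulate_reference_db()`,
`simulate_sample()`) generates reference phylogenies with evolved
sequences and read sets with planted targets, far-outgroup contaminants
and chimeras — every stage is testable end to end against ground truth
without any downloads.

## Worked example

```r
library(treebard)

db <- simulate_reference_db(n_species = 50, seq_len = 130, seed = 11)
set.seed(301)
composition <- setNames(c(0.4, 0.25, 0.15, 0.12, 0.08),
                        sample(names(db$alignment), 5))
sim <- simulate_sample(db, composition, n_reads = 1000,
                       error_rate = 0.005, contam_frac = 0.1,
                       chimera_frac = 0.05, sample_id = "S1", seed = 1)
res <- run_pipeline(list(S1 = sim$records), db)

res$threshold
#> outlier_threshold: 99.9% quantile of 50 terminal branches = 0.1822 subst/site
res$identifications[, c("query_id", "n_reads", "status", "otu_label", "pendant_length")]
#>   query_id n_reads     status            otu_label pendant_length
#> 1  S1_c001     341 identified Genus014 aquaticus01    0.016370886
#> 2  S1_c002     212 identified Genus008 aquaticus02    0.000000000
#> 3  S1_c003     117 identified Genus007 aquaticus02    0.008115733
#> 4  S1_c004      94 identified Genus005 aquaticus01    0.016055469
#> 5  S1_c005      85 identified Genus012 aquaticus03    0.000000000
#> 6  S1_c006      50    outlier                 <NA>    0.688422572
#> 7  S1_c007      50    outlier                 <NA>    0.706372200
res$summary
#>   sample_id fresh reads_total pct_target otu_richness  shannon
#> 1        S1    NA        1000       84.9            5 1.460034
```

Reading the output: the five planted prey species come back as five
identified clusters with short pendant branches (the two zero pendants
are clusters whose representatives match a reference sequence
exactly), in read-count proportions close to the planted composition;
the two 50-read contaminant clusters attach with pendants ≈ 0.7
substitutions/site — far above the 0.18 threshold — and are rejected as
non-target outliers; the chimeric reads were removed before placement.
`pct_target` is the identified share of all 1000 reads assigned to the
sample, and H′ = 1.46 reflects a sample with reads spread over several
OTUs rather than dominated by one.

A thin command-line interface over the same functions is installed at
`system.file("cli", "treebard", package = "treebard")`, with
subcommands `preprocess`, `refdb`, `place`, `identify`, `quantify`,
`simulate` and `fixtures`.

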