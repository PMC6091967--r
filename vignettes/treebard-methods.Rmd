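---
title: "treebard: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treebard: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diet analysis from feces by metabarcoding sequences a short barcode
fragment (here a ~130 bp COI *minibarcode*, recoverable from degraded
DNA) from pooled prey remains, and must then solve three problems at
once: collapse millions of error-bearing reads into a manageable set of
amplicon clusters, decide which clusters come from target prey at all
(fecal samples collected in rivers are rich in decomposers, gut
microbiota and environmental DNA), and assign the target clusters to
taxa with read counts as a crude abundance surrogate. treebard
implements a complete desk-scale pipeline for this task built around
*tree-based identification*: each query cluster is placed by maximum
likelihood onto a fixed reference phylogeny of candidate prey species,
and the length of the branch that attaches it (the *pendant length* of
jplace files) decides whether it is a credible member of the reference
clade or a divergent non-target sequence.

The key advantage over pure database (BLAST-style) identification is
that a placement onto a tree remains informative when the exact species
is missing from the reference: the query attaches near its relatives
with a short pendant branch, and only sequences far from the whole tree
are rejected. Because the species label assigned this way may still be
wrong in detail, identified clusters are treated as OTUs rather than
confirmed species throughout.

## Pipeline stages and their rules

1. **Trimming and length filtering** (`trim_and_filter()`). The forward
   primer must match the 5' end with at most one mismatch; reads
   without a recognizable primer are dropped rather than passed through
   untrimmed. Reads shorter than `min_trimmed_len = 124` bp after
   trimming are discarded. Qualities are parsed but not used: the
   protocol is trim-then-length-filter, and quality filtering is
   intentionally absent.
2. **Greedy clustering** (`greedy_cluster()`). Per sample, reads are
   grouped into identical-sequence groups, ordered by multiplicity
   (descending, ties by first occurrence), and processed greedily: a
   group joins the *first* existing cluster whose representative is
   within `max_cluster_div = 3` mismatches, else founds a new cluster.
   Distance is Hamming over the common prefix plus the absolute length
   difference: minibarcode amplicons are near-fixed-length, so an
   ungapped comparison with a length penalty is an adequate stand-in
   for alignment, and whether indels should count inside the 3-bp
   budget is genuinely underdetermined — the convention is documented
   rather than hidden. The procedure has no randomness; identical
   inputs give identical clusters.
3. **Abundance filter** (`filter_small_clusters()`). Clusters of 10
   reads or less (`min_cluster_reads = 11`) are discarded; small
   clusters are dominated by PCR/sequencing artifacts.
4. **Chimera removal** (`detect_chimeras()`). Run on the *pooled*
   clusters of all samples, since multiplexed amplification can form
   chimeras between samples; the sample partition is restored
   afterwards. For each candidate cluster, in ascending abundance,
   potential parents are clusters with at least
   `chimera_abundance_skew = 2` times its reads. The candidate is
   flagged as a bimera iff the best two-parent splice (both segments at
   least `chimera_min_segment = 20` bp) (a) beats the best single
   parent by at least `chimera_min_advantage = 3` mismatches *and* (b)
   lies within `chimera_max_model_div = 3` mismatches of the candidate
   itself. Condition (b) is essential and easy to miss: without it,
   mutually saturated sequences (e.g. far-outgroup contaminants at ~75%
   identity to everything) get flagged by chance, because the best
   half-by-half combination of several random parents is almost always
   a few mismatches better than the best whole parent. A true bimera is
   explained by its parent mosaic up to sequencing noise, which is what
   (b) demands; de novo chimera detectors built on score models enforce
   the same idea implicitly. The search is exact: minimizing prefix and
   suffix parents independently per breakpoint either finds the true
   best pair or proves no pair can clear the advantage margin.
5. **Profile alignment** (`align_query_to_reference()`). Queries are
   aligned against the frozen reference columns (per-column base
   frequencies with a 0.02 pseudocount). Matching a base scores its
   column frequency; skipping a column costs 0.6 x column occupancy;
   dropping a query base (an insertion relative to the reference) costs
   1 and the base is discarded with a logged count, so the reference
   coordinate system never grows — a requirement for placement, and the
   reason the pipeline does not re-align the whole dataset the way a
   convenience MAFFT run would. N scores zero everywhere. A query whose
   mean per-base score falls below 0.15 is declared unalignable and
   treated downstream as non-target; the floor is set low deliberately
   so that even saturated (~25% match) contaminants still align and are
   rejected by the *pendant-length* filter, which is the designed
   mechanism, while all-N or non-nucleotide garbage fails outright.
6. **Placement** (`place_query()`). For every edge of the reference
   tree the query is attached at the edge midpoint and its pendant
   branch length is optimized on [0, 5] substitutions/site by Brent
   1-D maximization to tolerance 1e-6 (5 is beyond saturation; the
   boundary t = 0 is checked explicitly, so exact self-placements
   report pendant 0). Per-edge log-likelihoods come from Felsenstein
   pruning with per-node scaling, with conditional likelihoods at both
   ends of every edge precomputed once per reference
   (`placement_prep()`), making each query-edge evaluation O(sites).
   Like-weight ratios are softmax-normalized per query and sum to 1 by
   construction. Ties in log-likelihood break toward the smaller edge
   number. `optimize_distal = TRUE` additionally optimizes the
   attachment position by coordinate ascent; the midpoint heuristic is
   the default because at 124-130 bp the likelihood surface along the
   edge is flat relative to the pendant dimension and the speed
   difference matters.
7. **Identification** (`classify_placement()`). The outlier threshold
   is the `quantile_q = 0.999` empirical quantile of the reference
   tree's *terminal* branch lengths (`quantile_threshold()`), i.e.
   "no longer than the longest branches the reference itself
   contains". A query is identified iff the *best* placement's pendant
   length is strictly below the threshold ("shorter than"); a pendant
   exactly at the threshold is an outlier. The filter examines only the
   best placement, matching the downstream use of the first (best)
   jplace entry; alternative placements are still reported and feed the
   multi-order flag. The OTU label is the species of the leaf nearest
   to the attachment point by patristic distance, pendant edge
   excluded, ties broken lexicographically — "closest leaf" is
   topological shorthand in prose, so both the metric and the tie rule
   are fixed here.
8. **Quantification** (`build_otu_table()`, `sample_summary()`,
   `group_compare()`, `composition_table()`). Read counts of identified
   clusters per sample and OTU; percent target relative to the *total*
   reads assigned to the sample before any filtering; Shannon H' over
   read proportions; Jaccard similarity between OTU presence sets;
   two-group comparisons with means, medians and a two-sided
   Mann-Whitney rank-sum P-value (normal approximation with tie
   correction, no continuity correction, so identical groups give
   exactly P = 1).

## Substitution model

The default model is JC69; branch lengths are expected substitutions
per site. GTR with arbitrary exchangeabilities and stationary
frequencies is available (`subst_model("GTR", ...)`, eigendecomposition
of the reversible generator, rate-normalized). At minibarcode length
the placement ranking is very robust to this choice — with ~130
informative sites the likelihood differences between edges dwarf the
model refinement — so the simple model is the default and the decision
is exposed rather than buried. Gaps, N and all other ambiguity codes
are missing data: their tip likelihood is 1 for every state.

## Choices where the convention was genuinely open

- **jplace dialect**: version 3 is emitted, with fields in the order
  `edge_num, likelihood, like_weight_ratio, distal_length,
  pendant_length`; readers accept any field order by name. Edge numbers
  are assigned 0-based in postorder and the same numbering is the
  single source of truth for writing. `distal_length` is the distance
  from the attachment point to the child (away-from-root) node of the
  edge. Spaces in leaf labels become underscores inside the tree string
  (the usual newick convention); placements are reported until the
  accumulated like-weight ratio reaches 0.999.
- **Quantile estimator**: linear interpolation between order statistics
  (type 7), with the estimator type exposed, since quantile conventions
  differ across software and the threshold value moves slightly with
  the choice.
- **Species-level filter**: reference labels with a bare "sp." token
  and no disambiguating tag are dropped; tagged placeholder labels
  ("Habroleptoides sp. SC2014") are kept, because such OTU-level
  reference entries are routinely retained in practice even under a
  species-level policy.
- **Shannon log base**: natural log by default, configurable. Published
  per-sample H' values generally cannot be re-derived without the
  underlying per-OTU counts, so the base is documented, not inferred.
- **Statistical test**: group differences are assessed with the
  rank-sum test because medians and boxplots are the natural summary
  for strongly skewed per-sample read counts; published P-values
  obtained with unnamed tests are not comparable and are not asserted
  anywhere.
- **ID score** (`id_score()`): three pairwise comparisons of
  tree-based, database-1 and database-2 species, each scored 6 (same
  species), 5 (same genus), 3 (same order), 1 (same phylum), else 0;
  family is deliberately *not* a rung. Missing members score 0 in their
  pairs, keeping the 0-18 range interpretable with one or two
  identifications. Labels absent from the taxonomy are scored at the
  deepest rank derivable from the label itself (the genus token).

## The simulator: what it does and does not emulate

`simulate_reference_db()` draws a pure-birth topology, replaces branch
lengths by exponentials (`mean_branch = 0.05` substitutions/site, a
typical within-order COI scale), evolves a uniform root sequence along
the tree under JC69, and derives a taxonomy from clades (deepest clades
are orders, shallow clades genera), so taxonomic structure is congruent
with the sequences, as in a curated reference. `simulate_sample()`
emits exactly `n_reads` reads per sample: targets drawn from a species
composition with a per-base error rate (default 0.5%), contaminants
evolved from a far outgroup (default 1.75 substitutions/site from the
root — *phylogenetic* contaminants that genuinely stress the
pendant-length filter, unlike random strings), and chimeras spliced
from two target templates at a random interior breakpoint, emitted from
a small number of splice templates per sample so they form clusters as
real PCR chimeras do. Primer prefixes are prepended so the trimming
stage runs unchanged, and every read carries ground truth.

The simulator is substitution-only: no indel errors, no quality-score
profiles, no PCR abundance bias, no co-amplified host sequences.
Passing end-to-end tests therefore demonstrates the pipeline's logic
(clustering thresholds, chimera detection, outlier rejection,
quantification bookkeeping) on data with realistic phylogenetic
structure; it does not certify performance on real MiSeq error
profiles, nor the adequacy of any particular reference database.

## Problem sizes and numerical notes

The shipped tests run the simulator at 50 reference species, 130 bp,
1000 reads per sample and 3 seeds, with parameter-recovery and
contaminant-rejection checks at those sizes; the placement oracle
comparisons use 4-6 leaf trees with 200 columns where exhaustive grid
search is exact enough to be an independent referee. These sizes were
chosen so the full suite exercises every stage end to end in minutes on
one core while keeping every random quantity far from its decision
boundaries (e.g. contaminants at 1.75 substitutions/site against
thresholds around 0.2-0.3). Conditional likelihoods are rescaled
per node and per site, so trees far larger than the test sizes pose no
underflow risk. Placement log-likelihood floors (1e-300) only guard
degenerate zero-length/conflicting-state corners.

## Known limitations

- The pendant filter inherits the reference tree's coverage: a true
  prey species with no relative in the reference is rejected as an
  outlier, which is the designed behaviour but means "percent target"
  is a lower bound on true diet reads.
- Read counts are a crude abundance surrogate; no biomass calibration
  is attempted, and none should be inferred without mock-community
  controls.
- The greedy clustering rule is order-dependent by design (abundance
  first); it reproduces the behaviour of single-pass greedy tools, not
  of exact single-linkage clustering.
- `group_compare()` requires two groups with at least two samples each
  and skips metrics otherwise.
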