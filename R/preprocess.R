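## Read preprocessing: primer trimming with a length filter, greedy
## per-sample clustering with abundance tracking, removal of
## low-abundance clusters, and de novo two-parent (bimera) chimera
## detection on the pooled cluster set.

## Mismatches between two sequences: Hamming distance over the common
## prefix plus the absolute length difference. Minibarcode amplicons are
## near-fixed-length, so an ungapped comparison with a length penalty
## stands in for full alignment.
seq_divergence <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  ra <- charToRaw(a); rb <- charToRaw(b)
  sum(ra[seq_len(n)] != rb[seq_len(n)]) + abs(na - nb)
}

#' Trim the forward primer and filter by length
#'
#' The primer must match at the 5' end with at most one mismatch; reads
#' without a recognizable primer are dropped, as are reads shorter than
#' `min_trimmed_len` after trimming. Input order is preserved.
#'
#' @param records Sequence records of one sample.
#' @param config A [pipeline_config()].
#' @return The surviving records, trimmed; attributes `n_input`,
#'   `n_no_primer` and `n_short` carry the filter counters.
#' @export
trim_and_filter <- function(records, config = pipeline_config()) {
  primer <- config$primer_fwd
  np <- nchar(primer)
  pr <- charToRaw(primer)
  n_input <- nrow(records)
  has_primer <- vapply(records$bases, function(b) {
    if (nchar(b) < np) return(FALSE)
    sum(charToRaw(substr(b, 1L, np)) != pr) <= 1L
  }, logical(1), USE.NAMES = FALSE)
  out <- records[has_primer, , drop = FALSE]
  out$bases <- substring(out$bases, np + 1L)
  out$qualities <- lapply(out$qualities, function(q) {
    if (is.null(q)) NULL else q[-seq_len(np)]
  })
  long_enough <- nchar(out$bases) >= config$min_trimmed_len
  res <- out[long_enough, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_input") <- n_input
  attr(res, "n_no_primer") <- sum(!has_primer)
  attr(res, "n_short") <- sum(!long_enough)
  res
}

#' Greedy single-pass clustering of one sample's reads
#'
#' Reads are pooled into identical-sequence groups, ordered by
#' multiplicity (descending; ties by first occurrence), and processed
#' greedily: each group joins the first existing cluster whose
#' representative is within `max_cluster_div` mismatches (Hamming over
#' the common prefix plus length difference), otherwise it founds a new
#' cluster with itself as representative. The procedure is fully
#' deterministic.
#'
#' @param records Trimmed sequence records of one sample.
#' @param config A [pipeline_config()].
#' @return A data.frame of clusters sorted by `n_reads` descending
#'   (ties by cluster foundation order) with columns `cluster_id`,
#'   `sample_id`, `representative`, `n_reads`, `member_ids` (list
#'   column) and `chimera_flag` (initialized FALSE).
#' @export
greedy_cluster <- function(records, config = pipeline_config()) {
  empty <- data.frame(cluster_id = character(), sample_id = character(),
                      representative = character(), n_reads = integer(),
                      stringsAsFactors = FALSE)
  empty$member_ids <- list(); empty$chimera_flag <- logical()
  if (nrow(records) == 0L) return(empty)
  sample_id <- records$sample_id[1L]
  groups <- split(records$id, factor(records$bases, levels = unique(records$bases)))
  uniq <- names(groups)
  mult <- lengths(groups)
  ord <- order(-mult, seq_along(uniq))
  reps <- character(0)
  assign <- integer(length(uniq))
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (seq_divergence(uniq[i], reps[k]) <= config$max_cluster_div) {
        hit <- k; break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, uniq[i])
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  n_reads <- as.integer(tapply(mult, assign, sum))
  members <- lapply(split(seq_along(uniq), assign),
                    function(ix) unlist(groups[ix], use.names = FALSE))
  out_ord <- order(-n_reads, seq_along(n_reads))
  out <- data.frame(
    cluster_id = sprintf("%s_c%03d", sample_id, seq_along(out_ord)),
    sample_id = sample_id,
    representative = reps[out_ord],
    n_reads = n_reads[out_ord],
    stringsAsFactors = FALSE)
  out$member_ids <- unname(members[out_ord])
  out$chimera_flag <- FALSE
  out
}

#' Drop low-abundance clusters
#'
#' Retains only clusters with at least `min_cluster_reads` reads
#' (default 11, i.e. clusters of 10 reads or less are discarded).
#'
#' @param clusters Clusters from [greedy_cluster()].
#' @param config A [pipeline_config()].
#' @return The retained clusters.
#' @export
filter_small_clusters <- function(clusters, config = pipeline_config()) {
  res <- clusters[clusters$n_reads >= config$min_cluster_reads, , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Per-position mismatch indicator of `parent` against a candidate of
## length L; positions past the parent's end always mismatch.
mismatch_vector <- function(candidate_raw, parent, L) {
  pr <- charToRaw(parent)
  np <- length(pr)
  v <- rep(TRUE, L)
  n <- min(np, L)
  v[seq_len(n)] <- pr[seq_len(n)] != candidate_raw[seq_len(n)]
  v
}

#' De novo chimera (bimera) detection on pooled clusters
#'
#' Clusters from all samples are analyzed jointly (chimeras can form
#' between amplicons of different samples in a multiplexed run). For
#' each candidate cluster, in ascending abundance, every cluster with
#' at least `chimera_abundance_skew` times its reads is a potential
#' parent. The candidate is flagged as a chimera iff some two-parent
#' model (left segment from one parent, right segment from another,
#' both segments at least `chimera_min_segment` bp) (a) fits the
#' candidate with at least `chimera_min_advantage` fewer mismatches
#' than the best single parent, and (b) explains the candidate to
#' within `chimera_max_model_div` mismatches. A true bimera matches its
#' parent mosaic up to sequencing noise; without cap (b), mutually
#' saturated sequences get flagged by chance.
#'
#' @param clusters Pooled clusters (all samples).
#' @param config A [pipeline_config()].
#' @return The clusters with `chimera_flag` set (input order
#'   preserved); flagged clusters should be excluded downstream but are
#'   retained here for reporting.
#' @export
detect_chimeras <- function(clusters, config = pipeline_config()) {
  n <- nrow(clusters)
  if (n == 0L) return(clusters)
  flag <- rep(FALSE, n)
  minseg <- config$chimera_min_segment
  for (ci in order(clusters$n_reads, seq_len(n))) {
    cand <- clusters$representative[ci]
    L <- nchar(cand)
    if (L < 2L * minseg) next
    parents <- which(clusters$n_reads >=
                       config$chimera_abundance_skew * clusters$n_reads[ci])
    parents <- setdiff(parents, ci)
    if (length(parents) < 1L) next
    cr <- charToRaw(cand)
    mism <- vapply(parents, function(p) {
      mismatch_vector(cr, clusters$representative[p], L)
    }, logical(L))
    ## columns = parents; add the parent-length penalty to totals
    len_pen <- abs(nchar(clusters$representative[parents]) - L)
    pref <- apply(mism, 2L, cumsum)              # L x P
    totals <- pref[L, ] + len_pen
    best_single <- min(totals)
    ks <- seq(minseg, L - minseg)
    ## best chimeric model at breakpoint k: best prefix parent + best
    ## suffix parent, minimized independently (exact: if the optimum
    ## uses the same parent twice it equals that single parent's score
    ## and cannot clear the advantage margin).
    pref_k <- pref[ks, , drop = FALSE]
    suff_k <- sweep(-pref_k, 2L, totals, "+")    # totals - pref at k
    best_two <- min(apply(pref_k, 1L, min) + apply(suff_k, 1L, min))
    if (best_single - best_two >= config$chimera_min_advantage &&
        best_two <= config$chimera_max_model_div) {
      flag[ci] <- TRUE
    }
  }
  clusters$chimera_flag <- flag
  clusters
}

#' Preprocess one sample end to end
#'
#' Convenience wrapper: [trim_and_filter()], [greedy_cluster()],
#' [filter_small_clusters()]. Chimera detection is *not* included here
#' because it must run jointly on the pooled clusters of all samples
#' (see [detect_chimeras()]).
#'
#' @param records Raw sequence records of one sample.
#' @param config A [pipeline_config()].
#' @return A list with `clusters`, and `stats` (reads at each stage).
#' @export
preprocess_sample <- function(records, config = pipeline_config()) {
  trimmed <- trim_and_filter(records, config)
  clusters <- greedy_cluster(trimmed, config)
  kept <- filter_small_clusters(clusters, config)
  list(clusters = kept,
       stats = data.frame(
         sample_id = if (nrow(records)) records$sample_id[1L] else NA_character_,
         n_reads_raw = nrow(records),
         n_reads_trimmed = nrow(trimmed),
         n_clusters = nrow(clusters),
         n_clusters_kept = nrow(kept),
         n_reads_kept = sum(kept$n_reads)))
}
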