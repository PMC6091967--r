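## OTU-by-sample read-count tables and the pipeline's quantitative
## outputs: percent target reads, OTU richness, Shannon diversity,
## Jaccard beta diversity, taxon-group composition, and group
## comparisons (e.g. fresh vs old samples).

#' Build an OTU-by-sample read-count table
#'
#' Sums the read counts of *identified* clusters per sample and OTU
#' label; outlier and unalignable clusters are excluded.
#'
#' @param identifications A data.frame as from [identification_table()]
#'   (columns `sample_id`, `status`, `otu_label`, `n_reads`), or a list
#'   of `identification` objects.
#' @param samples Optional character vector fixing the sample set (and
#'   row order); defaults to the samples present. Samples with no
#'   identified cluster get all-zero rows.
#' @return An object of class `otu_table`: integer matrix samples x
#'   OTUs with `counts` accessible as the matrix itself.
#' @export
build_otu_table <- function(identifications, samples = NULL) {
  if (!is.data.frame(identifications)) {
    identifications <- identification_table(identifications)
  }
  df <- identifications
  if (is.null(samples)) samples <- unique(df$sample_id)
  idf <- df[df$status == "identified", , drop = FALSE]
  otus <- sort(unique(idf$otu_label))
  m <- matrix(0L, nrow = length(samples), ncol = length(otus),
              dimnames = list(samples, otus))
  idf <- idf[!is.na(idf$sample_id) & !is.na(idf$otu_label), , drop = FALSE]
  if (nrow(idf)) {
    agg <- stats::aggregate(n_reads ~ sample_id + otu_label, data = idf, FUN = sum)
    agg <- agg[agg$sample_id %in% samples, , drop = FALSE]
    m[cbind(agg$sample_id, agg$otu_label)] <- as.integer(agg$n_reads)
  }
  structure(m, class = c("otu_table", class(m)))
}

#' Percent of a sample's reads in identified target clusters
#'
#' @param sample_reads_total Total reads assigned to the sample before
#'   any filtering.
#' @param identifications Identification table (or list) for that
#'   sample; only rows with `status == "identified"` count.
#' @return Percentage in `[0, 100]`, or `NA` if the denominator is 0.
#' @export
percent_target <- function(sample_reads_total, identifications) {
  if (!is.data.frame(identifications)) {
    identifications <- identification_table(identifications)
  }
  target <- sum(identifications$n_reads[identifications$status == "identified"])
  if (sample_reads_total == 0L) return(NA_real_)
  stopifnot(sample_reads_total >= target)
  100 * target / sample_reads_total
}

#' Shannon diversity index
#'
#' H' = -sum p_i log(p_i) over OTUs with positive counts, with read
#' proportions as abundance surrogate. Natural log by default.
#'
#' @param counts Non-negative counts (one vector = one sample).
#' @param log_base `"e"` (default), `"2"` or `"10"`.
#' @return H' (non-negative scalar).
#' @export
shannon_index <- function(counts, log_base = c("e", "2", "10")) {
  log_base <- match.arg(log_base)
  stopifnot(all(counts >= 0))
  if (sum(counts) <= 0) stop("shannon_index: counts must sum to > 0")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = shannon_base_value(log_base)))
}

#' Jaccard similarity of two OTU presence sets
#'
#' J = |A intersect B| / |A union B|.
#'
#' @param otus_a,otus_b Character vectors (presence sets).
#' @return J in `[0, 1]`, or `NA` if both sets are empty.
#' @export
jaccard_index <- function(otus_a, otus_b) {
  a <- unique(otus_a); b <- unique(otus_b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Per-sample summary statistics
#'
#' The per-sample report schema: total reads, percent target reads,
#' OTU richness and Shannon H'.
#'
#' @param otu_table An [build_otu_table()] matrix.
#' @param sample_reads_total Named integer vector: total reads assigned
#'   to each sample (before any filtering).
#' @param fresh Optional named logical vector (fresh vs old samples).
#' @param log_base Shannon log base.
#' @return A data.frame with columns `sample_id`, `fresh`,
#'   `reads_total`, `pct_target`, `otu_richness`, `shannon`.
#' @export
sample_summary <- function(otu_table, sample_reads_total, fresh = NULL,
                           log_base = "e") {
  samples <- rownames(otu_table)
  stopifnot(all(samples %in% names(sample_reads_total)))
  ident_reads <- rowSums(otu_table)
  totals <- sample_reads_total[samples]
  data.frame(
    sample_id = samples,
    fresh = if (is.null(fresh)) NA else unname(fresh[samples]),
    reads_total = unname(totals),
    pct_target = unname(ifelse(totals > 0, 100 * ident_reads / totals, NA_real_)),
    otu_richness = unname(rowSums(otu_table > 0)),
    shannon = vapply(samples, function(s) {
      if (ident_reads[[s]] > 0) shannon_index(otu_table[s, ], log_base) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare per-sample metrics between two groups
#'
#' For each metric (reads, percent target, OTU richness, H'): per-group
#' means and medians, a two-sided rank-sum (Mann-Whitney) P-value with
#' the normal approximation and tie correction, and box-plot summary
#' statistics (quartiles and whiskers) as data.
#'
#' @param summaries A data.frame as from [sample_summary()] (columns
#'   `reads_total`, `pct_target`, `otu_richness`, `shannon` plus the
#'   grouping column).
#' @param group_field Name of a logical/two-level column (default
#'   `"fresh"`).
#' @param metrics Metric columns to compare.
#' @return A list with `table` (one row per metric x group:
#'   mean/median/n and the shared P-value) and `boxplot` (per metric x
#'   group: the five boxplot statistics).
#' @export
group_compare <- function(summaries, group_field = "fresh",
                          metrics = c("reads_total", "pct_target",
                                      "otu_richness", "shannon")) {
  g <- summaries[[group_field]]
  stopifnot(!is.null(g))
  levs <- sort(unique(g[!is.na(g)]), decreasing = TRUE)
  if (length(levs) != 2L) stop("group_compare: need exactly two groups")
  rows <- list(); box <- list()
  for (m in metrics) {
    x <- summaries[[m]][g == levs[1L] & !is.na(g)]
    y <- summaries[[m]][g == levs[2L] & !is.na(g)]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning(sprintf("group_compare: skipping metric '%s' (a group has < 2 samples)", m))
      next
    }
    pv <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE)$p.value)
    for (lv in levs) {
      v <- if (identical(lv, levs[1L])) x else y
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = as.character(lv), n = length(v),
        mean = mean(v), median = stats::median(v), p_value = pv,
        stringsAsFactors = FALSE)
      bs <- grDevices::boxplot.stats(v)$stats
      box[[length(box) + 1L]] <- data.frame(
        metric = m, group = as.character(lv),
        lower_whisker = bs[1L], q1 = bs[2L], median = bs[3L],
        q3 = bs[4L], upper_whisker = bs[5L], stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), boxplot = do.call(rbind, box))
}

#' Map OTUs to reporting groups
#'
#' Groups are the taxonomy's orders, with the family Chironomidae split
#' out of Diptera (the remainder reported as "Diptera excl.
#' Chironomidae"). OTUs absent from the taxonomy map to "other".
#'
#' @param otus Character vector of OTU (species) labels.
#' @param taxonomy Taxonomy data.frame.
#' @return Named character vector OTU -> group.
#' @export
otu_groups <- function(otus, taxonomy) {
  i <- match(otus, taxonomy$species)
  grp <- taxonomy$order[i]
  fam <- taxonomy$family[i]
  chir <- !is.na(grp) & grp == "Diptera" & !is.na(fam) & fam == "Chironomidae"
  grp[chir] <- "Chironomidae"
  grp[!is.na(grp) & grp == "Diptera" & !chir] <- "Diptera excl. Chironomidae"
  unknown <- is.na(grp)
  if (any(unknown)) {
    message("OTUs without taxonomy mapped to group 'other': ",
            paste(otus[unknown], collapse = ", "))
    grp[unknown] <- "other"
  }
  stats::setNames(grp, otus)
}

#' Per-sample taxon-group composition
#'
#' For every sample and group: the number of distinct OTUs detected and
#' the percentage of the sample's identified reads in that group.
#' Percentages per sample sum to 100 (up to rounding) for samples with
#' any identified reads.
#'
#' @param otu_table An [build_otu_table()] matrix.
#' @param taxonomy Taxonomy data.frame.
#' @return A data.frame with columns `sample_id`, `group`, `n_otus`,
#'   `pct_reads`.
#' @export
composition_table <- function(otu_table, taxonomy) {
  groups <- otu_groups(colnames(otu_table), taxonomy)
  glev <- sort(unique(groups))
  rows <- lapply(rownames(otu_table), function(s) {
    v <- otu_table[s, ]
    tot <- sum(v)
    data.frame(
      sample_id = s, group = glev,
      n_otus = vapply(glev, function(g) sum(v[groups == g] > 0), integer(1)),
      pct_reads = vapply(glev, function(g) {
        if (tot == 0) 0 else 100 * sum(v[groups == g]) / tot
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
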