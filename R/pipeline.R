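## End-to-end orchestration: raw per-sample reads -> trimmed reads ->
## clusters -> pooled chimera removal -> profile alignment -> placement
## -> identification -> OTU table and per-sample summaries.

#' Run the full pipeline on per-sample read sets
#'
#' @param sample_records Named list (sample id -> sequence records) of
#'   raw reads, e.g. from [read_fastq()] or [simulate_sample()].
#' @param refdb Reference database.
#' @param config A [pipeline_config()].
#' @param model A [subst_model()].
#' @param threshold Optional [quantile_threshold()]; by default the
#'   `config$quantile_q` quantile of the reference tree's terminal
#'   branch lengths.
#' @return A list: `clusters` (pooled, with chimera flags),
#'   `identifications` (data.frame, one row per non-chimeric cluster),
#'   `otu_table`, `summary` (per-sample reads/% target/richness/H'),
#'   `threshold`, `stats` (per-sample preprocessing counts),
#'   `placements` (named list of placement data.frames).
#' @export
run_pipeline <- function(sample_records, refdb,
                         config = pipeline_config(),
                         model = subst_model(),
                         threshold = NULL) {
  stopifnot(!is.null(names(sample_records)))
  if (is.null(threshold)) {
    threshold <- quantile_threshold(terminal_branch_lengths(refdb$tree),
                                    q = config$quantile_q)
  }
  pre <- lapply(names(sample_records), function(s) {
    recs <- sample_records[[s]]
    recs$sample_id <- s
    preprocess_sample(recs, config)
  })
  names(pre) <- names(sample_records)
  stats <- do.call(rbind, lapply(pre, `[[`, "stats"))
  clusters <- do.call(rbind, lapply(pre, `[[`, "clusters"))
  rownames(clusters) <- NULL
  if (nrow(clusters)) clusters <- detect_chimeras(clusters, config)
  keep <- clusters[!clusters$chimera_flag, , drop = FALSE]
  prep <- placement_prep(refdb, model)
  refdb <- cache_distances(refdb)
  placements <- list()
  idents <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    aligned <- align_query_to_reference(keep$representative[i], refdb)
    pl <- if (is.na(aligned)) NULL else {
      place_query(aligned, refdb, model, prep = prep)
    }
    placements[[keep$cluster_id[i]]] <- pl
    idents[[i]] <- classify_placement(pl, refdb, threshold,
                                      query_id = keep$cluster_id[i],
                                      sample_id = keep$sample_id[i],
                                      n_reads = keep$n_reads[i])
  }
  ident_tab <- identification_table(idents)
  otab <- build_otu_table(ident_tab, samples = names(sample_records))
  totals <- stats::setNames(stats$n_reads_raw, stats$sample_id)
  summ <- sample_summary(otab, totals, log_base = config$shannon_log_base)
  list(clusters = clusters, identifications = ident_tab,
       otu_table = otab, summary = summ, threshold = threshold,
       stats = stats, placements = placements)
}
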