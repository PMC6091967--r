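#' Pipeline configuration
#'
#' Collects the tunable constants of the pipeline in one validated object.
#' The defaults encode the published protocol: reads shorter than 124 bp
#' after primer trimming are discarded, reads are clustered at a
#' divergence of at most 3 bp, and clusters of 10 reads or less are
#' discarded (i.e. at least 11 reads are required).
#'
#' @param primer_fwd Forward primer expected at the 5' end of every read
#'   (bases over A/C/G/T). Trimming allows at most one mismatch.
#' @param min_trimmed_len Minimum read length after primer removal (bp).
#' @param max_cluster_div Maximum divergence (mismatches, including
#'   length difference) between a read and its cluster representative.
#' @param min_cluster_reads Minimum reads per retained cluster.
#' @param chimera_abundance_skew Minimum abundance ratio parent/candidate
#'   for a cluster to act as a chimera parent.
#' @param chimera_min_segment Minimum length (bp) of each chimeric segment.
#' @param chimera_min_advantage Minimum improvement (mismatches) of the
#'   best two-parent model over the best single parent to call a chimera.
#' @param chimera_max_model_div Maximum mismatches allowed between the
#'   best two-parent model and the candidate for a chimera call (a true
#'   bimera is explained by its parents up to sequencing noise; without
#'   this cap, mutually saturated sequences get flagged by chance).
#' @param quantile_q Quantile of the terminal branch-length distribution
#'   used as the pendant-length identification threshold.
#' @param shannon_log_base Logarithm base for the Shannon index: one of
#'   `"e"`, `"2"`, `"10"`.
#' @param seed Integer seed for all stochastic operations.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_trimmed_len
#' @export
pipeline_config <- function(primer_fwd = "TCCACTAATCACAAGGATATTGGTAC",
                            min_trimmed_len = 124L,
                            max_cluster_div = 3L,
                            min_cluster_reads = 11L,
                            chimera_abundance_skew = 2.0,
                            chimera_min_segment = 20L,
                            chimera_min_advantage = 3L,
                            chimera_max_model_div = 3L,
                            quantile_q = 0.999,
                            shannon_log_base = c("e", "2", "10"),
                            seed = 1L) {
  shannon_log_base <- match.arg(shannon_log_base)
  stopifnot(
    is.character(primer_fwd), length(primer_fwd) == 1L,
    min_trimmed_len >= 1L,
    max_cluster_div >= 0L,
    min_cluster_reads >= 1L,
    chimera_abundance_skew > 0,
    chimera_min_segment >= 1L,
    chimera_min_advantage >= 1L,
    chimera_max_model_div >= 0L,
    quantile_q > 0, quantile_q < 1
  )
  structure(list(
    primer_fwd = toupper(primer_fwd),
    min_trimmed_len = as.integer(min_trimmed_len),
    max_cluster_div = as.integer(max_cluster_div),
    min_cluster_reads = as.integer(min_cluster_reads),
    chimera_abundance_skew = chimera_abundance_skew,
    chimera_min_segment = as.integer(chimera_min_segment),
    chimera_min_advantage = as.integer(chimera_min_advantage),
    chimera_max_model_div = as.integer(chimera_max_model_div),
    quantile_q = quantile_q,
    shannon_log_base = shannon_log_base,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

shannon_base_value <- function(shannon_log_base) {
  switch(shannon_log_base, e = exp(1), `2` = 2, `10` = 10)
}
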