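## Seed-deterministic synthetic data: reference databases (tree +
## evolved sequences + clade-derived taxonomy), fecal-sample read sets
## with planted targets, contaminants and chimeras (with ground truth),
## and a packaged table of published sample attributes used as a
## realistic fixture for the diversity statistics.

#' Evolve a sequence along a branch
#'
#' Per-site substitution under the model's transition probabilities;
#' a branch length of 0 returns an identical copy. Substitution-only
#' (no indels). Uses the current R random number generator state.
#'
#' @param parent_bases Parent sequence (A/C/G/T).
#' @param branch_length Branch length in expected substitutions/site.
#' @param model A [subst_model()].
#' @return The child sequence.
#' @export
evolve_sequence <- function(parent_bases, branch_length, model = subst_model()) {
  stopifnot(branch_length >= 0)
  if (branch_length == 0) return(parent_bases)
  enc <- encode_states(parent_bases)
  p <- transition_prob(model, branch_length)
  out <- enc
  for (state in 1:4) {
    idx <- which(enc == state)
    if (length(idx)) {
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = p[state, ])
    }
  }
  chars <- DNA_STATES[out]
  chars[is.na(enc)] <- "N"
  paste(chars, collapse = "")
}

## Deterministic clade labels: cut the tree's patristic distance matrix
## into k groups by average-linkage clustering.
clade_groups <- function(tree, k) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Simulate a reference database
#'
#' A pure-birth (Yule) topology with exponential branch lengths, a
#' uniform-random root sequence evolved along every branch under the
#' model, and a clade-derived taxonomy: orders are the deepest
#' `n_orders` clades (named after real freshwater-invertebrate orders
#' so group reports read naturally, with one Diptera family labelled
#' Chironomidae), genera are shallow clades. Fully deterministic given
#' `seed`.
#'
#' @param n_species Number of reference species (>= 4).
#' @param seq_len Minibarcode length in bp (>= 60).
#' @param mean_branch Mean of the exponential branch lengths
#'   (substitutions/site).
#' @param n_orders,n_families,n_genera Taxonomy granularity (defaults
#'   scale with `n_species`).
#' @param birth_rate Birth rate of the Yule topology.
#' @param model A [subst_model()].
#' @param seed Integer seed.
#' @return A `ref_db` (see [load_reference()]) with an extra `truth`
#'   element (the generating tree and sequences).
#' @export
simulate_reference_db <- function(n_species = 50L, seq_len = 130L,
                                  mean_branch = 0.05, n_orders = 4L,
                                  n_families = NULL, n_genera = NULL,
                                  birth_rate = 1, model = subst_model(),
                                  seed = 1L) {
  stopifnot(n_species >= 4L, seq_len >= 60L, mean_branch > 0)
  if (is.null(n_genera)) n_genera <- max(n_orders, n_species %/% 3L)
  if (is.null(n_families)) n_families <- max(n_orders, min(n_genera, n_species %/% 5L))
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / mean_branch)
  tree$tip.label <- sprintf("t%03d", seq_len(n_species))
  ## evolve sequences from a uniform root down the tree
  root_seq <- paste(sample(DNA_STATES, seq_len, replace = TRUE), collapse = "")
  ntip <- n_species
  seqs <- character(ntip + tree$Nnode)
  seqs[ntip + 1L] <- root_seq
  for (e in rev(postorder_edges(tree))) {
    seqs[tree$edge[e, 2L]] <- evolve_sequence(seqs[tree$edge[e, 1L]],
                                              tree$edge.length[e], model)
  }
  ## clade-derived taxonomy
  order_names <- c("Ephemeroptera", "Diptera", "Plecoptera", "Trichoptera",
                   "Coleoptera", "Odonata", "Megaloptera", "Crustacea")
  ord_id <- clade_groups(tree, n_orders)
  fam_id <- clade_groups(tree, n_families)
  gen_id <- clade_groups(tree, n_genera)
  ord <- order_names[(ord_id - 1L) %% length(order_names) + 1L]
  fam <- sprintf("Family%02d", fam_id)
  ## one Diptera family is Chironomidae (the first one encountered)
  dip_fams <- unique(fam_id[ord == "Diptera"])
  if (length(dip_fams)) fam[ord == "Diptera" & fam_id == dip_fams[1L]] <- "Chironomidae"
  genus <- sprintf("Genus%03d", gen_id)
  epithet <- stats::ave(seq_len(ntip), gen_id, FUN = seq_along)
  species <- sprintf("%s aquaticus%02d", genus, epithet)
  tree$tip.label <- species
  taxonomy <- data.frame(species = species, genus = genus, family = fam,
                         order = ord, phylum = "Arthropoda",
                         stringsAsFactors = FALSE)
  alignment <- stats::setNames(seqs[seq_len(ntip)], species)
  db <- ref_db(alignment, tree, taxonomy)
  db$truth <- list(root_seq = root_seq, node_seqs = seqs, seed = seed)
  db
}

#' Simulate one fecal sample's reads
#'
#' Emits exactly `n_reads` single-end reads: target reads drawn from
#' the given species composition with a per-base substitution error
#' rate, contaminant reads evolved from a far outgroup (default 1.75
#' substitutions/site from the root sequence, stressing the
#' pendant-length filter), and chimeric reads spliced from two randomly
#' chosen target templates at a random interior breakpoint (a small
#' number of splice templates per sample, so chimeric reads form
#' clusters as they do in multiplexed runs). Each read is prefixed with
#' the forward primer and truncated to the read length, so
#' [trim_and_filter()] applies unchanged.
#'
#' @param refdb Reference database (e.g. [simulate_reference_db()]).
#' @param composition Named numeric vector: reference species ->
#'   relative abundance (need not sum to 1).
#' @param n_reads Total reads to emit.
#' @param error_rate Per-base substitution error probability.
#' @param contam_frac,chimera_frac Fractions of contaminant and
#'   chimeric reads (the remainder is target).
#' @param sample_id Sample identifier.
#' @param read_len Sequenced read length (primer + insert).
#' @param outgroup_div Divergence of the contaminant outgroup from the
#'   root (substitutions/site).
#' @param n_chimera_templates Distinct splice templates per sample.
#' @param config A [pipeline_config()] (supplies the primer).
#' @param seed Integer seed.
#' @return A list: `records` (FASTQ-style sequence records), `truth`
#'   (data.frame: read_id, origin, source), `composition` (the true
#'   per-species target read counts).
#' @export
simulate_sample <- function(refdb, composition, n_reads = 1000L,
                            error_rate = 0.005, contam_frac = 0.1,
                            chimera_frac = 0.05, sample_id = "S1",
                            read_len = 150L, outgroup_div = 1.75,
                            n_chimera_templates = 2L,
                            config = pipeline_config(), seed = 1L) {
  unknown <- setdiff(names(composition), names(refdb$alignment))
  if (length(unknown)) {
    stop("composition references unknown species: ",
         paste(unknown, collapse = ", "))
  }
  stopifnot(contam_frac >= 0, chimera_frac >= 0,
            contam_frac + chimera_frac <= 1, n_reads >= 1L)
  set.seed(seed)
  primer <- config$primer_fwd
  insert_len <- read_len - nchar(primer)
  ungap <- function(s) gsub("-", "", s, fixed = TRUE)
  template_of <- function(sp) {
    substr(ungap(refdb$alignment[[sp]]), 1L, insert_len)
  }
  n_contam <- round(contam_frac * n_reads)
  n_chim <- round(chimera_frac * n_reads)
  n_target <- n_reads - n_contam - n_chim
  ## target composition counts
  probs <- composition / sum(composition)
  tgt_counts <- if (n_target > 0) {
    stats::rmultinom(1L, n_target, probs)[, 1L]
  } else stats::setNames(integer(length(probs)), names(probs))
  ## contaminant outgroup templates (two distinct far lineages)
  out_templates <- vapply(1:2, function(i) {
    substr(evolve_sequence(refdb$truth$root_seq %||%
                             ungap(refdb$alignment[[1L]]),
                           outgroup_div), 1L, insert_len)
  }, character(1))
  ## chimera splice templates from two random target species
  chim_templates <- character(0)
  if (n_chim > 0L) {
    spp <- names(composition)
    chim_templates <- vapply(seq_len(n_chimera_templates), function(i) {
      pair <- sample(spp, 2L, replace = length(spp) < 2L)
      a <- template_of(pair[1L]); b <- template_of(pair[2L])
      L <- min(nchar(a), nchar(b))
      k <- sample(seq(30L, L - 30L), 1L)
      paste0(substr(a, 1L, k), substr(b, k + 1L, L))
    }, character(1))
  }
  add_errors <- function(s, rate) {
    if (rate <= 0) return(s)
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(DNA_STATES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
    paste(ch, collapse = "")
  }
  bases <- character(n_reads); origin <- character(n_reads)
  source <- character(n_reads)
  i <- 0L
  for (sp in names(tgt_counts)) {
    tpl <- template_of(sp)
    for (r in seq_len(tgt_counts[[sp]])) {
      i <- i + 1L
      bases[i] <- add_errors(tpl, error_rate)
      origin[i] <- "target"; source[i] <- sp
    }
  }
  for (r in seq_len(n_contam)) {
    i <- i + 1L
    tpl <- out_templates[(r - 1L) %% length(out_templates) + 1L]
    bases[i] <- add_errors(tpl, error_rate)
    origin[i] <- "contaminant"; source[i] <- "outgroup"
  }
  for (r in seq_len(n_chim)) {
    i <- i + 1L
    tpl <- chim_templates[(r - 1L) %% length(chim_templates) + 1L]
    bases[i] <- add_errors(tpl, error_rate)
    origin[i] <- "chimera"
    source[i] <- sprintf("splice%d", (r - 1L) %% length(chim_templates) + 1L)
  }
  ids <- sprintf("%s_read%05d", sample_id, seq_len(n_reads))
  ## shuffle read order as a sequencer would
  ord <- sample.int(n_reads)
  records <- sequence_records(ids, paste0(primer, bases[ord]), sample_id)
  truth <- data.frame(read_id = ids, origin = origin[ord],
                      source = source[ord], stringsAsFactors = FALSE)
  list(records = records, truth = truth,
       composition = tgt_counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published per-sample attributes of 41 desman fecal samples
#'
#' A packaged summary table of 41 fecal samples of the Pyrenean desman
#' (*Galemys pyrenaicus*) from an Illumina COI-minibarcode
#' metabarcoding survey: per sample, whether it was collected fresh,
#' collection metadata, total assigned reads, the percentage of reads
#' in large clusters identified by the tree-based method, OTU richness
#' and Shannon H'. Used as a realistic fixture for the diversity and
#' group-comparison statistics.
#'
#' @return A data.frame with 41 rows and columns `sample`, `fresh`
#'   (logical), `date`, `river`, `system`, `region`, `reads`,
#'   `pct_target`, `otus`, `shannon`.
#' @export
desman_samples <- function() {
  path <- system.file("extdata", "desman_sample_attributes.tsv",
                      package = "treebard", mustWork = TRUE)
  read_tabular(path, c(sample = "character", fresh = "logical",
                       date = "character", river = "character",
                       system = "character", region = "character",
                       reads = "integer", pct_target = "double",
                       otus = "integer", shannon = "double"))
}
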