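## Reference database: fixed-column alignment + species-level taxonomy
## + rooted tree with branch lengths. Also the terminal branch-length
## distribution, its outlier quantile (the pendant-length
## identification threshold), and profile alignment of queries into the
## fixed reference coordinate system.

taxonomy_schema <- c(species = "character", genus = "character",
                     family = "character", order = "character",
                     phylum = "character")

## A species label is "identified to species level" unless it carries a
## bare "sp." token with no disambiguating tag ("Baetis sp." is dropped,
## "Habroleptoides sp. SC2014" is kept).
is_species_level <- function(label) {
  toks <- strsplit(label, "\\s+")
  vapply(toks, function(t) !(length(t) == 2L && t[2L] == "sp."), logical(1))
}

#' Load and validate a reference database
#'
#' Reads the reference alignment (FASTA, equal column counts), the
#' taxonomy table (TSV with columns species, genus, family, order,
#' phylum) and the reference tree (newick). Leaves lacking a taxonomy
#' record, and labels not identified to species level (a bare "sp."
#' with no tag), are dropped from the alignment and pruned from the
#' tree; the dropped labels are recorded in the `dropped` element.
#'
#' @param alignment_fasta Path to the gapped reference FASTA.
#' @param taxonomy_tsv Path to the taxonomy TSV.
#' @param tree_newick Path to (or text of) the reference newick tree.
#' @return An object of class `ref_db`: list with `alignment` (named
#'   character vector), `tree` (phylo, edge-numbered), `taxonomy`
#'   (data.frame), `n_columns` and `dropped`.
#' @export
load_reference <- function(alignment_fasta, taxonomy_tsv, tree_newick) {
  recs <- read_fasta(alignment_fasta)
  ## newick files conventionally encode spaces in species labels as
  ## underscores; normalize both sides to spaces
  und2sp <- function(x) gsub("_", " ", x, fixed = TRUE)
  alignment <- stats::setNames(recs$bases, und2sp(recs$id))
  taxonomy <- read_tabular(taxonomy_tsv, taxonomy_schema)
  taxonomy$species <- und2sp(taxonomy$species)
  tree <- read_newick(tree_newick)
  tree$tip.label <- und2sp(tree$tip.label)
  ref_db(alignment, tree, taxonomy)
}

#' Assemble a reference database from in-memory parts
#'
#' @param alignment Named character vector of gapped sequences.
#' @param tree An [ape::phylo] tree.
#' @param taxonomy Data.frame with columns species, genus, family,
#'   order, phylum.
#' @return A `ref_db` object (see [load_reference()]).
#' @export
ref_db <- function(alignment, tree, taxonomy) {
  stopifnot(!is.null(names(alignment)), is.data.frame(taxonomy))
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) {
    stop("reference alignment validation error: unequal column counts")
  }
  drop_tax <- setdiff(names(alignment), taxonomy$species)
  drop_sp <- names(alignment)[!is_species_level(names(alignment))]
  dropped <- union(drop_tax, drop_sp)
  if (length(dropped)) {
    message(sprintf("dropping %d reference sequence(s) without species-level taxonomy: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    alignment <- alignment[setdiff(names(alignment), dropped)]
    tree <- ape::drop.tip(tree, intersect(tree$tip.label, dropped))
    if (is.null(tree)) stop("reference validation error: no leaves left after filtering")
  }
  only_aln <- setdiff(names(alignment), tree$tip.label)
  only_tree <- setdiff(tree$tip.label, names(alignment))
  if (length(only_aln) || length(only_tree)) {
    stop("reference validation error: tree/alignment leaf sets differ; ",
         "alignment-only: [", paste(only_aln, collapse = ", "),
         "]; tree-only: [", paste(only_tree, collapse = ", "), "]")
  }
  if (length(alignment) < 4L) {
    stop("reference validation error: fewer than 4 leaves")
  }
  genus_tok <- vapply(strsplit(names(alignment), "\\s+"), `[[`, character(1), 1L)
  tx <- taxonomy[match(names(alignment), taxonomy$species), ]
  bad_genus <- which(tx$genus != genus_tok)
  if (length(bad_genus)) {
    warning("taxonomy genus differs from the species-label genus token for: ",
            paste(tx$species[bad_genus], collapse = ", "), call. = FALSE)
  }
  tree <- edge_numbering(tree)
  structure(list(alignment = alignment, tree = tree,
                 taxonomy = tx, n_columns = widths,
                 dropped = dropped),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("ref_db: %d leaves, %d alignment columns, %d orders\n",
              length(x$alignment), x$n_columns,
              length(unique(x$taxonomy$order))))
  invisible(x)
}

#' Terminal branch lengths of a tree
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A named numeric vector, one value per leaf: the length of
#'   the leaf's incident edge.
#' @export
terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  stopifnot(ntip >= 1L)
  idx <- match(seq_len(ntip), tree$edge[, 2L])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

#' Empirical quantile threshold of branch lengths
#'
#' Linear interpolation between order statistics (type 7, the common
#' default) unless another estimator type is requested.
#'
#' @param lengths Non-empty numeric vector of branch lengths.
#' @param q Quantile level in (0, 1).
#' @param type Quantile estimator type (see [stats::quantile()]).
#' @return An object of class `outlier_threshold`: list with `q`,
#'   `value` (substitutions/site) and `n_branches`.
#' @export
quantile_threshold <- function(lengths, q = 0.999, type = 7L) {
  if (length(lengths) == 0L) stop("`lengths` must be non-empty")
  stopifnot(q > 0, q < 1, all(lengths >= 0))
  structure(list(q = q,
                 value = unname(stats::quantile(lengths, probs = q, type = type)),
                 n_branches = length(lengths)),
            class = "outlier_threshold")
}

#' @export
print.outlier_threshold <- function(x, ...) {
  cat(sprintf("outlier_threshold: %.1f%% quantile of %d terminal branches = %.4g subst/site\n",
              100 * x$q, x$n_branches, x$value))
  invisible(x)
}

#' Flag leaves on exceptionally long terminal branches
#'
#' A curation aid (no automatic pruning): leaves whose terminal branch
#' exceeds the threshold, sorted by length descending.
#'
#' @param tree An [ape::phylo] tree.
#' @param threshold Numeric threshold or an [quantile_threshold()]
#'   object.
#' @return Character vector of flagged leaf labels.
#' @export
flag_long_branches <- function(tree, threshold) {
  if (inherits(threshold, "outlier_threshold")) threshold <- threshold$value
  stopifnot(threshold >= 0)
  tl <- terminal_branch_lengths(tree)
  flagged <- tl[tl > threshold]
  names(flagged)[order(-flagged)]
}

## Column profile of the reference alignment: per-column frequency of
## each base among non-gap residues (with a small pseudocount) and the
## column occupancy (fraction non-gap).
reference_profile <- function(refdb) {
  if (!is.null(refdb$profile)) return(refdb$profile)
  mat <- do.call(rbind, strsplit(refdb$alignment, "", fixed = TRUE))
  s <- ncol(mat)
  counts <- vapply(DNA_STATES, function(b) colSums(mat == b), numeric(s))
  nongap <- rowSums(counts)  # per column, over the 4 bases (N excluded)
  freq <- (counts + 0.02) / (nongap + 0.08)
  occ <- nongap / nrow(mat)
  list(freq = t(freq), occupancy = occ, n_columns = s)  # freq: 4 x S
}

#' Align a query into the fixed reference coordinate system
#'
#' Global dynamic-programming alignment of the query against the
#' reference column profile with the reference columns held fixed: no
#' new columns are created, and query bases that would require an
#' insertion relative to the reference are discarded (their count is
#' returned as an attribute). Matching a base to a column scores the
#' column's relative frequency of that base; skipping a column costs
#' proportionally to its occupancy; N scores zero everywhere.
#'
#' @param query_bases Ungapped query string (at least 20 bases).
#' @param refdb Reference database.
#' @param min_mean_score Mean per-base score below which the query is
#'   declared unalignable (all-N or garbage input).
#' @return The gapped query string of exactly `refdb$n_columns`
#'   characters, or `NA_character_` if unalignable. Attributes:
#'   `n_inserted_dropped`, `mean_score`.
#' @export
align_query_to_reference <- function(query_bases, refdb,
                                     min_mean_score = 0.15) {
  stopifnot(nchar(query_bases) >= 20L)
  prof <- reference_profile(refdb)
  s <- prof$n_columns
  q <- encode_states(query_bases)
  nq <- length(q)
  ## score of query base i against column j
  score <- matrix(0, nq, s)
  obs <- which(!is.na(q))
  if (length(obs)) score[obs, ] <- prof$freq[q[obs], , drop = FALSE]
  del_cost <- -0.6 * prof$occupancy   # skip column j (gap in query)
  ins_cost <- -1.0                    # drop query base (insertion)
  ## DP over (query position i, column j), global in both
  dp <- matrix(-Inf, nq + 1L, s + 1L)
  dp[1L, ] <- c(0, cumsum(del_cost))
  dp[, 1L] <- c(0, cumsum(rep(ins_cost, nq)))
  bt <- matrix(0L, nq + 1L, s + 1L)   # 1 = diag, 2 = del col, 3 = ins base
  bt[1L, -1L] <- 2L; bt[-1L, 1L] <- 3L
  for (i in seq_len(nq)) {
    diag_sc <- dp[i, -(s + 1L)] + score[i, ]
    up_sc <- dp[i, -1L] + ins_cost
    row <- numeric(s + 1L); row[1L] <- dp[i + 1L, 1L]
    btrow <- integer(s + 1L); btrow[1L] <- 3L
    for (j in seq_len(s)) {
      left_sc <- row[j] + del_cost[j]
      best <- max(diag_sc[j], left_sc, up_sc[j])
      row[j + 1L] <- best
      btrow[j + 1L] <- if (best == diag_sc[j]) 1L else if (best == left_sc) 2L else 3L
    }
    dp[i + 1L, ] <- row
    bt[i + 1L, ] <- btrow
  }
  mean_score <- dp[nq + 1L, s + 1L] / nq
  if (mean_score < min_mean_score) {
    out <- NA_character_
    attr(out, "mean_score") <- mean_score
    return(out)
  }
  ## traceback
  aligned <- rep("-", s)
  qchars <- strsplit(toupper(query_bases), "", fixed = TRUE)[[1]]
  i <- nq + 1L; j <- s + 1L; dropped <- 0L
  while (i > 1L || j > 1L) {
    move <- bt[i, j]
    if (move == 1L) {
      aligned[j - 1L] <- qchars[i - 1L]; i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      j <- j - 1L
    } else {
      dropped <- dropped + 1L; i <- i - 1L
    }
  }
  out <- paste(aligned, collapse = "")
  attr(out, "n_inserted_dropped") <- dropped
  attr(out, "mean_score") <- mean_score
  out
}
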