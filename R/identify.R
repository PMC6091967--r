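## Turning placements into identifications: pendant-branch-length
## outlier filtering, nearest-leaf OTU assignment, multi-order flags,
## database-hit filtering, and the 0-18 concordance score of the
## tree-based identification against two database identifications.

#' Nearest reference leaf of a placement
#'
#' The leaf minimizing the path length (sum of branch lengths) from the
#' attachment point of the placement, ignoring the pendant edge.
#' `distal_length` is the distance from the attachment point to the
#' child (away-from-root) node of the edge. Ties are broken
#' lexicographically by leaf label.
#'
#' @param refdb Reference database.
#' @param placement A one-row placement (list or data.frame row) with
#'   `edge_num` and `distal_length`.
#' @return The leaf (species) label.
#' @export
nearest_leaf <- function(refdb, placement) {
  tree <- refdb$tree
  e <- which(tree$edge.num == placement$edge_num[[1L]])
  if (length(e) != 1L) stop("placement references an unknown edge number")
  d_child <- placement$distal_length[[1L]]
  d_parent <- tree$edge.length[e] - d_child
  nd <- node_distances(refdb)
  ntip <- length(tree$tip.label)
  child <- tree$edge[e, 2L]; parent <- tree$edge[e, 1L]
  ## every leaf path leaves the edge through either endpoint
  dist_leaf <- pmin(d_child + nd[child, seq_len(ntip)],
                    d_parent + nd[parent, seq_len(ntip)])
  labs <- tree$tip.label
  best <- which(dist_leaf == min(dist_leaf))
  labs[best][order(labs[best])][1L]
}

## Cached all-pairs node distance matrix (path lengths along the tree).
node_distances <- function(refdb) {
  cache <- attr(refdb, "node_dist_cache")
  if (!is.null(cache) && !is.null(cache$d)) return(cache$d)
  d <- ape::dist.nodes(refdb$tree)
  if (!is.null(cache)) cache$d <- d
  d
}

#' Attach a distance cache to a reference database
#'
#' Optional speed-up when calling [nearest_leaf()] many times: the
#' all-pairs node distance matrix is computed once and reused.
#'
#' @param refdb Reference database.
#' @return The same `ref_db` with a mutable cache attribute.
#' @export
cache_distances <- function(refdb) {
  attr(refdb, "node_dist_cache") <- new.env(parent = emptyenv())
  refdb
}

#' Classify a query's placements into identified / outlier / unalignable
#'
#' A query is *identified* iff the pendant length of its best placement
#' is strictly shorter than the outlier threshold; otherwise it is an
#' *outlier*. A query with no placements (unalignable) is
#' *unalignable*. Identified queries receive the species label of the
#' nearest leaf of the best placement as OTU label; the nearest-leaf
#' species of all reported placements are recorded as alternatives,
#' together with the set of taxonomic orders they span.
#'
#' @param placements Placement data.frame from [place_query()] (best
#'   first), or with zero rows for an unalignable query.
#' @param refdb Reference database.
#' @param threshold An [quantile_threshold()] object (or numeric).
#' @param query_id,sample_id,n_reads Query metadata to carry through.
#' @param lwr_cutoff Accumulated like-weight-ratio cutoff delimiting
#'   the *reported* placements used for alternatives and order flags.
#' @return An object of class `identification`: list with `query_id`,
#'   `sample_id`, `n_reads`, `status`, `otu_label`, `best_placement`,
#'   `alt_species`, `orders`, `pendant_length`, `multi_order`.
#' @export
classify_placement <- function(placements, refdb, threshold,
                               query_id = NA_character_,
                               sample_id = NA_character_,
                               n_reads = NA_integer_,
                               lwr_cutoff = 0.999) {
  thr <- if (inherits(threshold, "outlier_threshold")) threshold$value else threshold
  if (is.null(placements) || nrow(placements) == 0L) {
    return(structure(list(query_id = query_id, sample_id = sample_id,
                          n_reads = n_reads, status = "unalignable",
                          otu_label = NA_character_, best_placement = NULL,
                          alt_species = character(), orders = character(),
                          pendant_length = NA_real_, multi_order = FALSE),
                     class = "identification"))
  }
  best <- placements[1L, ]
  status <- if (best$pendant_length < thr) "identified" else "outlier"
  keep <- which(cumsum(placements$like_weight_ratio) >= lwr_cutoff)[1L]
  if (is.na(keep)) keep <- nrow(placements)
  reported <- placements[seq_len(keep), , drop = FALSE]
  alt <- vapply(seq_len(nrow(reported)), function(i) {
    nearest_leaf(refdb, reported[i, ])
  }, character(1))
  orders <- unique(refdb$taxonomy$order[match(alt, refdb$taxonomy$species)])
  orders <- sort(orders[!is.na(orders)])
  structure(list(query_id = query_id, sample_id = sample_id,
                 n_reads = n_reads, status = status,
                 otu_label = if (status == "identified") alt[[1L]] else NA_character_,
                 best_placement = best, alt_species = unique(alt),
                 orders = orders, pendant_length = best$pendant_length,
                 multi_order = length(orders) > 1L),
            class = "identification")
}

#' Multi-order flag of an identification
#'
#' TRUE iff the nearest-leaf species of the reported placements span
#' more than one taxonomic order (the best result is unaffected; the
#' flag is informational).
#'
#' @param result An `identification` from [classify_placement()].
#' @param taxonomy Unused (the orders are already resolved); kept for
#'   call-site symmetry.
#' @return Logical flag; the order set is in `attr(, "orders")`.
#' @export
multi_order_flag <- function(result, taxonomy = NULL) {
  out <- isTRUE(result$multi_order)
  attr(out, "orders") <- result$orders
  out
}

#' Filter database hits by percent identity
#'
#' @param hits Data.frame with columns `query_id`, `db_name`, `species`,
#'   `percent_identity`.
#' @param min_identity Minimum percent identity retained (hits with
#'   identity greater than or equal to the cutoff are kept).
#' @return The retained hits.
#' @export
filter_db_hits <- function(hits, min_identity = 97) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            all(hits$percent_identity >= 0 & hits$percent_identity <= 100))
  res <- hits[hits$percent_identity >= min_identity, , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Rank-ladder score of one unordered pair of species labels:
## 6 same species, 5 same genus, 3 same order, 1 same phylum, else 0.
## A missing member scores 0. Labels absent from the taxonomy are
## scored at the deepest rank derivable from the label (genus token).
pair_score <- function(a, b, taxonomy) {
  if (is.na(a) || is.na(b)) return(0L)
  if (a == b) return(6L)
  look <- function(sp) {
    i <- match(sp, taxonomy$species)
    genus_tok <- strsplit(sp, "\\s+")[[1]][1]
    if (is.na(i)) list(genus = genus_tok, order = NA_character_,
                       phylum = NA_character_, known = FALSE)
    else list(genus = taxonomy$genus[i], order = taxonomy$order[i],
              phylum = taxonomy$phylum[i], known = TRUE)
  }
  ta <- look(a); tb <- look(b)
  if (identical(ta$genus, tb$genus)) return(5L)
  if (!is.na(ta$order) && !is.na(tb$order) && ta$order == tb$order) return(3L)
  if (!is.na(ta$phylum) && !is.na(tb$phylum) && ta$phylum == tb$phylum) return(1L)
  0L
}

#' Concordance score of three identifications (ID score, 0-18)
#'
#' Sum of the three pairwise comparisons between the tree-based species
#' and two database species, each pair scored 6 (same species), 5 (same
#' genus), 3 (same order), 1 (same phylum) or 0; pairs with a missing
#' member score 0.
#'
#' @param tree_species,db1_species,db2_species Species labels (or NA).
#' @param taxonomy Taxonomy data.frame (species, genus, family, order,
#'   phylum). Labels absent from it are scored from the genus token of
#'   the label, with a message.
#' @return An object of class `id_score`: list with the three labels,
#'   `pairwise` (named integer vector) and `score` (0-18).
#' @export
id_score <- function(tree_species, db1_species, db2_species, taxonomy) {
  labs <- c(tree_species, db1_species, db2_species)
  unknown <- setdiff(labs[!is.na(labs)], taxonomy$species)
  if (length(unknown)) {
    message("species not in taxonomy, scored from the genus token: ",
            paste(unknown, collapse = ", "))
  }
  pw <- c(tree_db1 = pair_score(tree_species, db1_species, taxonomy),
          tree_db2 = pair_score(tree_species, db2_species, taxonomy),
          db1_db2 = pair_score(db1_species, db2_species, taxonomy))
  structure(list(tree_species = tree_species, db1_species = db1_species,
                 db2_species = db2_species, pairwise = pw,
                 score = sum(pw)),
            class = "id_score")
}

#' @export
print.id_score <- function(x, ...) {
  cat(sprintf("id_score: %d/18 (tree-db1 %d, tree-db2 %d, db1-db2 %d)\n",
              x$score, x$pairwise[["tree_db1"]], x$pairwise[["tree_db2"]],
              x$pairwise[["db1_db2"]]))
  invisible(x)
}

#' Tabulate a list of identifications
#'
#' @param identifications List of `identification` objects.
#' @return A data.frame with one row per query: `query_id`,
#'   `sample_id`, `n_reads`, `status`, `otu_label`, `pendant_length`,
#'   `best_lwr`, `multi_order`, `orders` (collapsed with ";").
#' @export
identification_table <- function(identifications) {
  data.frame(
    query_id = vapply(identifications, `[[`, character(1), "query_id"),
    sample_id = vapply(identifications, `[[`, character(1), "sample_id"),
    n_reads = vapply(identifications, function(x) as.integer(x$n_reads), integer(1)),
    status = vapply(identifications, `[[`, character(1), "status"),
    otu_label = vapply(identifications, `[[`, character(1), "otu_label"),
    pendant_length = vapply(identifications, `[[`, numeric(1), "pendant_length"),
    best_lwr = vapply(identifications, function(x) {
      if (is.null(x$best_placement)) NA_real_ else x$best_placement$like_weight_ratio
    }, numeric(1)),
    multi_order = vapply(identifications, function(x) isTRUE(x$multi_order), logical(1)),
    orders = vapply(identifications, function(x) paste(x$orders, collapse = ";"),
                    character(1)),
    stringsAsFactors = FALSE)
}
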