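## EPA-style maximum-likelihood placement of aligned query sequences on
## a fixed reference tree. For every edge of the tree the query is
## attached by a new node at the edge midpoint (optionally with the
## attachment point optimized), its pendant branch length is optimized
## by 1-D likelihood maximization, and per-edge log-likelihoods are
## normalized into like-weight ratios.
##
## The engine is the standard pruning recursion with per-node scaling:
## a down-pass computes, for every node, the conditional likelihood of
## its subtree; an up-pass computes, for every edge, the conditional
## likelihood of the remainder of the tree at the edge's parent node.
## Both are combined at the attachment point.

## Edge indices of `tree$edge` in postorder (children before parent),
## visiting the children of each node in edge-matrix order.
postorder_edges <- function(tree) {
  edge <- tree$edge
  n_edge <- nrow(edge)
  children <- split(seq_len(n_edge), edge[, 1L])
  out <- integer(n_edge)
  k <- 0L
  rec <- function(node) {
    for (e in children[[as.character(node)]]) {
      child <- edge[e, 2L]
      if (!is.null(children[[as.character(child)]])) rec(child)
      k <<- k + 1L
      out[k] <<- e
    }
  }
  rec(length(tree$tip.label) + 1L)
  out
}

#' Assign deterministic jplace edge numbers to a tree
#'
#' Edges are numbered 0-based in postorder (children of a node visited
#' in edge-matrix order). Renumbering an already numbered tree yields
#' identical numbers.
#'
#' @param tree An [ape::phylo] tree (rooted; polytomies allowed).
#' @return The tree with an integer vector `edge.num` parallel to the
#'   rows of `tree$edge`.
#' @export
edge_numbering <- function(tree) {
  po <- postorder_edges(tree)
  num <- integer(nrow(tree$edge))
  num[po] <- seq_along(po) - 1L
  tree$edge.num <- num
  tree
}

## One-hot (or all-ones for missing) tip likelihoods, 4 x n_sites.
tip_likelihood <- function(enc) {
  s <- length(enc)
  m <- matrix(1, 4L, s)
  obs <- which(!is.na(enc))
  if (length(obs)) {
    m[, obs] <- 0
    m[cbind(enc[obs], obs)] <- 1
  }
  m
}

## Rescale a conditional-likelihood matrix column-wise, returning the
## matrix and the per-site log scale factors.
rescale_cl <- function(m, logsc) {
  sc <- apply(m, 2L, max)
  sc[sc <= 0] <- 1
  list(m = sweep(m, 2L, sc, "/"), logsc = logsc + log(sc))
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning with per-node scaling; gaps and N are treated as
#' missing data (marginalized).
#'
#' @param tree An [ape::phylo] tree with branch lengths whose tip labels
#'   match the alignment names.
#' @param alignment Named character vector of equal-length (gapped)
#'   sequences, one per tip.
#' @param model A [subst_model()].
#' @return The total log-likelihood (sum over sites).
#' @export
compute_loglik <- function(tree, alignment, model = subst_model()) {
  down <- downpass(tree, alignment, model)
  root <- length(tree$tip.label) + 1L
  site_ll <- log(colSums(model$freqs * down$D[[root]])) + down$Dlog[[root]]
  sum(site_ll)
}

## Down-pass: per-node conditional likelihoods D (4 x S) and per-site
## log scale factors Dlog.
downpass <- function(tree, alignment, model) {
  ntip <- length(tree$tip.label)
  stopifnot(setequal(names(alignment), tree$tip.label))
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("alignment columns must be equal")
  s <- widths[[1L]]
  if (s < 1L) stop("zero-length alignment")
  n_nodes <- ntip + tree$Nnode
  D <- vector("list", n_nodes)
  Dlog <- vector("list", n_nodes)
  for (i in seq_len(ntip)) {
    D[[i]] <- tip_likelihood(encode_states(alignment[[tree$tip.label[i]]]))
    Dlog[[i]] <- numeric(s)
  }
  po <- postorder_edges(tree)
  edge <- tree$edge
  for (e in po) {
    p <- edge[e, 1L]; child <- edge[e, 2L]
    tmat <- transition_prob(model, tree$edge.length[e])
    contrib <- tmat %*% D[[child]]
    if (is.null(D[[p]])) {
      D[[p]] <- contrib
      Dlog[[p]] <- Dlog[[child]]
    } else {
      D[[p]] <- D[[p]] * contrib
      Dlog[[p]] <- Dlog[[p]] + Dlog[[child]]
    }
  }
  ## rescale internal nodes once assembled
  for (n in (ntip + 1L):n_nodes) {
    r <- rescale_cl(D[[n]], Dlog[[n]])
    D[[n]] <- r$m; Dlog[[n]] <- r$logsc
  }
  list(D = D, Dlog = Dlog, n_sites = s)
}

#' Precompute per-edge attachment conditionals
#'
#' For every edge of the reference tree, computes the conditional
#' likelihoods at the (default midpoint) attachment point from the
#' subtree below the edge and from the remainder of the tree. The
#' result makes placement of each query a cheap 1-D optimization.
#'
#' @param refdb A reference database from [load_reference()] or
#'   [simulate_reference_db()].
#' @param model A [subst_model()].
#' @return An opaque list used by [place_query()].
#' @export
placement_prep <- function(refdb, model = subst_model()) {
  tree <- refdb$tree
  if (is.null(tree$edge.num)) tree <- edge_numbering(tree)
  dp <- downpass(tree, refdb$alignment, model)
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  n_edge <- nrow(edge)
  s <- dp$n_sites
  ## up-pass in reverse postorder: M[node] = conditional of everything
  ## outside the node's subtree, evaluated at the node.
  M <- vector("list", ntip + tree$Nnode)
  Mlog <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  M[[root]] <- matrix(1, 4L, s); Mlog[[root]] <- numeric(s)
  U <- vector("list", n_edge)
  Ulog <- vector("list", n_edge)
  children <- split(seq_len(n_edge), edge[, 1L])
  for (e in rev(postorder_edges(tree))) {
    p <- edge[e, 1L]; child <- edge[e, 2L]
    sib <- setdiff(children[[as.character(p)]], e)
    u <- M[[p]]; ulog <- Mlog[[p]]
    for (e2 in sib) {
      u <- u * (transition_prob(model, tree$edge.length[e2]) %*% D_of(dp, edge[e2, 2L]))
      ulog <- ulog + dp$Dlog[[edge[e2, 2L]]]
    }
    r <- rescale_cl(u, ulog)
    U[[e]] <- r$m; Ulog[[e]] <- r$logsc
    M[[child]] <- transition_prob(model, tree$edge.length[e]) %*% r$m
    Mlog[[child]] <- r$logsc
  }
  ## midpoint attachment conditionals
  W <- vector("list", n_edge)
  Wlog <- vector("list", n_edge)
  colsum0 <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    half <- tree$edge.length[e] / 2
    a <- transition_prob(model, half) %*% dp$D[[edge[e, 2L]]]
    b <- transition_prob(model, half) %*% U[[e]]
    w <- model$freqs * a * b
    W[[e]] <- w
    Wlog[[e]] <- dp$Dlog[[edge[e, 2L]]] + Ulog[[e]]
    colsum0[[e]] <- colSums(w)
  }
  list(tree = tree, model = model, n_sites = s, down = dp,
       U = U, Ulog = Ulog, W = W, Wlog = Wlog, colsum0 = colsum0)
}

D_of <- function(dp, node) dp$D[[node]]

## Per-edge log-likelihood of a query attached with pendant length t,
## given the precomputed attachment conditionals of edge `e`.
edge_query_loglik <- function(prep, e, t, obs, qi) {
  p <- transition_prob(prep$model, t)
  w <- prep$W[[e]]
  vals <- crossprod(p, w)[cbind(qi, obs)]
  miss_ll <- if (length(obs) < prep$n_sites) {
    sum(log(pmax(prep$colsum0[[e]][-obs], 1e-300)))
  } else 0
  sum(log(pmax(vals, 1e-300))) + miss_ll + sum(prep$Wlog[[e]])
}

#' Place an aligned query on every edge of the reference tree
#'
#' The query is attached to each edge at the midpoint (or, with
#' `optimize_distal = TRUE`, at an optimized attachment point); the
#' pendant branch length is optimized on `[0, 5]` substitutions/site to
#' a tolerance of 1e-6. Like-weight ratios are normalized likelihoods
#' over all evaluated edges and sum to 1.
#'
#' @param aligned_query Gapped query string of exactly
#'   `refdb$n_columns` characters (from [align_query_to_reference()]).
#' @param refdb Reference database.
#' @param model A [subst_model()].
#' @param prep Optional precomputed [placement_prep()] (computed on the
#'   fly otherwise; pass it when placing many queries).
#' @param optimize_distal Also optimize the attachment position along
#'   the edge (slower; midpoint heuristic by default).
#' @return A data.frame of placements sorted by log-likelihood
#'   (descending; ties broken by smallest edge number) with columns
#'   `edge_num`, `log_likelihood`, `like_weight_ratio`,
#'   `distal_length`, `pendant_length`. Zero rows if the query carries
#'   no information (all missing).
#' @export
place_query <- function(aligned_query, refdb, model = subst_model(),
                        prep = NULL, optimize_distal = FALSE) {
  if (is.null(prep)) prep <- placement_prep(refdb, model)
  tree <- prep$tree
  enc <- encode_states(aligned_query)
  if (length(enc) != prep$n_sites) {
    stop(sprintf("aligned query has %d columns; reference has %d",
                 length(enc), prep$n_sites))
  }
  obs <- which(!is.na(enc))
  empty <- data.frame(edge_num = integer(), log_likelihood = numeric(),
                      like_weight_ratio = numeric(), distal_length = numeric(),
                      pendant_length = numeric())
  if (length(obs) == 0L) return(empty)
  qi <- enc[obs]
  n_edge <- nrow(tree$edge)
  ll <- numeric(n_edge); pend <- numeric(n_edge); dist <- numeric(n_edge)
  for (e in seq_len(n_edge)) {
    f <- function(t) edge_query_loglik(prep, e, t, obs, qi)
    opt <- stats::optimize(f, interval = c(0, 5), maximum = TRUE, tol = 1e-6)
    ll0 <- f(0)
    if (ll0 >= opt$objective) {
      pend[e] <- 0; ll[e] <- ll0
    } else {
      pend[e] <- opt$maximum; ll[e] <- opt$objective
    }
    dist[e] <- tree$edge.length[e] / 2
    if (optimize_distal) {
      res <- optimize_attachment(prep, e, obs, qi, pend[e])
      ll[e] <- res$ll; pend[e] <- res$pendant; dist[e] <- res$distal
    }
  }
  lwr <- exp(ll - max(ll))
  lwr <- lwr / sum(lwr)
  out <- data.frame(edge_num = tree$edge.num, log_likelihood = ll,
                    like_weight_ratio = lwr, distal_length = dist,
                    pendant_length = pend)
  out[order(-out$log_likelihood, out$edge_num), , drop = FALSE]
}

## Coordinate ascent over (distal, pendant) for one edge; distal is the
## distance from the attachment point to the child (away-from-root)
## node of the edge.
optimize_attachment <- function(prep, e, obs, qi, pend_init, n_iter = 3L) {
  tree <- prep$tree
  len <- tree$edge.length[e]
  child <- tree$edge[e, 2L]
  dcl <- prep$down$D[[child]]
  u <- prep$U[[e]]
  wlog <- prep$down$Dlog[[child]] + prep$Ulog[[e]]
  f2 <- function(d, t) {
    a <- transition_prob(prep$model, d) %*% dcl
    b <- transition_prob(prep$model, len - d) %*% u
    w <- prep$model$freqs * a * b
    p <- transition_prob(prep$model, t)
    vals <- crossprod(p, w)[cbind(qi, obs)]
    miss_ll <- if (length(obs) < prep$n_sites) {
      sum(log(pmax(colSums(w)[-obs], 1e-300)))
    } else 0
    sum(log(pmax(vals, 1e-300))) + miss_ll + sum(wlog)
  }
  d <- len / 2; t <- pend_init
  for (i in seq_len(n_iter)) {
    if (len > 0) {
      d <- stats::optimize(function(x) f2(x, t), c(0, len),
                           maximum = TRUE, tol = 1e-6)$maximum
    }
    od <- stats::optimize(function(x) f2(d, x), c(0, 5),
                          maximum = TRUE, tol = 1e-6)
    t <- if (f2(d, 0) >= od$objective) 0 else od$maximum
  }
  list(ll = f2(d, t), pendant = t, distal = d)
}

#' Assemble placements into a jplace document
#'
#' Per query, entries are reported in like-weight-ratio descending
#' order until the accumulated ratio reaches 0.999 (the remaining
#' entries are dropped from the document).
#'
#' @param placements_by_query Named list of placement data.frames from
#'   [place_query()].
#' @param refdb Reference database (supplies the numbered tree).
#' @param multiplicities Optional numeric vector (read counts per
#'   query), recycled; defaults to 1.
#' @param lwr_cutoff Accumulated like-weight-ratio reporting cutoff.
#' @return A `jplace` object (see [read_jplace()]).
#' @export
build_jplace <- function(placements_by_query, refdb, multiplicities = 1,
                         lwr_cutoff = 0.999) {
  stopifnot(!is.null(names(placements_by_query)))
  tree <- refdb$tree
  if (is.null(tree$edge.num)) tree <- edge_numbering(tree)
  mult <- rep_len(multiplicities, length(placements_by_query))
  placements <- lapply(seq_along(placements_by_query), function(i) {
    p <- placements_by_query[[i]]
    p <- p[order(-p$like_weight_ratio, p$edge_num), , drop = FALSE]
    keep <- which(cumsum(p$like_weight_ratio) >= lwr_cutoff)[1L]
    if (is.na(keep)) keep <- nrow(p)
    list(name = names(placements_by_query)[i], multiplicity = mult[i],
         p = p[seq_len(keep), c("edge_num", "log_likelihood",
                                "like_weight_ratio", "distal_length",
                                "pendant_length")])
  })
  names(placements) <- names(placements_by_query)
  ## jplace stores the likelihood column under the name "likelihood"
  placements <- lapply(placements, function(pl) {
    names(pl$p)[names(pl$p) == "log_likelihood"] <- "likelihood"
    pl
  })
  structure(list(tree = tree, placements = placements,
                 fields = jplace_required_fields, version = 3L,
                 metadata = list(invocation = "treebard")),
            class = "jplace")
}
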