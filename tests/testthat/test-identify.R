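# Pendant-length outlier filtering, nearest leaf, multi-order flags,
# database-hit filtering, ID score.

fake_placement <- function(edge_num, pendant, lwr = 1, distal = 0.01) {
  data.frame(edge_num = edge_num, log_likelihood = -100,
             like_weight_ratio = lwr, distal_length = distal,
             pendant_length = pendant)
}

test_that("identification status follows the strict pendant threshold", {
  db <- toy_refdb()
  thr <- quantile_threshold(c(rep(0.1, 999), 0.773), q = 0.5)
  thr$value <- 0.773   # fixed threshold for the boundary cases
  term_edge <- db$tree$edge.num[match(1, db$tree$edge[, 2])]

  r1 <- classify_placement(fake_placement(term_edge, 0.10), db, thr, "q1", "S1", 100L)
  expect_equal(r1$status, "identified")
  expect_equal(r1$otu_label, db$tree$tip.label[1])

  r2 <- classify_placement(fake_placement(term_edge, 0.90), db, thr, "q2", "S1", 50L)
  expect_equal(r2$status, "outlier")
  expect_true(is.na(r2$otu_label))

  # pendant exactly at the threshold is an outlier ("shorter than")
  r3 <- classify_placement(fake_placement(term_edge, 0.773), db, thr, "q3", "S1", 10L)
  expect_equal(r3$status, "outlier")

  r4 <- classify_placement(NULL, db, thr, "q4", "S1", 10L)
  expect_equal(r4$status, "unalignable")

  # the three statuses partition the queries
  tab <- identification_table(list(r1, r2, r3, r4))
  expect_equal(sort(table(tab$status), decreasing = TRUE),
               sort(c(identified = 1, outlier = 2, unalignable = 1),
                    decreasing = TRUE), ignore_attr = TRUE)
})

test_that("nearest leaf minimizes patristic distance from the attachment", {
  db <- toy_refdb()
  tr <- db$tree
  # placement on a terminal edge names that leaf
  for (lf in c(1L, 4L)) {
    e <- tr$edge.num[match(lf, tr$edge[, 2])]
    pl <- fake_placement(e, 0.1, distal = tr$edge.length[match(lf, tr$edge[, 2])] / 2)
    expect_equal(nearest_leaf(db, pl), tr$tip.label[lf])
  }
  # ties break lexicographically: equidistant leaves via a symmetric tree
  aln <- setNames(rep(strrep("A", 30), 4),
                  c("Baetis lutheri", "Ecdyonurus venosus", "Zeta zeta", "Alpha beta"))
  tax <- data.frame(species = names(aln), genus = sub(" .*", "", names(aln)),
                    family = "F", order = "O", phylum = "P")
  tr2 <- read_newick("((Baetis_lutheri:0.1,Ecdyonurus_venosus:0.1):0.1,(Zeta_zeta:0.1,Alpha_beta:0.3):0.1);")
  tr2$tip.label <- gsub("_", " ", tr2$tip.label)
  db2 <- ref_db(aln, tr2, tax)
  # attach at the midpoint of the internal edge above (Baetis, Ecdyonurus):
  # both are 0.05 + 0.1 away -> lexicographic winner is Baetis lutheri
  int_node <- db2$tree$edge[match(1L, db2$tree$edge[, 2]), 1]
  e_int <- db2$tree$edge.num[match(int_node, db2$tree$edge[, 2])]
  pl <- fake_placement(e_int, 0.2, distal = db2$tree$edge.length[
    match(int_node, db2$tree$edge[, 2])] / 2)
  expect_equal(nearest_leaf(db2, pl), "Baetis lutheri")
})

test_that("nearest leaf equals an independent shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(40)
  n <- 30
  tr <- ape::rtree(n)
  aln <- setNames(random_bases(n, 30), tr$tip.label)
  tax <- data.frame(species = tr$tip.label, genus = tr$tip.label,
                    family = "F", order = "O", phylum = "P")
  db <- ref_db(aln, tr, tax)
  tr <- db$tree
  # oracle graph: one vertex per node plus one for the attachment point
  for (i in 1:12) {
    e <- sample(nrow(tr$edge), 1)
    d_child <- runif(1, 0, tr$edge.length[e])
    n_nodes <- length(tr$tip.label) + tr$Nnode
    att <- n_nodes + 1L        # new vertex for the attachment point
    em <- rbind(cbind(tr$edge, tr$edge.length)[-e, , drop = FALSE],
                c(tr$edge[e, 2], att, d_child),
                c(tr$edge[e, 1], att, tr$edge.length[e] - d_child))
    g <- igraph::graph_from_data_frame(
      data.frame(from = em[, 1], to = em[, 2], weight = em[, 3]),
      directed = FALSE)
    dd <- igraph::distances(g, v = as.character(att),
                            to = as.character(seq_along(tr$tip.label)))
    want_dist <- min(dd)
    cand <- tr$tip.label[as.integer(colnames(dd)[dd == want_dist])]
    want <- sort(cand)[1]
    got <- nearest_leaf(db, fake_placement(tr$edge.num[e], 0.1, distal = d_child))
    expect_equal(got, want)
  }
})

test_that("multi-order flag spans the reported placements only", {
  db <- toy_refdb()
  tr <- db$tree
  e_baetis <- tr$edge.num[match(1L, tr$edge[, 2])]
  e_dixella <- tr$edge.num[match(4L, tr$edge[, 2])]
  thr <- quantile_threshold(rep(0.5, 10), 0.9)

  # two strong placements in different orders -> flagged
  pl <- rbind(fake_placement(e_baetis, 0.01, lwr = 0.6),
              fake_placement(e_dixella, 0.01, lwr = 0.4))
  r <- classify_placement(pl, db, thr, "q1", "S1", 10L)
  expect_true(multi_order_flag(r))
  expect_equal(attr(multi_order_flag(r), "orders"), c("Diptera", "Ephemeroptera"))
  # the best result is unchanged by the flag
  expect_equal(r$otu_label, "Baetis lutheri")

  # placements within one order -> not flagged
  e_baetis2 <- tr$edge.num[match(2L, tr$edge[, 2])]
  pl2 <- rbind(fake_placement(e_baetis, 0.01, lwr = 0.6),
               fake_placement(e_baetis2, 0.01, lwr = 0.4))
  expect_false(multi_order_flag(classify_placement(pl2, db, thr, "q2", "S1", 10L)))

  # a single reported placement can never be multi-order: the second
  # entry below the LWR cutoff is not reported
  pl3 <- rbind(fake_placement(e_baetis, 0.01, lwr = 0.9995),
               fake_placement(e_dixella, 0.01, lwr = 0.0005))
  expect_false(multi_order_flag(classify_placement(pl3, db, thr, "q3", "S1", 10L)))
})

test_that("database hits are filtered at 97% and 98% inclusively", {
  hits <- data.frame(
    query_id = sprintf("q%d", 1:4), db_name = "bold",
    species = "Baetis lutheri",
    percent_identity = c(97.0, 96.9, 97.5, 98.0))
  expect_equal(filter_db_hits(hits, 97)$query_id, c("q1", "q3", "q4"))
  expect_equal(filter_db_hits(hits, 98)$query_id, "q4")
  expect_error(filter_db_hits(transform(hits, percent_identity = 101), 97))
})

test_that("the ID score ladder sums three pairwise comparisons", {
  db <- toy_refdb()
  tax <- db$taxonomy

  # all three identical -> 18
  expect_equal(id_score("Baetis lutheri", "Baetis lutheri", "Baetis lutheri",
                        tax)$score, 18L)
  # same genus everywhere -> 15
  s <- id_score("Baetis lutheri", "Baetis fuscatus", "Baetis lutheri", tax)
  expect_equal(unname(s$pairwise), c(5L, 6L, 5L))
  s2 <- suppressMessages(
    id_score("Baetis lutheri", "Baetis fuscatus", "Baetis rhodani", tax))
  expect_equal(s2$score, 15L)
  # same order, different genus -> 3 per pair (family is skipped)
  s3 <- id_score("Baetis lutheri", "Ecdyonurus venosus", NA, tax)
  expect_equal(s3$score, 3L)
  # three different phyla -> 1+1+1
  tax3 <- data.frame(species = c("Aa aa", "Bb bb", "Cc cc"),
                     genus = c("Aa", "Bb", "Cc"), family = "F",
                     order = c("O1", "O2", "O3"),
                     phylum = c("P1", "P1", "P1"))
  expect_equal(id_score("Aa aa", "Bb bb", "Cc cc", tax3)$score, 3L)
  # no shared phylum at all -> 0
  tax0 <- transform(tax3, phylum = c("P1", "P2", "P3"))
  expect_equal(id_score("Aa aa", "Bb bb", "Cc cc", tax0)$score, 0L)
  # missing members score 0 in their pairs
  expect_equal(id_score("Baetis lutheri", NA, NA, tax)$score, 0L)
  # symmetric under permutation of inputs
  p <- id_score("Baetis lutheri", "Ecdyonurus venosus", "Dixella autumnalis", tax)
  q <- id_score("Dixella autumnalis", "Baetis lutheri", "Ecdyonurus venosus", tax)
  expect_equal(p$score, q$score)
})

test_that("contaminant queries are overwhelmingly classified outlier", {
  set.seed(41)
  db <- simulate_reference_db(n_species = 50, seq_len = 130, seed = 8)
  prep <- placement_prep(db)
  db <- cache_distances(db)
  thr <- quantile_threshold(terminal_branch_lengths(db$tree), 0.999)
  root_seq <- db$truth$root_seq
  n <- 100
  out <- vapply(seq_len(n), function(i) {
    contam <- evolve_sequence(root_seq, 1.75)
    aligned <- align_query_to_reference(substr(contam, 1, 124), db)
    if (is.na(aligned)) return("unalignable")
    pl <- place_query(aligned, db, prep = prep)
    classify_placement(pl, db, thr, sprintf("c%03d", i), "S1", 20L)$status
  }, character(1))
  expect_gte(mean(out == "outlier"), 0.90)
})
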