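# Trimming, greedy clustering, abundance filtering, chimera detection.

test_that("primer trimming enforces the 124-bp length boundary", {
  cfg <- pipeline_config()
  np <- nchar(PRIMER)
  set.seed(10)
  insert124 <- random_bases(1, 124)
  insert123 <- random_bases(1, 123)
  recs <- make_reads(c(
    paste0(PRIMER, insert124),              # kept: exactly 124 after trim
    paste0(PRIMER, insert123),              # dropped: 123 after trim
    paste0(mutate_k(PRIMER, 1), insert124), # kept: 1 primer mismatch allowed
    paste0(mutate_k(PRIMER, 2), insert124), # dropped: no primer match
    random_bases(1, 150)))                  # dropped: no primer at all
  out <- trim_and_filter(recs, cfg)
  expect_equal(out$id, c("r0001", "r0003"))
  expect_equal(nchar(out$bases), c(124L, 124L))
  expect_equal(out$bases[1], insert124)
  expect_equal(attr(out, "n_no_primer"), 2L)
  expect_equal(attr(out, "n_short"), 1L)
})

test_that("greedy clustering obeys the 3-mismatch divergence rule", {
  cfg <- pipeline_config()
  set.seed(11)
  base <- random_bases(1, 124)

  # 20 identical reads form one cluster
  cl <- greedy_cluster(make_reads(rep(base, 20)), cfg)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_reads, 20L)
  expect_equal(length(cl$member_ids[[1]]), 20L)

  # two reads differing at exactly 4 positions split into 2 clusters;
  # at 3 positions they merge
  far <- mutate_k(base, 4)
  expect_equal(nrow(greedy_cluster(make_reads(c(base, far)), cfg)), 2L)
  near <- mutate_k(base, 3)
  expect_equal(nrow(greedy_cluster(make_reads(c(base, near)), cfg)), 1L)

  expect_equal(nrow(greedy_cluster(make_reads(character(0)), cfg)), 0L)
})

test_that("greedy clustering matches an independent brute-force oracle", {
  # oracle: a direct re-implementation of the stated greedy rule
  oracle_cluster <- function(bases, max_div) {
    uniq <- unique(bases)
    mult <- as.integer(table(factor(bases, levels = uniq)))
    ord <- order(-mult, seq_along(uniq))
    reps <- character(0); assign <- integer(length(uniq))
    dist <- function(a, b) {
      n <- min(nchar(a), nchar(b))
      sum(strsplit(a, "")[[1]][1:n] != strsplit(b, "")[[1]][1:n]) +
        abs(nchar(a) - nchar(b))
    }
    for (i in ord) {
      hit <- 0L
      for (k in seq_along(reps)) {
        if (dist(uniq[i], reps[k]) <= max_div) { hit <- k; break }
      }
      if (hit == 0L) { reps <- c(reps, uniq[i]); hit <- length(reps) }
      assign[i] <- hit
    }
    assign[match(bases, uniq)]
  }
  cfg <- pipeline_config()
  for (seed in 1:5) {
    set.seed(seed)
    templates <- random_bases(3, 124)
    bases <- vapply(sample(rep(1:3, 10)), function(t) {
      mutate_k(templates[t], sample(0:1, 1))
    }, character(1))
    recs <- make_reads(bases)
    cl <- greedy_cluster(recs, cfg)
    got <- integer(length(bases))
    for (k in seq_len(nrow(cl))) {
      got[match(cl$member_ids[[k]], recs$id)] <- k
    }
    want <- oracle_cluster(bases, cfg$max_cluster_div)
    # identical partitions (cluster ids may be permuted): each cluster
    # of one maps to exactly one cluster of the other
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
    expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1))
  }
})

test_that("members stay within the divergence bound and reads are conserved", {
  cfg <- pipeline_config()
  set.seed(12)
  templates <- random_bases(4, 124)
  bases <- vapply(sample(rep(1:4, 25)), function(t) {
    mutate_k(templates[t], sample(0:2, 1))
  }, character(1))
  recs <- make_reads(paste0(PRIMER, bases))
  trimmed <- trim_and_filter(recs, cfg)
  cl <- greedy_cluster(trimmed, cfg)
  expect_equal(sum(cl$n_reads), nrow(trimmed))            # conservation
  expect_equal(cl$n_reads, lengths(cl$member_ids))
  seqs <- setNames(trimmed$bases, trimmed$id)
  for (k in seq_len(nrow(cl))) {
    d <- vapply(seqs[cl$member_ids[[k]]], hamming, numeric(1),
                b = cl$representative[k])
    expect_true(all(d <= cfg$max_cluster_div))
  }
  # determinism: identical input -> identical clusters
  cl2 <- greedy_cluster(trimmed, cfg)
  expect_identical(cl2, cl)
})

test_that("the abundance filter drops clusters of 10 reads or less", {
  cfg <- pipeline_config()
  set.seed(13)
  mk <- function(n_reads) {
    data.frame(cluster_id = paste0("c", n_reads), sample_id = "S1",
               representative = random_bases(1, 124), n_reads = n_reads,
               stringsAsFactors = FALSE)
  }
  cl <- do.call(rbind, lapply(c(10L, 11L, 1L, 100L), mk))
  kept <- filter_small_clusters(cl, cfg)
  expect_equal(kept$n_reads, c(11L, 100L))
  expect_equal(nrow(filter_small_clusters(cl[0, ], cfg)), 0L)
})

test_that("chimera detection flags constructed bimeras and not parents", {
  cfg <- pipeline_config()
  set.seed(14)
  p1 <- random_bases(1, 130)
  p2 <- mutate_k(p1, 40)
  bimera <- paste0(substr(p1, 1, 65), substr(p2, 66, 130))
  cl <- data.frame(
    cluster_id = c("P1", "P2", "C", "C2"),
    sample_id = c("S1", "S2", "S1", "S1"),
    representative = c(p1, p2, bimera, p1),
    n_reads = c(500L, 400L, 50L, 40L),
    stringsAsFactors = FALSE)
  out <- detect_chimeras(cl, cfg)
  expect_equal(out$chimera_flag, c(FALSE, FALSE, TRUE, FALSE))
  # C2 is identical to P1: single-parent mismatches = 0, never flagged
})

test_that("chimera flags match an exhaustive parent-pair x breakpoint oracle", {
  oracle_flags <- function(cl, cfg) {
    n <- nrow(cl)
    flags <- rep(FALSE, n)
    mism <- function(a, b) {
      # per-position mismatch of b against a (length of a); padded tail
      # counts as mismatched
      la <- nchar(a); lb <- nchar(b)
      v <- rep(TRUE, la)
      m <- min(la, lb)
      v[1:m] <- strsplit(a, "")[[1]][1:m] != strsplit(b, "")[[1]][1:m]
      v
    }
    for (ci in seq_len(n)) {
      cand <- cl$representative[ci]
      L <- nchar(cand)
      parents <- setdiff(which(cl$n_reads >=
                                 cfg$chimera_abundance_skew * cl$n_reads[ci]), ci)
      if (!length(parents) || L < 2 * cfg$chimera_min_segment) next
      # fixture sequences are equal-length, so mismatches over the
      # candidate's positions are the whole story
      tot <- vapply(parents, function(p) {
        sum(mism(cand, cl$representative[p]))
      }, numeric(1))
      best_single <- min(tot)
      best_two <- Inf
      for (i in seq_along(parents)) for (j in seq_along(parents)) {
        if (i == j) next
        mi <- cumsum(mism(cand, cl$representative[parents[i]]))
        mj <- cumsum(mism(cand, cl$representative[parents[j]]))
        totj <- tot[j]
        for (k in seq(cfg$chimera_min_segment, L - cfg$chimera_min_segment)) {
          best_two <- min(best_two, mi[k] + (totj - mj[k]))
        }
      }
      if (best_single - best_two >= cfg$chimera_min_advantage &&
          best_two <= cfg$chimera_max_model_div) {
        flags[ci] <- TRUE
      }
    }
    flags
  }
  cfg <- pipeline_config()
  set.seed(15)
  templates <- random_bases(6, 124)
  # abundant clusters: the template sequences (modal, error-free reads)
  # plus satellite variants at 1-2 mismatches
  reps <- c(templates, vapply(sample(1:6, 39, replace = TRUE), function(t) {
    mutate_k(templates[t], sample(1:2, 1))
  }, character(1)))
  # plant 5 bimeras from abundant parents
  bimeras <- vapply(1:5, function(i) {
    ab <- sample(1:6, 2)
    k <- sample(40:84, 1)
    paste0(substr(templates[ab[1]], 1, k), substr(templates[ab[2]], k + 1, 124))
  }, character(1))
  cl <- data.frame(
    cluster_id = sprintf("c%02d", 1:50),
    sample_id = sample(c("S1", "S2"), 50, replace = TRUE),
    representative = c(reps, bimeras),
    n_reads = c(sample(100:500, 45, replace = TRUE), sample(11:40, 5, replace = TRUE)),
    stringsAsFactors = FALSE)
  got <- detect_chimeras(cl, cfg)$chimera_flag
  want <- oracle_flags(cl, cfg)
  expect_equal(got, want)
  expect_true(all(got[46:50]))   # every planted bimera is caught
})

test_that("pooled chimera analysis is unaffected by sample partitioning", {
  cfg <- pipeline_config()
  set.seed(16)
  p1 <- random_bases(1, 124); p2 <- mutate_k(p1, 30)
  bim <- paste0(substr(p1, 1, 60), substr(p2, 61, 124))
  cl <- data.frame(
    cluster_id = c("a", "b", "c"),
    sample_id = c("S1", "S2", "S3"),       # parents and chimera in
    representative = c(p1, p2, bim),       # different samples
    n_reads = c(300L, 200L, 20L), stringsAsFactors = FALSE)
  expect_equal(detect_chimeras(cl, cfg)$chimera_flag, c(FALSE, FALSE, TRUE))
  # same result under a different row order (abundance rule, not order)
  perm <- cl[c(3, 1, 2), ]
  expect_equal(detect_chimeras(perm, cfg)$chimera_flag, c(TRUE, FALSE, FALSE))
})
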