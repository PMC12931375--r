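test_that("log CP10K matches its closed form and scale law", {
  s <- toy_sample(matrix(c(1, 1), 2, 1))
  n <- normalize_counts(s)
  expect_equal(as.numeric(n), rep(log1p(5000), 2L))

  # scaling one spot's counts x10 leaves its CP10K profile unchanged
  c2 <- matrix(c(3, 7, 30, 70), 2)
  n2 <- as.matrix(normalize_counts(toy_sample(c2)))
  expect_equal(n2[, 1], n2[, 2])

  expect_error(normalize_counts(toy_sample(matrix(c(1, 0), 1))),
               "qc_filter_spots")
})

test_that("Pearson residuals vanish for a constant matrix", {
  s <- toy_sample(matrix(5, 4, 6))
  r <- normalize_counts(s, method = "pearson_residual")
  expect_lt(max(abs(r)), 1e-12)
})

test_that("batch centering is a no-op for identical batches and removes
           a planted offset", {
  set.seed(1)
  m <- matrix(rnorm(40 * 30, sd = 2), 40, 30,
              dimnames = list(sprintf("G%d", 1:40),
                              sprintf("S%d", 1:30)))
  batch <- rep(c("a", "b"), each = 15)
  m[, 16:30] <- m[, 1:15]                  # identical batches
  e0 <- reduce_and_correct(m, n_dims = 5, batch = NULL)
  e1 <- reduce_and_correct(m, n_dims = 5, batch = batch)
  expect_lt(max(abs(e0 - e1)), 1e-10)

  m2 <- m
  m2[1, batch == "b"] <- m2[1, batch == "b"] + 50   # constant offset
  e2 <- reduce_and_correct(m2, n_dims = 5, batch = batch)
  means <- apply(e2, 2, function(pc) tapply(pc, batch, mean))
  expect_lt(max(abs(means["a", ] - means["b", ])), 1e-10)

  expect_error(reduce_and_correct(m, n_dims = 50), "rank|variance")
})

test_that("first PC separates synthetic compartments (AUC > 0.9)", {
  d <- small_sim(seed = 31L)
  s <- d$samples$samples[[1]]
  norm <- normalize_counts(s)
  emb <- reduce_and_correct(norm, n_dims = 5)
  comp <- d$truth$spots$compartment[d$truth$spots$sample_id ==
                                      s$sample_id]
  pc1 <- emb[, 1]
  pos <- pc1[comp == "epidermis"]; neg <- pc1[comp == "dermis"]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(max(auc, 1 - auc), 0.9)
})

test_that("k-means stand-in is seeded and recovers planted blobs", {
  set.seed(2)
  blob <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30))
  rownames(blob) <- sprintf("S%d", 1:60)
  lab <- cluster_spots(blob, k = 2, seed = 7)
  truth <- rep(0:1, each = 30)
  # ARI = 1 for a perfect (possibly label-swapped) recovery
  expect_true(all(lab[1:30] == lab[1]) && all(lab[31:60] == lab[31]) &&
                lab[1] != lab[31])
  expect_identical(lab, cluster_spots(blob, k = 2, seed = 7))
  expect_identical(unname(cluster_spots(blob, k = 1)), rep(0L, 60))
  expect_error(cluster_spots(blob, k = 100), "exceeds")
})

test_that("find_markers applies the detection, fold-change and FDR filters", {
  # gene SEP: 5 in all cluster-a spots, 0 elsewhere; gene FLAT identical
  set.seed(3)
  counts <- matrix(rpois(100 * 40, 2), 100, 40)
  counts[1, ] <- rep(c(5L, 0L), each = 20)
  counts[2, ] <- 3L
  rownames(counts) <- c("SEP", "FLAT", sprintf("BG%d", 3:100))
  colnames(counts) <- sprintf("S%d", 1:40)
  norm <- normalize_counts(toy_sample(counts, symbols = rownames(counts)))
  labels <- rep(c("a", "b"), each = 20)
  tab <- find_markers(norm, labels)
  sep <- tab[tab$gene == "SEP", ]
  expect_identical(sep$cluster_id, "a")
  expect_equal(sep$pct_in, 1)
  expect_equal(sep$pct_out, 0)
  expect_false("FLAT" %in% tab$gene)
  expect_true(all(tab$log2fc >= 0.25))
  expect_true(all(tab$p_adj <= 0.05))
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("clusters below three spots are skipped with a warning", {
  counts <- matrix(rpois(50 * 23, 3), 50, 23)
  rownames(counts) <- sprintf("G%d", 1:50)
  norm <- normalize_counts(toy_sample(counts))
  labels <- c(rep("a", 10), rep("b", 11), rep("tiny", 2))
  expect_warning(tab <- find_markers(norm, labels), "tiny")
  expect_false("tiny" %in% tab$cluster_id)
})

test_that("rank-sum p for {1,2,3} vs {4,5,6} equals the enumerated 0.1", {
  expect_equal(brute_ranksum_p(1:3, 4:6), 0.1)
  expect_equal(spotscore:::.rank_sum_p(1:3, 4:6), 0.1)
})

test_that("exact and approximate rank-sum p agree within 0.02 without ties", {
  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(10:30, 1); n2 <- sample(10:30, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, 0, 1))
    p_exact <- suppressWarnings(
      stats::wilcox.test(x, y, exact = TRUE)$p.value)
    p_approx <- spotscore:::.rank_sum_p(x, y, exact = FALSE)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("planted reference markers are recovered at high sensitivity and
           low FDR", {
  ref <- generate_scrna_reference(
    sim_config(n_background_genes = 300L, seed = 8L),
    n_clusters = 4L, n_markers = 10L, marker_fold = 8,
    cells_per_cluster = 60L)
  norm <- normalize_counts(ref$counts)
  tab <- find_markers(norm, ref$cell_cluster)
  planted <- unlist(ref$markers, use.names = FALSE)
  hit <- mapply(function(cl, g) g %in% ref$markers[[cl]],
                tab$cluster_id, tab$gene)
  sens <- sum(unique(tab$gene[hit]) %in% planted) / length(planted)
  fdr <- 1 - mean(hit)
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.10)
})
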