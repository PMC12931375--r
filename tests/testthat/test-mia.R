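test_that("BH adjustment matches hand-computed cases and validates input", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.04, 0.9)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.9))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # order stability
  p <- c(0.9, 0.005, 0.04, 0.04)
  expect_equal(bh_adjust(p), bh_adjust(rev(p))[4:1])
  # monotone in p-rank, capped at 1
  set.seed(5)
  q <- runif(50)
  adj <- bh_adjust(q)
  expect_true(all(diff(adj[order(q)]) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric scores equal brute-force pmf summation", {
  for (N in c(10L, 50L, 100L, 200L)) {
    for (m in c(1L, 5L, 10L, 25L, 50L)) {
      for (n in c(1L, 5L, 10L, 25L, 50L)) {
        if (m > N || n > N) next
        for (k in unique(c(0L, 1L, floor(m * n / N),
                           ceiling(m * n / N) + 1L, min(m, n)))) {
          if (k > min(m, n)) next
          got <- spotscore:::.hyper_score(k, m, n, N)
          want <- brute_hyper_score(k, m, n, N)
          expect_equal(got, want, tolerance = 1e-10,
                       label = sprintf("score(k=%d,m=%d,n=%d,N=%d)",
                                       k, m, n, N))
        }
      }
    }
  }
})

test_that("perfect overlap scores log10 C(100,10); expectation-level
           overlap scores below 1", {
  expect_equal(spotscore:::.hyper_score(10L, 10L, 10L, 100L),
               log10(choose(100, 10)), tolerance = 1e-10)
  # k at its expectation in a symmetric small case
  expect_lt(abs(spotscore:::.hyper_score(2L, 4L, 5L, 10L)), 1)
})

test_that("enrichment score is monotone increasing in overlap", {
  scores <- vapply(0:10, spotscore:::.hyper_score, numeric(1),
                   m = 10L, n = 20L, N = 100L)
  expect_true(all(diff(scores) > 0))
})

test_that("mia_enrichment filters, ranks, and caps markers at top_n", {
  mk <- function(cluster, genes, l2fc, p_adj)
    data.frame(cluster_id = cluster, gene = genes, log2fc = l2fc,
               pct_in = 1, pct_out = 0, p = p_adj / 2, p_adj = p_adj)
  universe <- sprintf("G%03d", 1:500)
  st <- mk("st1", universe[1:400], l2fc = seq(5, 1, length.out = 400),
           p_adj = 0.01)
  sc <- mk("ref1", universe[1:50], l2fc = 2, p_adj = 0.01)
  res <- mia_enrichment(st, sc, universe, top_n = 300L)
  expect_identical(unname(res$st_set_sizes["st1"]), 300L)
  # top 300 by log2fc are G001..G300, so all 50 reference genes overlap
  expect_identical(unname(res$overlap["st1", "ref1"]), 50)

  # markers failing the adjusted-p or fold-change filters are ignored
  st2 <- rbind(st, mk("st2", universe[401:450], l2fc = 0.1, p_adj = 0.01))
  expect_warning(res2 <- mia_enrichment(st2, sc, universe), "st2")
  expect_identical(unname(res2$scores["st2", "ref1"]), 0)
})

test_that("matched synthetic clusters attain the row-maximum MIA score", {
  d <- small_sim(seed = 19L)
  s <- merge_samples(d$samples)
  norm <- normalize_counts(s)
  comp <- d$truth$spots$compartment
  st_markers <- find_markers(norm, comp)
  cfg <- d$truth$config
  ref <- generate_scrna_reference(
    cfg, n_clusters = 3L,
    cluster_names = c("Keratinocyte-1", "Fibroblast-1", "Myeloid-1"),
    marker_genes = list(cfg$epidermis_markers, cfg$dermis_markers,
                        unique(c(cfg$anchor_gene, cfg$m1_panel,
                                 cfg$m2_panel))))
  sc_markers <- find_markers(normalize_counts(ref$counts),
                             ref$cell_cluster)
  universe <- intersect(s$gene_symbols, rownames(ref$counts))
  res <- mia_enrichment(st_markers, sc_markers, universe)
  expect_identical(colnames(res$scores)[
    which.max(res$scores["epidermis", ])], "Keratinocyte-1")
  expect_identical(colnames(res$scores)[
    which.max(res$scores["dermis", ])], "Fibroblast-1")
})

test_that("local over-representation ranks a self-match first", {
  universe <- sprintf("G%04d", 1:1000)
  lib <- gene_set_library(
    list(self = universe[1:20], other = universe[501:540],
         empty_overlap = universe[900:950]),
    universe)
  res <- enrich_gene_sets(universe[1:20], lib)
  expect_identical(res$set[1], "self")
  expect_true(all(diff(res$p_adj) >= 0))

  # zero overlap with every set -> all p = 1
  res0 <- enrich_gene_sets(universe[100:110], lib)
  expect_true(all(res0$p == 1) && all(res0$p_adj == 1))

  expect_error(suppressWarnings(enrich_gene_sets("NOTAGENE", lib)),
               "empty query")
})

test_that("GMT round-trips a library", {
  universe <- sprintf("G%03d", 1:100)
  lib <- gene_set_library(list(a = universe[1:5], b = universe[6:20]),
                          universe)
  path <- tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  back <- read_gmt(path)
  expect_identical(back$sets, lib$sets)
})
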