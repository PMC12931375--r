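panel_of <- function(...) gene_set_panel("p", c(...))

test_that("positivity follows the k-of-n rule on raw counts", {
  counts <- rbind(IFIT1 = c(1, 0, 0), USP18 = c(0, 0, 0),
                  MX1 = c(0, 0, 0))
  s <- toy_sample(counts, symbols = rownames(counts))
  expect_warning(
    pos <- positivity_matrix(s, gene_set_panel("isg",
                                               c("IFIT1", "USP18", "MX1",
                                                 "OAS1"))),
    "OAS1")
  expect_identical(unname(pos), c(TRUE, FALSE, FALSE))

  # 4 of 5 apoptosis markers: positive at k=2, negative at k=5
  ap <- c("CASP3", "CASP8", "BAX", "BAK1", "CYCS")
  counts2 <- matrix(c(1, 1, 1, 1, 0), 5, 1,
                    dimnames = list(ap, "BC1"))
  s2 <- toy_sample(counts2, symbols = ap)
  expect_true(positivity_matrix(s2, gene_set_panel("ap", ap,
                                                   k_required = 2)))
  expect_false(positivity_matrix(s2, gene_set_panel("ap", ap,
                                                    k_required = 5)))
  expect_error(positivity_matrix(s2, gene_set_panel("none", "ZZZ")) |>
                 suppressWarnings(), "no genes present")
})

test_that("panel construction validates the k-of-n invariant", {
  expect_error(gene_set_panel("x", character(0)), "no genes")
  expect_error(gene_set_panel("x", c("A", "B"), k_required = 3), "k_required")
  expect_identical(gene_set_panel("x", c("TNFa", "tnf"))$genes, "TNF")
})

test_that("geneset_percent counts scoped spots and flags empty scopes", {
  counts <- rbind(IFIT1 = c(rep(1, 9), 0))
  s <- toy_sample(counts, symbols = "IFIT1")
  r <- geneset_percent(s, panel_of("IFIT1"))
  expect_equal(r$percent, 90)
  ann <- data.frame(sample_id = "toy", barcode = sprintf("BC%d", 1:10),
                    cluster_id = "1", compartment = "dermis")
  r_epi <- geneset_percent(sample_set(list(s), "control"),
                           panel_of("IFIT1"), ann, scope = "epidermis")
  expect_true(is.na(r_epi$percent))
  expect_identical(r_epi$denominator, 0L)
})

test_that("positivity is monotone in k and under panel growth;
           scopes are additive", {
  d <- small_sim(seed = 37L)
  s <- d$samples$samples[[4]]
  ap <- c("CASP3", "CASP8", "BAX", "BAK1", "CYCS")
  p1 <- positivity_matrix(s, gene_set_panel("a", ap, k_required = 1))
  p2 <- positivity_matrix(s, gene_set_panel("a", ap, k_required = 2))
  expect_true(all(p1 >= p2))          # spot-for-spot monotone in k
  grown <- positivity_matrix(s, gene_set_panel("a", c(ap, "RIPK1")))
  expect_true(all(grown >= p1))       # adding a gene never loses spots

  pan <- gene_set_panel("isg", d$truth$config$isg_panel)
  tot <- geneset_percent(d$samples, pan, d$annotation, "total")
  parts <- lapply(c("epidermis", "dermis", "other"), function(sc)
    geneset_percent(d$samples, pan, d$annotation, sc))
  num_sum <- Reduce(`+`, lapply(parts, function(p)
    ifelse(is.na(p$percent) & p$denominator == 0L, 0L, p$numerator)))
  expect_identical(tot$numerator, as.integer(num_sum))
})

test_that("polarization fractions sum to 100 and classify correctly", {
  # 4 anchor+ spots: 1 A-only, 2 B-only, 1 both, 1 anchor-negative
  counts <- rbind(CD68 = c(1, 1, 1, 1, 0),
                  FCGR3A = c(1, 0, 0, 1, 1),
                  CD163 = c(0, 1, 1, 1, 1))
  s <- toy_sample(counts, symbols = rownames(counts))
  pol <- conditional_polarization(s, panel_of("CD68"), panel_of("FCGR3A"),
                                  panel_of("CD163"))
  expect_equal(pol$percent, c(25, 50, 25))
  expect_equal(sum(pol$percent), 100, tolerance = 1e-9)

  none <- toy_sample(rbind(CD68 = 0, FCGR3A = 1, CD163 = 1),
                     symbols = c("CD68", "FCGR3A", "CD163"))
  expect_true(all(is.na(
    conditional_polarization(none, panel_of("CD68"), panel_of("FCGR3A"),
                             panel_of("CD163"))$percent)))
  expect_error(
    conditional_polarization(s, panel_of("CD68"), panel_of("FCGR3A"),
                             panel_of("FCGR3A")), "overlap")
})

test_that("polarization recovers planted B-only co-expression", {
  d <- generate_dataset(sim_config(
    n_samples = 1L, grid_rows = 40L, grid_cols = 50L, groups = "control",
    inflamed_fraction = 0.05, anchor_fraction = 0.4,
    m1_given_anchor = 0, m2_given_anchor = 0.9, both_given_anchor = 0,
    n_background_genes = 20L, seed = 41L))
  s <- d$samples$samples[[1]]
  panels <- load_panels()
  pol <- conditional_polarization(s, panels$anchor_cd68,
                                  panels$m1_markers, panels$m2_markers)
  expect_lt(pol$percent[pol$category == "A_only"], 5)
  expect_gt(pol$percent[pol$category == "B_only"], 90)
})

test_that("conditional and co-occurrence percentages count correctly", {
  counts <- rbind(CD68 = c(1, 1, 1, 1, 1, 0),
                  TGFB1 = c(1, 1, 0, 0, 0, 1))
  s <- toy_sample(counts, symbols = rownames(counts))
  r <- conditional_percent(s, panel_of("CD68"), panel_of("TGFB1"))
  expect_equal(r$percent, 40)
  expect_equal(conditional_percent(s, panel_of("CD68"),
                                   panel_of("CD68"))$percent, 100)

  co <- cooccurrence_percent(s, panel_of("CD68"), panel_of("TGFB1"))
  expect_equal(co$percent[co$stratum == "positive"], 40)
  expect_equal(co$percent[co$stratum == "negative"], 100)

  # outcome contained in conditioning -> 0% within the negative stratum
  sub <- toy_sample(rbind(A = c(1, 1, 0, 0), B = c(1, 0, 0, 0)),
                    symbols = c("A", "B"))
  co2 <- cooccurrence_percent(sub, panel_of("A"), panel_of("B"))
  expect_equal(co2$percent[co2$stratum == "negative"], 0)
})

test_that("co-occurrence reflects planted dependence and independence", {
  panels <- load_panels()
  dep <- generate_dataset(sim_config(
    n_samples = 1L, grid_rows = 40L, grid_cols = 50L, groups = "lesion",
    inflamed_fraction = 0.5, apoptosis_given_isg_pos = 0.6,
    apoptosis_given_isg_neg = 0.2, n_background_genes = 20L, seed = 43L))
  co <- cooccurrence_percent(dep$samples$samples[[1]], panels$isg,
                             panels$apoptosis)
  expect_gt(co$percent[co$stratum == "positive"],
            co$percent[co$stratum == "negative"])

  ind <- generate_dataset(sim_config(
    n_samples = 1L, grid_rows = 40L, grid_cols = 50L, groups = "lesion",
    inflamed_fraction = 0.5, apoptosis_given_isg_pos = 0.3,
    apoptosis_given_isg_neg = 0.3, n_background_genes = 20L, seed = 47L))
  co2 <- cooccurrence_percent(ind$samples$samples[[1]], panels$isg,
                              panels$apoptosis)
  gap <- abs(co2$percent[co2$stratum == "positive"] -
               co2$percent[co2$stratum == "negative"])
  se <- 100 * sqrt(0.3 * 0.7 * (1 / co2$denominator[1] +
                                  1 / co2$denominator[2]))
  expect_lt(gap, 3 * se)
})

test_that("planted fractions are recovered within 3 binomial SEs across
           20 seeded datasets", {
  worst <- 0
  for (seed in 1:20) {
    d <- generate_dataset(sim_config(
      n_samples = 2L, grid_rows = 20L, grid_cols = 25L,
      inflamed_fraction = c(0.05, 0.61), groups = c("control", "lesion"),
      n_background_genes = 20L, seed = seed))
    pan <- gene_set_panel("isg", d$truth$config$isg_panel)
    r <- geneset_percent(d$samples, pan, d$annotation, "total")
    planted <- 100 * d$truth$planted_fractions[r$sample_id]
    se <- 100 * sqrt((planted / 100) * (1 - planted / 100) /
                       r$denominator)
    worst <- max(worst, max(abs(r$percent - planted) / se))
  }
  expect_lte(worst, 3)
})

test_that("group comparisons match closed forms and enumerate exactly", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6), method = "student")
  expect_equal(cmp$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 0.02131164, tolerance = 1e-6)

  same <- compare_groups(c(2, 4, 6), c(2, 4, 6), method = "student")
  expect_equal(same$p, 1)
  expect_equal(same$statistic, 0)

  perm <- compare_groups(c(1, 2, 3), c(4, 5, 6), method = "permutation",
                         n_perm = 1000)
  expect_identical(perm$mode, "exact")
  expect_equal(perm$n_perm, choose(6, 3))
  expect_equal(perm$p * 20, round(perm$p * 20))  # multiple of 1/20
  expect_equal(perm$p, 0.1)                      # both extreme splits

  expect_error(compare_groups(1, c(2, 3), method = "student"),
               "permutation")
  samp <- compare_groups(rnorm(8), rnorm(8, 2), method = "permutation",
                         n_perm = 200, seed = 3)
  expect_identical(samp$mode, "sampled")
  expect_lte(samp$p, 1)
})
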