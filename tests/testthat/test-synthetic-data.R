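test_that("sim_config validates proportions and grid dimensions", {
  expect_error(sim_config(inflamed_fraction = 1.2), "proportions")
  expect_error(sim_config(m1_given_anchor = 0.6, m2_given_anchor = 0.5,
                          both_given_anchor = 0.2), "<= 1")
  expect_error(sim_config(grid_rows = 0), "grid_rows")
  expect_error(sim_config(epidermis_band_rows = 99, grid_rows = 10),
               "exceeds")
  expect_error(
    sim_config(gene_universe = c("CD68", "BGX"), isg_panel = "IFIT1"),
    "IFIT1")
})

test_that("zero inflamed fraction plants zero ISG-positive spots", {
  d <- generate_dataset(sim_config(n_samples = 2L, grid_rows = 8L,
                                   grid_cols = 8L, inflamed_fraction = 0,
                                   groups = "control",
                                   n_background_genes = 20L, seed = 5L))
  expect_false(any(d$truth$spots$isg_pos))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_samples = 2L, grid_rows = 10L, grid_cols = 10L,
                    n_background_genes = 30L, seed = 11L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$samples$samples[[1]]$counts,
                   d2$samples$samples[[1]]$counts)
  expect_identical(d1$truth$spots, d2$truth$spots)
})

test_that("empirical planted fraction matches 0.9 within 0.02 at 2000 spots", {
  d <- generate_dataset(sim_config(n_samples = 1L, grid_rows = 40L,
                                   grid_cols = 50L,
                                   inflamed_fraction = 0.9,
                                   groups = "lesion",
                                   n_background_genes = 20L, seed = 2L))
  expect_lt(abs(mean(d$truth$spots$isg_pos) - 0.9), 0.02)
})

test_that("anchor-conditional polarization frequencies match config", {
  # >= 1000 anchor+ spots: 3 binomial SEs around each planted conditional
  cfg <- sim_config(n_samples = 1L, grid_rows = 60L, grid_cols = 60L,
                    groups = "lesion", anchor_fraction = 0.4,
                    m1_given_anchor = 0.2, m2_given_anchor = 0.5,
                    both_given_anchor = 0.2,
                    n_background_genes = 20L, seed = 9L)
  d <- generate_dataset(cfg)
  tr <- d$truth$spots
  anc <- tr$anchor
  expect_gte(sum(anc), 1000L)
  n <- sum(anc)
  for (case in list(c("m1", 0.2), c("m2", 0.5), c("both", 0.2))) {
    p <- as.numeric(case[2])
    obs <- mean(tr$polarization[anc] == case[1])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("scRNA reference plants disjoint marker sets of requested size", {
  ref <- generate_scrna_reference(
    sim_config(n_background_genes = 50L, seed = 3L),
    n_clusters = 2L, n_markers = 10L)
  expect_length(ref$markers, 2L)
  expect_true(all(lengths(ref$markers) == 10L))
  expect_length(intersect(ref$markers[[1]], ref$markers[[2]]), 0L)
  expect_error(generate_scrna_reference(sim_config(), n_clusters = 1L),
               "at least 2 clusters")
  expect_error(generate_scrna_reference(
    sim_config(), n_clusters = 2L,
    marker_genes = list(c("A", "B"), c("B", "C"))), "disjoint")
})

test_that("label masks render planted areas and reproduce under a seed", {
  m0 <- generate_label_mask(0L, pixel_size_um = 2)
  expect_true(all(m0$mask == 0L))

  m <- generate_label_mask(2L, areas_um2 = c(4000, 6000),
                           pixel_size_um = 2, seed = 4L)
  af <- area_fraction_above(m$mask, threshold_um2 = 0,
                            exclude_border = FALSE)
  rendered <- af$areas$area_um2[order(af$areas$label)]
  expect_equal(rendered, c(4000, 6000), tolerance = 0.05)

  m2 <- generate_label_mask(2L, areas_um2 = c(4000, 6000),
                            pixel_size_um = 2, seed = 4L)
  expect_identical(unclass(m$mask), unclass(m2$mask))

  expect_error(generate_label_mask(9L, areas_um2 = 4000,
                                   pixel_size_um = 2,
                                   dim = c(30L, 30L), seed = 1L),
               "without overlap")
})

test_that("spaceranger writer round-trips exactly, also at scale", {
  toy <- toy_sample(matrix(c(1, 0, 0, 0, 2, 0), 2, byrow = TRUE))
  dir <- tempfile("layout_")
  write_spaceranger_layout(toy, dir)
  back <- read_spaceranger(dir, sample_id = "toy")
  expect_equal(as.matrix(back$counts), as.matrix(toy$counts))
  expect_identical(back$barcodes, toy$barcodes)
  expect_identical(back$array_row, toy$array_row)

  big <- small_sim(seed = 21L)$samples$samples[[1]]   # 500-spot sample
  dir2 <- tempfile("layout_")
  write_spaceranger_layout(big, dir2)
  back2 <- read_spaceranger(dir2, sample_id = big$sample_id)
  expect_equal(as.matrix(back2$counts), as.matrix(big$counts))
  expect_identical(back2$in_tissue, big$in_tissue)
})

test_that("ground truth exports to CSV + JSON", {
  d <- generate_dataset(sim_config(n_samples = 1L, grid_rows = 6L,
                                   grid_cols = 6L,
                                   epidermis_band_rows = 2L,
                                   groups = "control",
                                   n_background_genes = 10L, seed = 1L))
  dir <- tempfile("gt_")
  export_ground_truth(d$truth, dir)
  expect_true(file.exists(file.path(dir, "ground_truth_spots.csv")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$config$seed, 1L)
})
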