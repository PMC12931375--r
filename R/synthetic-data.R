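#' Configuration for the synthetic Visium simulator
#'
#' Defines the study conditions emulated by [generate_dataset()]: a
#' multi-sample skin-biopsy layout on a hexagonal spot grid with an
#' epidermis band over a dermis body, negative-binomial UMI counts, planted
#' per-sample "IFN-I inflamed" spot fractions for a six-gene ISG panel,
#' CD68-anchored M1/M2 co-expression, and apoptosis-marker positivity
#' conditional on ISG status.
#'
#' Defaults mirror a three-control/three-lesion skin study: planted ISG
#' fractions `c(0.05, 0.05, 0.05, 0.90, 0.61, 0.90)`, a 40 x 50 hex grid
#' (2000 spots/sample), baseline NB mean 0.05 per gene with dispersion
#' `theta = 2` (variance `mu + mu^2/theta`), and a 50x mean boost for
#' "positive" spots so positivity calling is statistical but near-certain.
#'
#' @param n_samples number of samples.
#' @param grid_rows,grid_cols hex-grid dimensions per sample.
#' @param epidermis_band_rows top rows labelled epidermis; the rest dermis.
#' @param inflamed_fraction per-sample planted ISG-positive spot fraction
#'   (recycled to `n_samples`).
#' @param groups per-sample group labels (`"control"`/`"lesion"`).
#' @param isg_panel,apoptosis_panel,necroptosis_panel gene symbol vectors.
#' @param anchor_gene the anchor gene (CD68).
#' @param m1_panel,m2_panel macrophage polarization marker genes.
#' @param m1_cytokines,m2_cytokines cytokine genes boosted with the
#'   corresponding polarization flag.
#' @param epidermis_markers,dermis_markers compartment marker genes boosted
#'   in their own compartment (drives PCA/cluster separation).
#' @param baseline_mean NB mean per gene for unboosted spots.
#' @param panel_off_mean NB mean of flag-driven panel genes (ISG, anchor,
#'   M1/M2 markers and cytokines, apoptosis) in spots *not* carrying the
#'   corresponding flag.  Kept well below `baseline_mean` so that any-of-k
#'   panel positivity has a negligible background rate and planted
#'   fractions are recoverable at binomial precision.
#' @param nb_dispersion NB dispersion theta (> 0).
#' @param positive_boost multiplicative mean boost for flagged spots
#'   (applied to `baseline_mean`).
#' @param anchor_fraction P(anchor-positive flag).
#' @param m1_given_anchor,m2_given_anchor,both_given_anchor conditional
#'   probabilities of M1-only / M2-only / both flags given anchor-positive;
#'   must sum to at most 1.
#' @param apoptosis_given_isg_pos,apoptosis_given_isg_neg P(apoptosis flag)
#'   given ISG status.
#' @param n_background_genes number of synthetic background genes (BG0001,
#'   ...).
#' @param gene_universe optional explicit gene universe; all panel genes
#'   must be members.
#' @param seed integer seed making every draw reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 6L,
                       grid_rows = 40L, grid_cols = 50L,
                       epidermis_band_rows = 8L,
                       inflamed_fraction = c(0.05, 0.05, 0.05,
                                             0.90, 0.61, 0.90),
                       groups = NULL,
                       isg_panel = c("IFIT1", "USP18", "MX1", "IFI27",
                                     "IFI44L", "OAS1"),
                       apoptosis_panel = c("CASP3", "CASP8", "BAX",
                                           "BAK1", "CYCS"),
                       necroptosis_panel = c("RIPK1", "MLKL"),
                       anchor_gene = "CD68",
                       m1_panel = c("FCGR3A", "FCGR1A"),
                       m2_panel = c("CD163", "ARG1"),
                       m1_cytokines = c("IL1B", "TNF", "IL12B", "IL18"),
                       m2_cytokines = c("IL10", "ARG1", "TGFB1"),
                       epidermis_markers = c("KRT5", "KRT10", "KRT14",
                                             "KRT1", "LOR"),
                       dermis_markers = c("COL1A1", "COL1A2", "COL3A1",
                                          "DCN", "LUM"),
                       baseline_mean = 0.05,
                       panel_off_mean = 0.001,
                       nb_dispersion = 2,
                       positive_boost = 50,
                       anchor_fraction = 0.25,
                       m1_given_anchor = 0.15,
                       m2_given_anchor = 0.55,
                       both_given_anchor = 0.15,
                       apoptosis_given_isg_pos = 0.6,
                       apoptosis_given_isg_neg = 0.2,
                       n_background_genes = 300L,
                       gene_universe = NULL,
                       seed = 1L) {
  stopifnot(.is_count(n_samples, 1L), .is_count(grid_rows, 1L),
            .is_count(grid_cols, 1L), .is_count(epidermis_band_rows, 0L),
            .is_count(n_background_genes, 0L))
  if (epidermis_band_rows > grid_rows)
    .stopf("epidermis_band_rows exceeds grid_rows")
  inflamed_fraction <- rep_len(inflamed_fraction, n_samples)
  props <- c(inflamed_fraction, anchor_fraction, m1_given_anchor,
             m2_given_anchor, both_given_anchor,
             apoptosis_given_isg_pos, apoptosis_given_isg_neg)
  if (!.is_prop(props)) .stopf("all proportions must lie in [0, 1]")
  if (m1_given_anchor + m2_given_anchor + both_given_anchor > 1 + 1e-12)
    .stopf("m1_given_anchor + m2_given_anchor + both_given_anchor must be <= 1")
  stopifnot(baseline_mean >= 0, panel_off_mean >= 0, nb_dispersion > 0,
            positive_boost > 0)
  if (is.null(groups))
    groups <- ifelse(inflamed_fraction >= 0.5, "lesion", "control")
  groups <- rep_len(as.character(groups), n_samples)

  cfg <- list(
    n_samples = as.integer(n_samples),
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    epidermis_band_rows = as.integer(epidermis_band_rows),
    inflamed_fraction = inflamed_fraction, groups = groups,
    isg_panel = normalize_gene_symbols(isg_panel),
    apoptosis_panel = normalize_gene_symbols(apoptosis_panel),
    necroptosis_panel = normalize_gene_symbols(necroptosis_panel),
    anchor_gene = normalize_gene_symbols(anchor_gene),
    m1_panel = normalize_gene_symbols(m1_panel),
    m2_panel = normalize_gene_symbols(m2_panel),
    m1_cytokines = normalize_gene_symbols(m1_cytokines),
    m2_cytokines = normalize_gene_symbols(m2_cytokines),
    epidermis_markers = normalize_gene_symbols(epidermis_markers),
    dermis_markers = normalize_gene_symbols(dermis_markers),
    baseline_mean = baseline_mean, panel_off_mean = panel_off_mean,
    nb_dispersion = nb_dispersion,
    positive_boost = positive_boost,
    anchor_fraction = anchor_fraction,
    m1_given_anchor = m1_given_anchor, m2_given_anchor = m2_given_anchor,
    both_given_anchor = both_given_anchor,
    apoptosis_given_isg_pos = apoptosis_given_isg_pos,
    apoptosis_given_isg_neg = apoptosis_given_isg_neg,
    n_background_genes = as.integer(n_background_genes),
    gene_universe = gene_universe, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  # validate panels against an explicit universe, naming the offender
  if (!is.null(gene_universe)) {
    u <- normalize_gene_symbols(gene_universe)
    for (p in .sim_panel_fields) {
      miss <- setdiff(cfg[[p]], u)
      if (length(miss) > 0L)
        .stopf("panel gene(s) absent from gene universe: %s",
               paste(miss, collapse = ", "))
    }
    cfg$gene_universe <- u
  }
  cfg
}

.sim_panel_fields <- c("isg_panel", "apoptosis_panel", "necroptosis_panel",
                       "anchor_gene", "m1_panel", "m2_panel",
                       "m1_cytokines", "m2_cytokines",
                       "epidermis_markers", "dermis_markers")

.sim_gene_universe <- function(cfg) {
  panel_genes <- unique(unlist(cfg[.sim_panel_fields], use.names = FALSE))
  extra <- c("IFNB1", "ZBP1")            # scored but unboosted by default
  bg <- if (cfg$n_background_genes > 0L)
    sprintf("BG%04d", seq_len(cfg$n_background_genes)) else character(0)
  if (!is.null(cfg$gene_universe)) return(cfg$gene_universe)
  unique(c(panel_genes, extra, bg))
}

#' Save / load a simulator configuration as YAML
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Generate a synthetic multi-sample Visium dataset with ground truth
#'
#' Each sample is a hex grid of spots (even array rows offset by one
#' column, mirroring the Visium layout).  Spots in the top
#' `epidermis_band_rows` rows are epidermis, the rest dermis.  Counts are
#' negative binomial with per-gene mean `baseline_mean`, multiplied by
#' `positive_boost` for the panel genes of every planted flag:
#' compartment markers in their own compartment, ISG panel in ISG-positive
#' spots, the anchor gene in anchor-positive spots, M1/M2 markers (plus the
#' matching cytokines) per the conditional polarization draw, and the
#' apoptosis panel in apoptosis-flagged spots (probability depending on ISG
#' status).  All draws derive from `config$seed`, so repeated calls are
#' bit-identical.
#'
#' @param config a [sim_config()].
#' @return list with elements `samples` (a [sample_set()]), `annotation`
#'   (a `spot_annotation` labelling compartments), and `truth` (a
#'   `ground_truth` object: per-spot flags, per-sample planted fractions,
#'   and the config).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- .sim_gene_universe(config)
  n_g <- length(genes)
  gi <- function(p) match(config[[p]], genes)

  rows <- config$grid_rows; cols <- config$grid_cols
  n_s <- rows * cols
  array_row <- rep(seq_len(rows) - 1L, each = cols)
  array_col <- 2L * (rep(seq_len(cols), rows) - 1L) + array_row %% 2L
  compartment <- ifelse(array_row < config$epidermis_band_rows,
                        "epidermis", "dermis")
  sample_ids <- sprintf("%s_%d", config$groups,
                        as.integer(stats::ave(seq_len(config$n_samples),
                                              config$groups,
                                              FUN = seq_along)))

  samples <- vector("list", config$n_samples)
  truth_spots <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    isg <- stats::rbinom(n_s, 1L, config$inflamed_fraction[s]) == 1L
    anchor <- stats::rbinom(n_s, 1L, config$anchor_fraction) == 1L
    polar <- rep("none", n_s)
    n_anchor <- sum(anchor)
    if (n_anchor > 0L) {
      pr <- c(config$m1_given_anchor, config$m2_given_anchor,
              config$both_given_anchor)
      polar[anchor] <- sample(c("m1", "m2", "both", "none"), n_anchor,
                              replace = TRUE, prob = c(pr, 1 - sum(pr)))
    }
    p_apo <- ifelse(isg, config$apoptosis_given_isg_pos,
                    config$apoptosis_given_isg_neg)
    apo <- stats::rbinom(n_s, 1L, p_apo) == 1L

    mu <- matrix(config$baseline_mean, n_g, n_s)
    b <- config$positive_boost
    # flag-driven panels sit near zero unless their flag is on
    flagged_panels <- c("isg_panel", "anchor_gene", "m1_panel", "m2_panel",
                        "m1_cytokines", "m2_cytokines", "apoptosis_panel")
    mu[unique(unlist(lapply(flagged_panels, gi))), ] <-
      config$panel_off_mean
    mu[gi("epidermis_markers"), compartment == "epidermis"] <-
      config$baseline_mean * b
    mu[gi("dermis_markers"), compartment == "dermis"] <-
      config$baseline_mean * b
    if (any(isg)) mu[gi("isg_panel"), isg] <- config$baseline_mean * b
    if (any(anchor)) mu[gi("anchor_gene"), anchor] <-
      config$baseline_mean * b
    m1s <- polar %in% c("m1", "both"); m2s <- polar %in% c("m2", "both")
    if (any(m1s)) {
      mu[gi("m1_panel"), m1s] <- config$baseline_mean * b
      mu[gi("m1_cytokines"), m1s] <- config$baseline_mean * b
    }
    if (any(m2s)) {
      mu[gi("m2_panel"), m2s] <- config$baseline_mean * b
      mu[gi("m2_cytokines"), m2s] <- config$baseline_mean * b
    }
    if (any(apo)) mu[gi("apoptosis_panel"), apo] <-
      config$baseline_mean * b

    counts <- matrix(stats::rnbinom(n_g * n_s, mu = as.vector(mu),
                                    size = config$nb_dispersion), n_g, n_s)
    barcodes <- sprintf("SPOT%05d-1", seq_len(n_s))
    samples[[s]] <- spot_matrix(
      counts,
      gene_ids = sprintf("SIMG%05d", seq_len(n_g)),
      gene_symbols = genes, barcodes = barcodes,
      array_row = array_row, array_col = array_col,
      pxl_row = 100 + array_row * 120, pxl_col = 100 + array_col * 70,
      in_tissue = rep(TRUE, n_s), sample_id = sample_ids[s])
    truth_spots[[s]] <- data.frame(
      sample_id = sample_ids[s], barcode = barcodes,
      compartment = compartment, isg_pos = isg, anchor = anchor,
      polarization = polar, apoptosis = apo, stringsAsFactors = FALSE)
  }
  truth_spots <- do.call(rbind, truth_spots)
  ann <- data.frame(
    sample_id = truth_spots$sample_id, barcode = truth_spots$barcode,
    cluster_id = ifelse(truth_spots$compartment == "epidermis", "3", "0"),
    compartment = truth_spots$compartment, stringsAsFactors = FALSE)
  class(ann) <- c("spot_annotation", "data.frame")
  attr(ann, "cluster_map") <- data.frame(
    cluster_id = c("3", "0"), compartment = c("epidermis", "dermis"),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    spots = truth_spots,
    planted_fractions = stats::setNames(config$inflamed_fraction,
                                        sample_ids),
    config = config), class = "ground_truth")
  list(samples = sample_set(samples, config$groups),
       annotation = ann, truth = truth)
}

#' Export generator ground truth
#'
#' Writes the per-spot truth table as CSV and the planted per-sample
#' fractions plus configuration as JSON.
#'
#' @param truth a `ground_truth` object from [generate_dataset()].
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
export_ground_truth <- function(truth, directory) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$spots,
                   file.path(directory, "ground_truth_spots.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(planted_fractions = as.list(truth$planted_fractions),
         config = unclass(truth$config)),
    file.path(directory, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

#' Generate a synthetic single-cell reference with planted markers
#'
#' Builds `n_clusters` cell populations over a shared gene universe where
#' each cluster has a disjoint planted marker set whose NB mean is
#' `marker_fold` times the baseline; all other genes sit at baseline.
#' Returns per-cluster mean profiles (the signature matrix), the planted
#' marker lists, and a sampled cell-level count matrix for marker-recovery
#' experiments.
#'
#' @param config a [sim_config()]; supplies baseline mean, dispersion,
#'   background-gene count and the seed (offset so reference draws are
#'   decoupled from [generate_dataset()]).
#' @param n_clusters number of clusters (>= 2).
#' @param n_markers planted markers per cluster (ignored when
#'   `marker_genes` given).
#' @param marker_fold mean fold elevation of a cluster's markers.
#' @param cells_per_cluster sampled cells per cluster.
#' @param marker_genes optional list of per-cluster marker symbol vectors
#'   (must be disjoint).
#' @param cluster_names optional cluster names (default Cluster-1, ...).
#' @return list with `signatures` (gene x cluster mean matrix),
#'   `markers` (named list of planted marker sets), `counts` (gene x cell
#'   sparse matrix), `cell_cluster` (factor per cell).
#' @export
generate_scrna_reference <- function(config = sim_config(),
                                     n_clusters = 4L, n_markers = 10L,
                                     marker_fold = 8,
                                     cells_per_cluster = 60L,
                                     marker_genes = NULL,
                                     cluster_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!.is_count(n_clusters, 0L) || n_clusters < 2L)
    .stopf("generate_scrna_reference: at least 2 clusters required")
  stopifnot(.is_count(n_markers, 1L), marker_fold > 0,
            .is_count(cells_per_cluster, 1L))
  set.seed(config$seed + 1L)

  if (is.null(cluster_names))
    cluster_names <- sprintf("Cluster-%d", seq_len(n_clusters))
  stopifnot(length(cluster_names) == n_clusters)

  if (is.null(marker_genes)) {
    marker_genes <- lapply(seq_len(n_clusters), function(cl)
      sprintf("MK%02d_%02d", cl, seq_len(n_markers)))
  } else {
    marker_genes <- lapply(marker_genes, normalize_gene_symbols)
    stopifnot(length(marker_genes) == n_clusters)
  }
  all_mk <- unlist(marker_genes, use.names = FALSE)
  if (anyDuplicated(all_mk))
    .stopf("planted marker sets must be disjoint (duplicated: %s)",
           paste(unique(all_mk[duplicated(all_mk)]), collapse = ", "))
  names(marker_genes) <- cluster_names

  bg <- if (config$n_background_genes > 0L)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character(0)
  genes <- unique(c(all_mk, bg))
  if (length(genes) < length(all_mk))
    .stopf("requested markers exceed gene universe")
  n_g <- length(genes)

  # baseline for reference cells a little higher than spots; markers boosted
  base <- max(config$baseline_mean, 0.1)
  mu <- matrix(base, n_g, n_clusters,
               dimnames = list(genes, cluster_names))
  for (cl in cluster_names)
    mu[marker_genes[[cl]], cl] <- base * marker_fold

  cell_cluster <- factor(rep(cluster_names, each = cells_per_cluster),
                         levels = cluster_names)
  n_c <- length(cell_cluster)
  mu_cells <- mu[, as.integer(cell_cluster), drop = FALSE]
  counts <- matrix(stats::rnbinom(n_g * n_c, mu = as.vector(mu_cells),
                                  size = config$nb_dispersion), n_g, n_c)
  dimnames(counts) <- list(genes, sprintf("CELL%05d", seq_len(n_c)))
  list(signatures = mu, markers = marker_genes,
       counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "generalMatrix"),
       cell_cluster = cell_cluster)
}

#' Generate a labelled segmentation mask with known cell areas
#'
#' Renders `n_cells` non-overlapping disks on an integer-labelled image
#' (0 = background, k > 0 = cell k) and records each cell's planted area in
#' square micrometres.  Target areas come either from `areas_um2` or from a
#' log-normal draw.
#'
#' @param n_cells number of cells (>= 0).
#' @param areas_um2 optional explicit target areas (recycled to
#'   `n_cells`).
#' @param area_meanlog,area_sdlog log-normal parameters used when
#'   `areas_um2` is `NULL`.  Defaults centre cell area near 4000 um^2.
#' @param pixel_size_um micrometres per pixel side (> 0).
#' @param dim optional `c(nrow, ncol)` image size; auto-sized when `NULL`.
#'   An explicit size too small to place all cells without overlap is an
#'   error.
#' @param seed integer seed.
#' @return list with `mask` (integer matrix; a `label_mask` with attribute
#'   `pixel_size_um`) and `areas_um2` (planted per-label truth).
#' @export
generate_label_mask <- function(n_cells, areas_um2 = NULL,
                                area_meanlog = log(4000),
                                area_sdlog = 0.35,
                                pixel_size_um = 2, dim = NULL, seed = 1L) {
  stopifnot(.is_count(n_cells, 0L), pixel_size_um > 0)
  set.seed(seed)
  if (n_cells == 0L) {
    mask <- matrix(0L, 32L, 32L)
    return(list(mask = label_mask(mask, pixel_size_um),
                areas_um2 = numeric(0)))
  }
  areas <- if (is.null(areas_um2))
    stats::rlnorm(n_cells, area_meanlog, area_sdlog)
  else rep_len(as.numeric(areas_um2), n_cells)
  stopifnot(all(areas > 0))
  r_px <- sqrt(areas / pi) / pixel_size_um
  cell_px <- ceiling(2 * max(r_px)) + 4L          # grid cell with margin
  per_row <- ceiling(sqrt(n_cells))
  need_rows <- ceiling(n_cells / per_row) * cell_px
  need_cols <- per_row * cell_px
  if (is.null(dim)) {
    dim <- c(need_rows, need_cols)
  } else if (dim[1L] < need_rows || dim[2L] < need_cols) {
    .stopf(paste0("cannot place %d cells of max radius %.1f px in a ",
                  "%d x %d image without overlap"),
           n_cells, max(r_px), dim[1L], dim[2L])
  }
  mask <- matrix(0L, dim[1L], dim[2L])
  for (k in seq_len(n_cells)) {
    gr <- (k - 1L) %/% per_row; gc <- (k - 1L) %% per_row
    cy <- gr * cell_px + cell_px / 2 + stats::runif(1, -1, 1)
    cx <- gc * cell_px + cell_px / 2 + stats::runif(1, -1, 1)
    rr <- r_px[k]
    ys <- max(1L, floor(cy - rr)):min(dim[1L], ceiling(cy + rr))
    xs <- max(1L, floor(cx - rr)):min(dim[2L], ceiling(cx + rr))
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    inside <- dy^2 + dx^2 <= rr^2
    sub <- mask[ys, xs, drop = FALSE]
    sub[inside] <- k
    mask[ys, xs] <- sub
  }
  list(mask = label_mask(mask, pixel_size_um), areas_um2 = areas)
}
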