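#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()].  Either simulated input (`simulate = TRUE`, with
#' `sim` a [sim_config()]) or real input (`sample_dirs` naming Space
#' Ranger-style directories plus per-sample `groups`, and optionally
#' `annotation_csv` + `cluster_map_csv`).
#'
#' @param simulate generate input with [generate_dataset()] (default).
#' @param sim a [sim_config()] used when simulating.
#' @param sample_dirs,groups real-input sample directories and group
#'   labels.
#' @param annotation_csv,cluster_map_csv optional annotation inputs for
#'   real data.
#' @param panels_path panel YAML (`NULL` = bundled defaults).
#' @param min_genes QC threshold (default 200).
#' @param n_clusters k for the k-means stage (default 2: the synthetic
#'   epidermis/dermis structure).
#' @param n_dims embedding dimensions (default 20).
#' @param deconv_threshold score threshold for [fraction_above()]
#'   (default 0.5).
#' @param mia_top_n top markers per cluster for MIA (default 300).
#' @param min_pct,min_log2fc,alpha marker-detection filters.
#' @param seed master seed.
#' @param output_dir where reports are written.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            sample_dirs = NULL, groups = NULL,
                            annotation_csv = NULL, cluster_map_csv = NULL,
                            panels_path = NULL, min_genes = 200L,
                            n_clusters = 2L, n_dims = 20L,
                            deconv_threshold = 0.5, mia_top_n = 300L,
                            min_pct = 0.25, min_log2fc = 0.25,
                            alpha = 0.05, seed = 1L,
                            output_dir = tempfile("spotscore_run_")) {
  stopifnot(.is_count(min_genes, 0L), .is_count(n_clusters, 1L),
            .is_count(n_dims, 1L), .is_count(mia_top_n, 1L),
            deconv_threshold >= 0, deconv_threshold <= 1,
            .is_prop(c(min_pct, alpha)), min_log2fc >= 0)
  if (!simulate) {
    if (is.null(sample_dirs) || is.null(groups) ||
        length(sample_dirs) != length(groups))
      .stopf("real input needs sample_dirs and matching groups")
  }
  structure(list(simulate = simulate, sim = sim,
                 sample_dirs = sample_dirs, groups = groups,
                 annotation_csv = annotation_csv,
                 cluster_map_csv = cluster_map_csv,
                 panels_path = panels_path, min_genes = min_genes,
                 n_clusters = as.integer(n_clusters),
                 n_dims = as.integer(n_dims),
                 deconv_threshold = deconv_threshold,
                 mia_top_n = as.integer(mia_top_n),
                 min_pct = min_pct, min_log2fc = min_log2fc,
                 alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

.stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e)
    .stopf("stage %s failed: %s", name, conditionMessage(e)))
}

#' Run the full scoring pipeline
#'
#' Sequences simulate/read, QC, merge, normalization, embedding,
#' clustering, marker detection, MIA, deconvolution, all spot-level panel
#' scores and the group comparisons, writing CSV reports, a log and a
#' manifest (config hash, seed, package version) to
#' `config$output_dir`.  Reruns with the same configuration and seed are
#' bit-identical.  Any stage error aborts with the stage name.
#'
#' Emitted score-report rows cover every figure-level statistic family:
#' per-gene and any-of-six ISG positivity (total and per compartment),
#' IFNB1 by compartment, myeloid deconvolution score thresholding, M1/M2
#' polarization and cytokine percentages within CD68+ spots, TGFB1 in the
#' biopsy / within CD68+ spots / per cluster, apoptosis marker combinations
#' (k = 1, 2, 5) and necroptosis by compartment, apoptosis-ISG
#' co-occurrence, and ZBP1 by compartment.
#'
#' @param config a [pipeline_config()] or path to a YAML file of its
#'   fields.
#' @return invisibly, a list of the in-memory results (`report`,
#'   `comparisons`, `markers`, `mia`, `deconv`, `output_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "log.txt")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message("[spotscore] ", msg)
  }
  panels <- load_panels(config$panels_path)

  # --- input -------------------------------------------------------------
  inp <- .stage("input", log, {
    if (config$simulate) {
      sim <- config$sim
      sim$seed <- config$seed
      generate_dataset(sim)
    } else {
      sl <- lapply(config$sample_dirs, read_spaceranger)
      ss <- sample_set(sl, config$groups)
      ann <- if (!is.null(config$annotation_csv))
        read_annotations(config$annotation_csv, ss,
                         config$cluster_map_csv)
      else NULL
      list(samples = ss, annotation = ann, truth = NULL)
    }
  })
  samples <- inp$samples; annotation <- inp$annotation

  # --- qc ---------------------------------------------------------------
  samples <- .stage("qc", log, {
    filtered <- lapply(samples$samples, qc_filter_spots,
                       min_genes = config$min_genes)
    kept <- vapply(filtered, n_spots, integer(1))
    log(sprintf("qc: retained %s spots",
                paste(kept, collapse = "/")))
    if (all(kept == 0L)) stop("no spots remain")
    keep <- kept > 0L
    sample_set(filtered[keep], samples$group[keep])
  })
  if (!is.null(annotation)) {
    keep_bc <- unlist(lapply(samples$samples, function(s)
      paste0(s$sample_id, "\r", s$barcodes)), use.names = FALSE)
    annotation <- annotation[
      paste0(annotation$sample_id, "\r", annotation$barcode) %in% keep_bc,
      , drop = FALSE]
  }

  # --- merge + normalize + embed + cluster ------------------------------
  merged <- .stage("merge", log, merge_samples(samples))
  norm <- .stage("normalize", log, normalize_counts(merged))
  emb <- .stage("embed", log,
                reduce_and_correct(norm,
                                   n_dims = min(config$n_dims,
                                                ncol(norm) - 1L,
                                                nrow(norm) - 1L),
                                   batch = merged$sample_of))
  labels <- .stage("cluster", log,
                   cluster_spots(emb, config$n_clusters,
                                 seed = config$seed))
  st_markers <- .stage("markers", log,
                       find_markers(norm, labels,
                                    min_pct = config$min_pct,
                                    min_log2fc = config$min_log2fc,
                                    alpha = config$alpha))

  # --- reference, MIA, deconvolution ------------------------------------
  ref <- .stage("reference", log, {
    if (config$simulate) {
      sim <- config$sim; sim$seed <- config$seed
      generate_scrna_reference(
        sim, n_clusters = 3L,
        cluster_names = c("Keratinocyte-1", "Fibroblast-1", "Myeloid-1"),
        marker_genes = list(sim$epidermis_markers, sim$dermis_markers,
                            unique(c(sim$anchor_gene, sim$m1_panel,
                                     sim$m2_panel))))
    } else NULL
  })
  mia <- NULL; deconv <- NULL; deconv_rows <- NULL
  if (!is.null(ref)) {
    sc_norm <- normalize_counts(ref$counts)
    sc_markers <- .stage("reference_markers", log,
                         find_markers(sc_norm, ref$cell_cluster,
                                      min_pct = config$min_pct,
                                      min_log2fc = config$min_log2fc,
                                      alpha = config$alpha))
    universe <- intersect(
      merged$gene_symbols[Matrix::rowSums(merged$counts) > 0],
      rownames(ref$counts))
    mia <- .stage("mia", log,
                  mia_enrichment(st_markers, sc_markers, universe,
                                 top_n = config$mia_top_n,
                                 p_adj_max = config$alpha,
                                 min_log2fc = config$min_log2fc))
    sigs <- .stage("signatures", log,
                   build_signatures(ref$counts, ref$cell_cluster))
    deconv <- .stage("deconv", log,
                     lapply(samples$samples, score_spots, signatures = sigs))
    deconv_rows <- do.call(rbind, lapply(deconv, function(d)
      fraction_above(d, "Myeloid-1",
                     threshold = config$deconv_threshold)))
  }

  # --- spot scores -------------------------------------------------------
  report <- .stage("score", log, {
    rows <- list()
    add <- function(x) rows[[length(rows) + 1L]] <<- x
    scopes <- c("total", "epidermis", "dermis")
    add(geneset_percent(samples, panels$isg, annotation, "total",
                        per_gene = TRUE))
    for (sc in scopes) {
      add(geneset_percent(samples, panels$isg, annotation, sc))
      add(geneset_percent(samples, panels$ifnb1, annotation, sc))
      add(geneset_percent(samples, panels$zbp1, annotation, sc))
      add(geneset_percent(samples, panels$necroptosis, annotation, sc))
      for (k in c(1L, 2L, 5L)) {
        pk <- gene_set_panel(sprintf("apoptosis_k%d", k),
                             panels$apoptosis$genes, k_required = k)
        add(geneset_percent(samples, pk, annotation, sc))
      }
    }
    add(geneset_percent(samples, panels$tgfb, annotation, "total"))
    for (cid in sort(unique(annotation$cluster_id %||% character(0))))
      add(geneset_percent(samples, panels$tgfb, annotation,
                          paste0("cluster:", cid)))
    out <- do.call(rbind, rows)
    class(out) <- c("score_report", "data.frame")
    out
  })

  cond <- .stage("conditional", log, {
    pol <- do.call(rbind, lapply(samples$samples, function(s)
      conditional_polarization(s, panels$anchor_cd68,
                               panels$m1_markers, panels$m2_markers)))
    cyto <- do.call(rbind, lapply(samples$samples, function(s) rbind(
      conditional_percent(s, panels$anchor_cd68, panels$m1_cytokines),
      conditional_percent(s, panels$anchor_cd68, panels$m2_cytokines),
      conditional_percent(s, panels$anchor_cd68, panels$tgfb))))
    cooc <- do.call(rbind, lapply(samples$samples, function(s)
      cooccurrence_percent(s, panels$isg, panels$apoptosis)))
    list(polarization = pol, conditional = cyto, cooccurrence = cooc)
  })

  # --- group comparisons -------------------------------------------------
  comparisons <- .stage("compare", log, {
    grp <- samples$group
    ctrl <- names(grp)[grp == "control"]; les <- names(grp)[grp == "lesion"]
    if (length(ctrl) >= 2L && length(les) >= 2L) {
      keys <- unique(report[, c("panel", "scope")])
      res <- lapply(seq_len(nrow(keys)), function(i) {
        sel <- report$panel == keys$panel[i] & report$scope == keys$scope[i]
        x <- report$percent[sel & report$sample_id %in% ctrl]
        y <- report$percent[sel & report$sample_id %in% les]
        if (anyNA(x) || anyNA(y)) return(NULL)
        cmp <- compare_groups(x, y)
        data.frame(panel = keys$panel[i], scope = keys$scope[i],
                   mean_control = cmp$mean_control,
                   mean_lesion = cmp$mean_lesion,
                   t = cmp$statistic, df = cmp$df, p = cmp$p,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    } else NULL
  })

  # --- outputs -----------------------------------------------------------
  .stage("write", log, {
    out <- config$output_dir
    utils::write.csv(report, file.path(out, "score_report.csv"),
                     row.names = FALSE)
    utils::write.csv(st_markers, file.path(out, "markers_st.csv"),
                     row.names = FALSE)
    utils::write.csv(cond$polarization,
                     file.path(out, "polarization.csv"), row.names = FALSE)
    utils::write.csv(cond$conditional,
                     file.path(out, "conditional_percent.csv"),
                     row.names = FALSE)
    utils::write.csv(cond$cooccurrence,
                     file.path(out, "cooccurrence.csv"), row.names = FALSE)
    if (!is.null(mia)) {
      utils::write.csv(mia$scores, file.path(out, "mia_scores.csv"))
      utils::write.csv(mia$overlap, file.path(out, "mia_overlap.csv"))
    }
    if (!is.null(deconv)) {
      all_scores <- do.call(rbind, lapply(deconv, function(d)
        data.frame(sample_id = d$sample_id,
                   barcode = rownames(d$scores), d$scores,
                   check.names = FALSE)))
      utils::write.csv(all_scores, file.path(out, "deconv_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(deconv_rows,
                       file.path(out, "deconv_fraction_above.csv"),
                       row.names = FALSE)
    }
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out, "comparisons.csv"),
                       row.names = FALSE)
    if (!is.null(inp$truth)) export_ground_truth(inp$truth, out)
    manifest <- list(
      config_hash = .config_hash(unclass(config)),
      seed = config$seed,
      package = "spotscore",
      version = as.character(utils::packageVersion("spotscore")),
      n_samples = length(samples$samples),
      created = "run")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, log_path)
  })

  invisible(list(report = report, polarization = cond$polarization,
                 conditional = cond$conditional,
                 cooccurrence = cond$cooccurrence,
                 deconv_fraction = deconv_rows,
                 comparisons = comparisons, markers = st_markers,
                 mia = mia, deconv = deconv,
                 labels = labels, output_dir = config$output_dir))
}
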