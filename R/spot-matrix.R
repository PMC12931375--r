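#' Construct a spot matrix (one Visium sample)
#'
#' Container for one sample's gene x spot UMI counts together with barcode
#' coordinates.  Counts are stored as a sparse `dgCMatrix` with genes in
#' rows (row names are gene symbols, disambiguated with the gene id on
#' duplicates) and spots in columns (column names are barcodes).
#'
#' @param counts gene x spot matrix of non-negative integers (coerced to
#'   sparse).
#' @param gene_ids,gene_symbols per-gene identifiers and symbols.
#' @param barcodes unique spot barcodes (one per column).
#' @param array_row,array_col integer array coordinates per spot.
#' @param pxl_row,pxl_col full-resolution pixel coordinates per spot.
#' @param in_tissue logical per spot.
#' @param sample_id single string identifying the sample.
#' @return an object of class `spot_matrix`.
#' @export
spot_matrix <- function(counts, gene_ids, gene_symbols, barcodes,
                        array_row, array_col, pxl_row = NULL, pxl_col = NULL,
                        in_tissue = NULL, sample_id = "sample") {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  n_g <- nrow(counts); n_s <- ncol(counts)
  stopifnot(length(gene_ids) == n_g, length(gene_symbols) == n_g,
            length(barcodes) == n_s,
            length(array_row) == n_s, length(array_col) == n_s)
  if (anyDuplicated(barcodes))
    .stopf("duplicate barcodes within sample '%s'", sample_id)
  if (any(counts@x < 0)) .stopf("counts must be non-negative")
  sym <- as.character(gene_symbols)
  dup <- duplicated(sym) | duplicated(sym, fromLast = TRUE)
  if (any(dup)) sym[dup] <- paste0(sym[dup], "_", gene_ids[dup])
  dimnames(counts) <- list(sym, as.character(barcodes))
  structure(list(
    counts = counts,
    gene_ids = as.character(gene_ids),
    gene_symbols = sym,
    barcodes = as.character(barcodes),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    pxl_row = as.numeric(pxl_row %||% rep(NA_real_, n_s)),
    pxl_col = as.numeric(pxl_col %||% rep(NA_real_, n_s)),
    in_tissue = as.logical(in_tissue %||% rep(TRUE, n_s)),
    sample_id = sample_id
  ), class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("<spot_matrix> %s: %d genes x %d spots (%d in tissue)\n",
              x$sample_id, nrow(x$counts), ncol(x$counts),
              sum(x$in_tissue)))
  invisible(x)
}

#' Number of spots in a sample
#' @param x a `spot_matrix`.
#' @return integer spot count.
#' @export
n_spots <- function(x) ncol(x$counts)

# subset spots by index/logical, keeping metadata aligned
.subset_spots <- function(x, keep) {
  idx <- if (is.logical(keep)) which(keep) else keep
  x$counts <- x$counts[, idx, drop = FALSE]
  for (f in c("barcodes", "array_row", "array_col", "pxl_row", "pxl_col",
              "in_tissue"))
    x[[f]] <- x[[f]][idx]
  if (!is.null(x$sample_of)) x$sample_of <- x$sample_of[idx]
  x
}

#' Bundle samples into an ordered sample set
#'
#' @param samples list of [spot_matrix()] objects with unique sample ids.
#' @param group per-sample group label, e.g. `"control"` or `"lesion"`.
#' @return an object of class `sample_set` (a list with elements `samples`
#'   and `group`).
#' @export
sample_set <- function(samples, group) {
  stopifnot(is.list(samples), length(samples) >= 1L,
            length(group) == length(samples))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) .stopf("duplicate sample ids: %s",
                                 paste(ids[duplicated(ids)], collapse = ", "))
  names(samples) <- ids
  structure(list(samples = samples,
                 group = stats::setNames(as.character(group), ids)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples: %s\n", length(x$samples),
              paste(sprintf("%s (%s)", names(x$samples), x$group),
                    collapse = ", ")))
  invisible(x)
}

#' Remove low-complexity spots
#'
#' Standard per-spot quality control: spots in which fewer than `min_genes`
#' genes are detected (raw count >= 1) are removed.  "Below 200" means spots
#' with exactly 200 detected genes are retained.  Genes are never removed.
#' The returned object carries the removal log in attribute `qc_log`
#' (a data frame of removed barcodes and their detected-gene counts).
#'
#' @param sample a [spot_matrix()].
#' @param min_genes minimum detected-gene count to retain a spot
#'   (default 200).
#' @return the filtered `spot_matrix`; possibly with zero spots.
#' @export
qc_filter_spots <- function(sample, min_genes = 200L) {
  stopifnot(inherits(sample, "spot_matrix"))
  if (!.is_count(min_genes, 0L)) .stopf("min_genes must be a count >= 0")
  detected <- Matrix::colSums(sample$counts >= 1L)
  keep <- detected >= min_genes
  out <- .subset_spots(sample, keep)
  attr(out, "qc_log") <- data.frame(
    barcode = sample$barcodes[!keep],
    detected_genes = as.integer(detected[!keep]),
    stringsAsFactors = FALSE)
  if (!any(keep))
    .warnf("qc_filter_spots: no spots remain in sample '%s'",
           sample$sample_id)
  out
}

#' Merge samples onto the shared gene universe
#'
#' Restricts every sample to the intersection of gene symbols and
#' concatenates spot columns.  Barcodes are prefixed with the sample id so
#' they stay unique; the per-spot origin is kept in field `sample_of`.
#'
#' @param samples a [sample_set()].
#' @return a single merged `spot_matrix` (sample_id `"merged"`).
#' @export
merge_samples <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  sl <- samples$samples
  if (length(sl) == 1L) {
    out <- sl[[1L]]
    out$sample_of <- rep(out$sample_id, n_spots(out))
    return(out)
  }
  shared <- Reduce(intersect, lapply(sl, function(s) s$gene_symbols))
  if (length(shared) == 0L) .stopf("merge_samples: empty gene intersection")
  shared <- sort(shared)
  parts <- lapply(sl, function(s) s$counts[shared, , drop = FALSE])
  counts <- do.call(cbind, parts)
  first <- sl[[1L]]
  ids <- first$gene_ids[match(shared, first$gene_symbols)]
  bc <- unlist(lapply(sl, function(s) paste0(s$sample_id, "_", s$barcodes)),
               use.names = FALSE)
  out <- spot_matrix(
    counts, gene_ids = ids, gene_symbols = shared, barcodes = bc,
    array_row = unlist(lapply(sl, `[[`, "array_row"), use.names = FALSE),
    array_col = unlist(lapply(sl, `[[`, "array_col"), use.names = FALSE),
    pxl_row = unlist(lapply(sl, `[[`, "pxl_row"), use.names = FALSE),
    pxl_col = unlist(lapply(sl, `[[`, "pxl_col"), use.names = FALSE),
    in_tissue = unlist(lapply(sl, `[[`, "in_tissue"), use.names = FALSE),
    sample_id = "merged")
  out$sample_of <- rep(names(sl),
                       vapply(sl, n_spots, integer(1)))
  out
}
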