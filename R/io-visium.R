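# Space Ranger-style directory I/O: matrix.mtx(.gz) + features.tsv(.gz) +
# barcodes.tsv(.gz) + tissue_positions.csv (or the pre-2.0
# tissue_positions_list.csv dialect without header).

.find_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

# Matrix::readMM needs a plain file; transparently inflate .gz first.
.read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    tf <- tempfile(fileext = ".mtx")
    on.exit(unlink(tf))
    inc <- gzfile(path, "rb"); outc <- file(tf, "wb")
    repeat {
      chunk <- readBin(inc, "raw", 1024L * 1024L)
      if (length(chunk) == 0L) break
      writeBin(chunk, outc)
    }
    close(inc); close(outc)
    path <- tf
    Matrix::readMM(path)
  } else Matrix::readMM(path)
}

.read_table_maybe_gz <- function(path, sep, header) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  utils::read.table(con, sep = sep, header = header,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

#' Read one Space Ranger-style Visium sample
#'
#' Expects a directory holding `matrix.mtx(.gz)`, `features.tsv(.gz)`,
#' `barcodes.tsv(.gz)` and tissue positions as either
#' `tissue_positions.csv` (with header, Space Ranger >= 2.0) or
#' `tissue_positions_list.csv` (headerless).  Counts are loaded losslessly
#' and joined to positions by barcode.  By default only `in_tissue` spots
#' are retained.
#'
#' @param directory path to the sample directory.
#' @param sample_id sample identifier; defaults to the directory basename.
#' @param keep_all keep spots outside the tissue as well (default `FALSE`).
#' @return a [spot_matrix()].
#' @export
read_spaceranger <- function(directory, sample_id = basename(directory),
                             keep_all = FALSE) {
  if (!dir.exists(directory)) .stopf("no such directory: %s", directory)
  mtx <- .find_file(directory, c("matrix.mtx.gz", "matrix.mtx"))
  fts <- .find_file(directory, c("features.tsv.gz", "features.tsv",
                                 "genes.tsv.gz", "genes.tsv"))
  bcs <- .find_file(directory, c("barcodes.tsv.gz", "barcodes.tsv"))
  pos <- .find_file(directory, c("tissue_positions.csv",
                                 "tissue_positions.csv.gz",
                                 "tissue_positions_list.csv",
                                 "tissue_positions_list.csv.gz"))
  if (is.null(mtx) || is.null(fts) || is.null(bcs))
    .stopf("directory %s lacks matrix/features/barcodes files", directory)
  if (is.null(pos)) .stopf("directory %s lacks tissue positions", directory)

  counts <- tryCatch(.read_mm(mtx),
                     error = function(e) .stopf("malformed MTX '%s': %s",
                                                mtx, conditionMessage(e)))
  feats <- .read_table_maybe_gz(fts, sep = "\t", header = FALSE)
  barcodes <- .read_table_maybe_gz(bcs, sep = "\t", header = FALSE)[[1L]]
  if (nrow(feats) != nrow(counts) || length(barcodes) != ncol(counts))
    .stopf("matrix dimensions (%d x %d) disagree with features/barcodes",
           nrow(counts), ncol(counts))

  # positions: sniff the header dialect
  first <- readLines(if (grepl("\\.gz$", pos)) gzfile(pos) else pos, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  posdf <- .read_table_maybe_gz(pos, sep = ",", header = has_header)
  colnames(posdf) <- c("barcode", "in_tissue", "array_row", "array_col",
                       "pxl_row_in_fullres", "pxl_col_in_fullres")
  m <- match(barcodes, posdf$barcode)
  if (anyNA(m))
    .stopf("barcode(s) in matrix but not in positions: %s",
           paste(utils::head(barcodes[is.na(m)], 5L), collapse = ", "))
  posdf <- posdf[m, , drop = FALSE]

  out <- spot_matrix(counts,
                     gene_ids = feats[[1L]],
                     gene_symbols = if (ncol(feats) >= 2L) feats[[2L]]
                                    else feats[[1L]],
                     barcodes = barcodes,
                     array_row = posdf$array_row,
                     array_col = posdf$array_col,
                     pxl_row = posdf$pxl_row_in_fullres,
                     pxl_col = posdf$pxl_col_in_fullres,
                     in_tissue = posdf$in_tissue == 1,
                     sample_id = sample_id)
  if (!keep_all) out <- .subset_spots(out, out$in_tissue)
  out
}

#' Write a sample as a Space Ranger-style directory
#'
#' Writes `matrix.mtx(.gz)` (1-based Matrix Market coordinates),
#' `features.tsv(.gz)` (id, symbol, "Gene Expression"),
#' `barcodes.tsv(.gz)` and `tissue_positions.csv`.
#' [read_spaceranger()] on the output reproduces the input exactly.
#'
#' @param sample a [spot_matrix()] with at least one spot.
#' @param directory output directory (created if needed).
#' @param gzip gzip the matrix/features/barcodes files (default `TRUE`).
#' @return `directory`, invisibly.
#' @export
write_spaceranger_layout <- function(sample, directory, gzip = TRUE) {
  stopifnot(inherits(sample, "spot_matrix"))
  if (n_spots(sample) < 1L) .stopf("sample has no spots")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) .stopf("cannot create directory %s", directory)

  plain <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(sample$counts, plain)
  .write_tsv <- function(df, base) {
    path <- file.path(directory, if (gzip) paste0(base, ".gz") else base)
    con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  if (gzip) {
    gz <- file.path(directory, "matrix.mtx.gz")
    inc <- file(plain, "rb"); outc <- gzfile(gz, "wb")
    repeat {
      chunk <- readBin(inc, "raw", 1024L * 1024L)
      if (length(chunk) == 0L) break
      writeBin(chunk, outc)
    }
    close(inc); close(outc)
    unlink(plain)
  }
  .write_tsv(data.frame(sample$gene_ids, sample$gene_symbols,
                        "Gene Expression"), "features.tsv")
  .write_tsv(data.frame(sample$barcodes), "barcodes.tsv")
  posdf <- data.frame(barcode = sample$barcodes,
                      in_tissue = as.integer(sample$in_tissue),
                      array_row = sample$array_row,
                      array_col = sample$array_col,
                      pxl_row_in_fullres = sample$pxl_row,
                      pxl_col_in_fullres = sample$pxl_col)
  utils::write.csv(posdf, file.path(directory, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(directory)
}

#' Read per-spot cluster annotations
#'
#' `csv` must have columns `sample_id`, `barcode`, `cluster_id`;
#' `cluster_map` maps `cluster_id` to a compartment (`epidermis`, `dermis`
#' or `other`).  Clusters absent from the map are assigned compartment
#' `"other"` with a warning.  Both arguments may be file paths or data
#' frames.
#'
#' @param csv annotation CSV (or data frame).
#' @param samples a [sample_set()] the annotation must refer to.
#' @param cluster_map CSV (or data frame) with columns `cluster_id`,
#'   `compartment`.
#' @return a `spot_annotation` data frame with columns `sample_id`,
#'   `barcode`, `cluster_id`, `compartment`; the map is kept in attribute
#'   `cluster_map`.
#' @export
read_annotations <- function(csv, samples, cluster_map) {
  ann <- if (is.character(csv)) utils::read.csv(csv, stringsAsFactors = FALSE)
         else as.data.frame(csv)
  map <- if (is.character(cluster_map))
           utils::read.csv(cluster_map, stringsAsFactors = FALSE)
         else as.data.frame(cluster_map)
  if (nrow(ann) == 0L) {
    .warnf("empty annotation")
    out <- data.frame(sample_id = character(0), barcode = character(0),
                      cluster_id = character(0), compartment = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("spot_annotation", "data.frame")
    attr(out, "cluster_map") <- map
    return(out)
  }
  need <- c("sample_id", "barcode", "cluster_id")
  if (!all(need %in% colnames(ann)))
    .stopf("annotation must have columns %s", paste(need, collapse = ", "))
  stopifnot(inherits(samples, "sample_set"))
  for (sid in unique(ann$sample_id)) {
    if (!sid %in% names(samples$samples))
      .stopf("annotation references unknown sample '%s'", sid)
    bad <- setdiff(ann$barcode[ann$sample_id == sid],
                   samples$samples[[sid]]$barcodes)
    if (length(bad) > 0L)
      .stopf("annotation references unknown barcode(s) in sample '%s': %s",
             sid, paste(utils::head(bad, 5L), collapse = ", "))
  }
  ann$cluster_id <- as.character(ann$cluster_id)
  map$cluster_id <- as.character(map$cluster_id)
  comp <- map$compartment[match(ann$cluster_id, map$cluster_id)]
  unmapped <- unique(ann$cluster_id[is.na(comp)])
  if (length(unmapped) > 0L)
    .warnf("cluster(s) %s not in cluster map; assigned compartment 'other'",
           paste(unmapped, collapse = ", "))
  comp[is.na(comp)] <- "other"
  out <- data.frame(sample_id = ann$sample_id, barcode = ann$barcode,
                    cluster_id = ann$cluster_id, compartment = comp,
                    stringsAsFactors = FALSE)
  class(out) <- c("spot_annotation", "data.frame")
  attr(out, "cluster_map") <- map
  out
}
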