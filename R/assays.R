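#' Relative expression by the delta-delta-Ct method
#'
#' For each target gene: `dCT = ct_target - ct_housekeeping`, `ddCT = dCT -
#' mean(dCT over the reference group)`, `RQ = 2^(-ddCT)` (amplification
#' efficiency fixed at 2, the standard ddCT assumption).  With a single
#' reference sample its RQ is exactly 1.
#'
#' @param table data frame with columns `sample_id`, `group` (`"reference"`
#'   or `"test"`), `target_gene`, `housekeeping_gene`, `ct_target`,
#'   `ct_housekeeping` (cycles).  Each target gene needs at least one
#'   reference sample; missing Ct values are an error naming the record.
#' @return the input with added columns `delta_ct`, `delta_delta_ct`,
#'   `rq`.
#' @export
#' @examples
#' ct <- data.frame(sample_id = c("ref", "t1"),
#'                  group = c("reference", "test"),
#'                  target_gene = "ISG15", housekeeping_gene = "GAPDH",
#'                  ct_target = c(27, 25), ct_housekeeping = c(20, 20))
#' ddct_relative_expression(ct)$rq   # 1, 4
ddct_relative_expression <- function(table) {
  table <- as.data.frame(table)
  need <- c("sample_id", "group", "target_gene", "housekeeping_gene",
            "ct_target", "ct_housekeeping")
  if (!all(need %in% colnames(table)))
    .stopf("Ct table must have columns %s", paste(need, collapse = ", "))
  bad <- !is.finite(table$ct_target) | !is.finite(table$ct_housekeeping)
  if (any(bad))
    .stopf("missing/non-finite Ct for sample(s): %s",
           paste(table$sample_id[bad], collapse = ", "))
  table$delta_ct <- table$ct_target - table$ct_housekeeping
  table$delta_delta_ct <- NA_real_
  for (g in unique(table$target_gene)) {
    sel <- table$target_gene == g
    ref <- sel & table$group == "reference"
    if (!any(ref))
      .stopf("target gene '%s' has no reference sample", g)
    table$delta_delta_ct[sel] <- table$delta_ct[sel] -
      mean(table$delta_ct[ref])
  }
  table$rq <- 2^(-table$delta_delta_ct)
  table
}

#' Read a Ct table from CSV
#' @param path CSV path with the columns documented in
#'   [ddct_relative_expression()].
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Labelled segmentation mask
#'
#' @param mask 2-D matrix of non-negative integers; 0 is background, any
#'   positive integer labels one cell (labels need not be contiguous).
#' @param pixel_size_um micrometres per pixel side (> 0).
#' @return a `label_mask` (integer matrix with attribute `pixel_size_um`).
#' @export
label_mask <- function(mask, pixel_size_um) {
  mask <- as.matrix(mask)
  if (pixel_size_um <= 0) .stopf("pixel_size_um must be > 0")
  if (any(mask < 0) || any(mask != floor(mask)))
    .stopf("mask must contain non-negative integers")
  storage.mode(mask) <- "integer"
  structure(mask, pixel_size_um = as.numeric(pixel_size_um),
            class = c("label_mask", "matrix", "array"))
}

#' Fraction of cells with area above a threshold
#'
#' Computes each labelled cell's area as pixel count times
#' `pixel_size_um^2` and reports the percentage of cells whose area
#' strictly exceeds `threshold_um2` (default 5000, the conventional
#' cell-size cutoff for calling epithelial-to-mesenchymal transition from
#' segmented images).  Cells touching the image border are excluded by
#' default because clipped cells bias the area down.
#'
#' @param mask a [label_mask()] (or plain integer matrix plus
#'   `pixel_size_um`).
#' @param threshold_um2 area threshold in square micrometres.
#' @param pixel_size_um required when `mask` is a plain matrix.
#' @param exclude_border drop border-touching cells (default `TRUE`).
#' @return list with `fraction_percent` (`NA` when no cell remains),
#'   `n_cells`, and `areas` (data frame of `label`, `pixels`,
#'   `area_um2`).
#' @export
area_fraction_above <- function(mask, threshold_um2 = 5000,
                                pixel_size_um = NULL,
                                exclude_border = TRUE) {
  if (!inherits(mask, "label_mask")) {
    if (is.null(pixel_size_um))
      .stopf("pixel_size_um required for a plain matrix mask")
    mask <- label_mask(mask, pixel_size_um)
  }
  psz <- attr(mask, "pixel_size_um")
  labs <- mask[mask > 0L]
  if (length(labs) == 0L)
    return(list(fraction_percent = NA_real_, n_cells = 0L,
                areas = data.frame(label = integer(0), pixels = integer(0),
                                   area_um2 = numeric(0))))
  counts <- table(labs)
  areas <- data.frame(label = as.integer(names(counts)),
                      pixels = as.integer(counts),
                      stringsAsFactors = FALSE)
  areas$area_um2 <- areas$pixels * psz^2
  if (exclude_border) {
    border <- unique(c(mask[1L, ], mask[nrow(mask), ],
                       mask[, 1L], mask[, ncol(mask)]))
    areas <- areas[!areas$label %in% border, , drop = FALSE]
  }
  n <- nrow(areas)
  frac <- if (n > 0) 100 * sum(areas$area_um2 > threshold_um2) / n
          else NA_real_
  list(fraction_percent = frac, n_cells = n, areas = areas)
}

#' Write / read a label mask as TIFF or PNG
#'
#' TIFF stores labels in a single 16-bit channel (up to 65535 cells per
#' image); PNG uses an 8-bit channel (up to 255 cells).  The pixel size is
#' not stored in the file and must be supplied on read.
#'
#' @param mask a [label_mask()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   returns a `label_mask`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  img <- unclass(mask)
  attr(img, "pixel_size_um") <- NULL
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(img) > 65535L)
      .stopf("more than 65535 labels do not fit 16-bit TIFF")
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(img) > 255L)
      .stopf("more than 255 labels do not fit 8-bit PNG; use TIFF")
    png::writePNG(img / 255, path)
  } else .stopf("unsupported mask format: %s", path)
  invisible(path)
}

#' @rdname write_label_mask
#' @param pixel_size_um micrometres per pixel side of the stored image.
#' @export
read_label_mask <- function(path, pixel_size_um) {
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  img <- if (is_tiff) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  label_mask(round(img * if (is_tiff) 65535 else 255), pixel_size_um)
}
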