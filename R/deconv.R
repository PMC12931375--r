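#' Build a cell-type signature matrix from a single-cell reference
#'
#' Averages reference expression per cell type on the shared gene set and
#' scales each column to unit L1 norm.  Accepts either a ready-made
#' gene x type profile matrix or a cell-level count matrix plus labels.
#'
#' @param reference gene x cell-type profile matrix, or gene x cell counts
#'   when `cell_types` is given per cell.
#' @param cell_types optional per-cell type labels (length = ncol of a
#'   cell-level `reference`).
#' @return a `signature_matrix`: gene x type numeric matrix, columns
#'   L1-normalized.
#' @export
build_signatures <- function(reference, cell_types = NULL) {
  m <- as.matrix(reference)
  if (!is.null(cell_types)) {
    stopifnot(length(cell_types) == ncol(m))
    cell_types <- as.character(cell_types)
    types <- unique(cell_types)
    if (length(types) < 2L) .stopf("need >= 2 cell types")
    prof <- vapply(types, function(tp) {
      idx <- which(cell_types == tp)
      if (length(idx) == 0L) .stopf("cell type '%s' has zero cells", tp)
      rowMeans(m[, idx, drop = FALSE])
    }, numeric(nrow(m)))
    m <- prof
  }
  if (ncol(m) < 2L) .stopf("need >= 2 cell types")
  if (anyDuplicated(colnames(m)))
    .stopf("duplicate cell type names: %s",
           paste(unique(colnames(m)[duplicated(colnames(m))]),
                 collapse = ", "))
  l1 <- colSums(abs(m))
  if (any(l1 == 0)) .stopf("all-zero signature column(s): %s",
                           paste(colnames(m)[l1 == 0], collapse = ", "))
  if (any(m < 0)) .stopf("signature profiles must be non-negative")
  out <- sweep(m, 2L, l1, "/")
  class(out) <- c("signature_matrix", class(out))
  out
}

#' Per-spot cell-type prediction scores by NNLS
#'
#' Regresses each spot's counts-per-10k profile onto the reference
#' signature columns by non-negative least squares (Lawson-Hanson, via
#' `pracma::lsqnonneg`) on the shared genes, then normalizes the
#' coefficients to sum to one so each row is a probability-like score
#' vector.  Spots with an all-zero solution are flagged rather than
#' normalized.
#'
#' @param sample a [spot_matrix()].
#' @param signatures a [build_signatures()] matrix.
#' @return a `deconv_scores` object: list with `scores` (spot x type
#'   matrix, rows summing to 1), `all_zero` (logical per spot) and
#'   `sample_id`.
#' @export
score_spots <- function(sample, signatures) {
  stopifnot(inherits(sample, "spot_matrix"))
  sig <- unclass(signatures)
  shared <- intersect(rownames(sig), sample$gene_symbols)
  if (length(shared) == 0L)
    .stopf("no shared genes between sample and signatures")
  A <- sig[shared, , drop = FALSE]
  cs <- Matrix::colSums(sample$counts)
  cs[cs == 0] <- 1
  prof <- as.matrix(sample$counts[shared, , drop = FALSE]) %*%
    diag(1e4 / cs, length(cs))
  n <- ncol(prof)
  scores <- matrix(0, n, ncol(A),
                   dimnames = list(sample$barcodes, colnames(A)))
  for (i in seq_len(n)) {
    coefs <- pracma::lsqnonneg(A, prof[, i])$x
    scores[i, ] <- coefs
  }
  tot <- rowSums(scores)
  all_zero <- tot <= 0
  scores[!all_zero, ] <- scores[!all_zero, , drop = FALSE] /
    tot[!all_zero]
  structure(list(scores = scores, all_zero = all_zero,
                 sample_id = sample$sample_id),
            class = "deconv_scores")
}

#' @export
print.deconv_scores <- function(x, ...) {
  cat(sprintf("<deconv_scores> %s: %d spots x %d cell types\n",
              x$sample_id, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Percentage of spots above a deconvolution score threshold
#'
#' The figure-level summary "percent of spots above a probability score of
#' 0.5": counts spots whose score for `celltype` strictly exceeds
#' `threshold` (set `strict = FALSE` for `>=`), within the whole sample or
#' a compartment scope.
#'
#' @param scores a [score_spots()] result.
#' @param celltype cell-type (column) name.
#' @param threshold score threshold (default 0.5).
#' @param annotation optional `spot_annotation` (needed for compartment
#'   scopes).
#' @param scope `"total"`, `"epidermis"`, `"dermis"` or `"other"`.
#' @param strict use `>` (default) rather than `>=`.
#' @return one-row data frame (`sample_id`, `celltype`, `scope`,
#'   `percent`, `numerator`, `denominator`); `percent` is `NA` when the
#'   scope is empty.
#' @export
fraction_above <- function(scores, celltype, threshold = 0.5,
                           annotation = NULL, scope = "total",
                           strict = TRUE) {
  stopifnot(inherits(scores, "deconv_scores"))
  if (!celltype %in% colnames(scores$scores))
    .stopf("cell type '%s' not in scores", celltype)
  bc <- rownames(scores$scores)
  keep <- if (scope == "total") rep(TRUE, length(bc)) else {
    if (is.null(annotation)) .stopf("scope '%s' needs an annotation", scope)
    a <- annotation[annotation$sample_id == scores$sample_id, , drop = FALSE]
    bc %in% a$barcode[a$compartment == scope]
  }
  den <- sum(keep)
  num <- if (den > 0)
    sum(if (strict) scores$scores[keep, celltype] > threshold
        else scores$scores[keep, celltype] >= threshold) else 0L
  data.frame(sample_id = scores$sample_id, celltype = celltype,
             scope = scope,
             percent = if (den > 0) 100 * num / den else NA_real_,
             numerator = num, denominator = den,
             stringsAsFactors = FALSE)
}
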