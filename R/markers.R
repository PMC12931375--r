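#' Normalize spot counts
#'
#' Two normalizations are offered.  `log_cp10k` is the standard
#' log-library-size transform `ln(1 + 1e4 * c / colsum)`.
#' `pearson_residual` computes analytic Pearson residuals under a
#' negative-binomial null with expected count
#' `mu = rowsum * colsum / total` and fixed dispersion `theta`
#' (`(c - mu) / sqrt(mu + mu^2/theta)`), clipped at `+/- sqrt(n_spots)`.
#' This serves as the variance-stabilizing stand-in for regularized NB
#' regression; downstream spot statistics depend only on cluster labels and
#' raw-count positivity, so the simpler transform suffices.
#'
#' @param sample a [spot_matrix()] or a gene x spot (sparse) count matrix.
#' @param method `"log_cp10k"` or `"pearson_residual"`.
#' @param theta NB dispersion for the Pearson residual null (default 100).
#' @return gene x spot normalized matrix (sparse for `log_cp10k`, dense for
#'   `pearson_residual`) with the input dimnames and attribute
#'   `normalization`.
#' @export
normalize_counts <- function(sample,
                             method = c("log_cp10k", "pearson_residual"),
                             theta = 100) {
  method <- match.arg(method)
  counts <- if (inherits(sample, "spot_matrix")) sample$counts else {
    m <- if (inherits(sample, "Matrix")) sample
         else Matrix::Matrix(as.matrix(sample), sparse = TRUE)
    methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  }
  if (any(counts@x < 0)) .stopf("counts must be non-negative")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    .stopf(paste0("spot(s) with zero total counts (e.g. %s); run ",
                  "qc_filter_spots first"),
           colnames(counts)[which(cs == 0)[1L]] %||% "unnamed")
  if (method == "log_cp10k") {
    out <- counts
    out@x <- log1p(out@x * rep.int(1e4 / cs, diff(out@p)))
  } else {
    d <- as.matrix(counts)
    rs <- rowSums(d); tot <- sum(d)
    mu <- outer(rs, cs) / tot
    out <- (d - mu) / sqrt(mu + mu^2 / theta)
    out[is.nan(out)] <- 0         # genes with zero total
    clip <- sqrt(ncol(d))
    out[out > clip] <- clip; out[out < -clip] <- -clip
  }
  attr(out, "normalization") <- method
  out
}

#' PCA embedding with per-batch centering
#'
#' Computes PCA scores of spots on the top `n_hvg` most variable genes
#' (variance ranking of the normalized matrix), then removes batch
#' structure by centering each batch's rows in PC space onto the global
#' mean.  This is a deliberately simple linear stand-in for iterative
#' mixture-based batch integration: the downstream statistics in this
#' package depend only on cluster labels.  The SVD sign is fixed by making
#' the largest-magnitude loading of each component positive, so results are
#' deterministic.
#'
#' @param normalized gene x spot normalized matrix.
#' @param n_dims number of dimensions to keep (default 20).
#' @param batch optional per-spot batch labels (e.g. sample ids).
#' @param n_hvg number of most-variable genes for the PCA (default 2000,
#'   truncated to the gene count).
#' @return spot x `n_dims` score matrix with attribute `batch`.
#' @export
reduce_and_correct <- function(normalized, n_dims = 20L, batch = NULL,
                               n_hvg = 2000L) {
  m <- as.matrix(normalized)
  stopifnot(.is_count(n_dims, 1L))
  v <- apply(m, 1L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(m)))]
  keep <- keep[v[keep] > 0]
  if (length(keep) < n_dims)
    .stopf("only %d genes with nonzero variance; cannot extract %d dims",
           length(keep), n_dims)
  x <- t(m[keep, , drop = FALSE])
  x <- sweep(x, 2L, colMeans(x))
  sv <- svd(x, nu = n_dims, nv = n_dims)
  if (sv$d[n_dims] <= sv$d[1L] * 1e-12)
    .stopf("n_dims = %d exceeds the numerical rank of the data", n_dims)
  # deterministic sign: largest-|loading| entry of each PC positive
  for (j in seq_len(n_dims)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  emb <- sv$u %*% diag(sv$d[seq_len(n_dims)], n_dims)
  rownames(emb) <- colnames(m)
  colnames(emb) <- sprintf("PC%d", seq_len(n_dims))
  if (!is.null(batch)) {
    stopifnot(length(batch) == nrow(emb))
    gm <- colMeans(emb)
    for (b in unique(batch)) {
      i <- which(batch == b)
      emb[i, ] <- sweep(emb[i, , drop = FALSE], 2L,
                        colMeans(emb[i, , drop = FALSE]) - gm)
    }
  }
  attr(emb, "batch") <- batch
  emb
}

#' Cluster spots by k-means
#'
#' Deterministic k-means (seeded, `nstart = 10`) on the embedding as the
#' clustering stand-in for graph/resolution-based community detection.
#' Labels run 0 .. k-1.
#'
#' @param embedding spot x dim matrix from [reduce_and_correct()].
#' @param k number of clusters (1 <= k <= number of spots).
#' @param seed integer seed.
#' @return integer vector of labels in 0..k-1, named by spot.
#' @export
cluster_spots <- function(embedding, k, seed = 1L) {
  emb <- as.matrix(embedding)
  stopifnot(.is_count(k, 1L))
  if (k > nrow(emb)) .stopf("k = %d exceeds the %d spots", k, nrow(emb))
  if (k == 1L)
    return(stats::setNames(rep(0L, nrow(emb)), rownames(emb)))
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = 10L, iter.max = 100L)
  stats::setNames(as.integer(km$cluster) - 1L, rownames(emb))
}

# two-sided rank-sum p; exact enumeration when both groups small and
# tie-free, else the normal approximation (tie-corrected).
.rank_sum_p <- function(x, y, exact = NULL) {
  if (is.null(exact))
    exact <- length(x) <= 10L && length(y) <= 10L &&
      !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact)$p.value)
}

#' One-vs-rest marker detection with Wilcoxon rank-sum tests
#'
#' For each cluster, every gene detected (nonzero) in at least `min_pct` of
#' the cluster or of the rest is tested with a two-sided Wilcoxon rank-sum
#' test on the normalized values (exact enumeration when both groups have
#' at most 10 spots without ties, otherwise the tie-corrected normal
#' approximation).  The log2 fold change is computed on de-logged means,
#' `log2((mean(expm1(in)) + eps) / (mean(expm1(out)) + eps))` with
#' `eps = 1e-9`.  P values are Benjamini-Hochberg adjusted across the full
#' tested set; records with `log2fc >= min_log2fc` (upregulated only) and
#' `p_adj <= alpha` are retained, ordered by cluster, then decreasing
#' log2fc, then gene symbol.
#'
#' @param normalized gene x spot log-normalized matrix (from
#'   [normalize_counts()] with `log_cp10k`).
#' @param labels per-spot cluster labels (>= 2 distinct values; clusters
#'   with fewer than 3 spots are skipped with a warning).
#' @param min_pct minimum detection fraction (default 0.25).
#' @param min_log2fc log2 fold-change cutoff (default 0.25).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return a `marker_table` data frame with columns `cluster_id`, `gene`,
#'   `log2fc`, `pct_in`, `pct_out`, `p`, `p_adj`.
#' @export
find_markers <- function(normalized, labels, min_pct = 0.25,
                         min_log2fc = 0.25, alpha = 0.05) {
  m <- normalized
  stopifnot(ncol(m) == length(labels))
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) .stopf("find_markers needs >= 2 clusters")
  small <- names(sizes)[sizes < 3L]
  if (length(small) > 0L)
    .warnf("cluster(s) with < 3 spots skipped: %s",
           paste(small, collapse = ", "))
  clusters <- setdiff(names(sizes), small)
  eps <- 1e-9
  dense <- as.matrix(m)
  det <- dense > 0
  rows <- list()
  for (cl in clusters) {
    inn <- labels == cl
    pct_in <- rowMeans(det[, inn, drop = FALSE])
    pct_out <- rowMeans(det[, !inn, drop = FALSE])
    tested <- which(pmax(pct_in, pct_out) >= min_pct)
    if (length(tested) == 0L) next
    mu_in <- rowMeans(expm1(dense[tested, inn, drop = FALSE]))
    mu_out <- rowMeans(expm1(dense[tested, !inn, drop = FALSE]))
    l2fc <- log2((mu_in + eps) / (mu_out + eps))
    p <- vapply(tested, function(g)
      .rank_sum_p(dense[g, inn], dense[g, !inn]), numeric(1))
    rows[[cl]] <- data.frame(
      cluster_id = cl, gene = rownames(dense)[tested], log2fc = l2fc,
      pct_in = pct_in[tested], pct_out = pct_out[tested], p = p,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0L) .stopf("no genes passed the detection filter")
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  tab <- tab[tab$log2fc >= min_log2fc & tab$p_adj <= alpha, , drop = FALSE]
  tab <- tab[order(tab$cluster_id, -tab$log2fc, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("marker_table", "data.frame")
  tab
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("<marker_table> %d markers across %d cluster(s)\n",
              nrow(x), length(unique(x$cluster_id))))
  NextMethod()
}
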