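#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`:
#' `p_adj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, stable under
#' input ordering.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.04, 0.04, 0.9))
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    .stopf("p values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Signed hypergeometric tail score used by MIA: for overlap k between sets
# of sizes m and n in a universe of N genes,
#   -log10 P(X >= k)  when k >= E[X] = m*n/N  (enrichment, positive)
#   +log10 P(X <= k)  otherwise               (depletion, negative)
# with p floored at 1e-300.  Ties at expectation break toward enrichment.
.hyper_score <- function(k, m, n, N) {
  if (m > N || n > N || k > min(m, n))
    .stopf("invalid hypergeometric configuration (k=%d, m=%d, n=%d, N=%d)",
           k, m, n, N)
  if (m == 0L || n == 0L) return(0)
  if (k >= m * n / N) {
    p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    -log10(max(p, 1e-300))
  } else {
    p <- stats::phyper(k, m, N - m, n, lower.tail = TRUE)
    log10(max(p, 1e-300))
  }
}

# filter + rank a marker table and return per-cluster top-N gene sets;
# clusters whose markers all fail the filters keep an empty set so they
# still appear (as zero rows/columns) in the score matrix.
.top_markers <- function(markers, top_n, p_adj_max, min_log2fc, universe) {
  clusters <- unique(as.character(markers$cluster_id))
  tab <- markers[markers$p_adj <= p_adj_max & markers$log2fc > min_log2fc,
                 , drop = FALSE]
  sets <- lapply(split(tab, factor(tab$cluster_id, levels = clusters)),
                 function(d) {
    d <- d[order(-d$log2fc, d$gene), , drop = FALSE]
    intersect(utils::head(d$gene, top_n), universe)
  })
  sets[order(names(sets))]
}

#' Multimodal intersection analysis (MIA)
#'
#' Scores the correspondence between spatial clusters and single-cell
#' reference clusters by the hypergeometric overlap of their marker-gene
#' sets.  Markers are first filtered to adjusted p <= `p_adj_max` and
#' log2 fold change > `min_log2fc`, ranked by decreasing log2 fold change
#' (ties by gene symbol), and capped at the top `top_n` per cluster
#' (default 300).  The enrichment score for overlap `k` between sets of
#' sizes `m` and `n` in a shared universe of `N` genes is
#' `-log10 P(X >= k)` when `k` is at or above its expectation `m*n/N`, and
#' the (negative) `log10 P(X <= k)` otherwise, with the p value floored at
#' 1e-300.
#'
#' @param st_markers,sc_markers `marker_table`s for the spatial and
#'   reference clusters.
#' @param universe character vector of genes forming the shared universe
#'   (typically: genes detected in the merged spatial data intersected with
#'   the reference genes).
#' @param top_n markers used per cluster after filtering (default 300).
#' @param p_adj_max,min_log2fc marker filters (defaults 0.05 and 0.25).
#' @return a `mia_enrichment` object: list with `scores` and `overlap`
#'   matrices (ST clusters x reference clusters), set sizes and
#'   `universe_size`.
#' @export
mia_enrichment <- function(st_markers, sc_markers, universe, top_n = 300L,
                           p_adj_max = 0.05, min_log2fc = 0.25) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) .stopf("empty gene universe")
  st_sets <- .top_markers(st_markers, top_n, p_adj_max, min_log2fc,
                          universe)
  sc_sets <- .top_markers(sc_markers, top_n, p_adj_max, min_log2fc,
                          universe)
  empty <- c(names(st_sets)[lengths(st_sets) == 0L],
             names(sc_sets)[lengths(sc_sets) == 0L])
  if (length(empty) > 0L)
    .warnf("cluster(s) with no passing markers score 0: %s",
           paste(unique(empty), collapse = ", "))
  N <- length(universe)
  scores <- matrix(0, length(st_sets), length(sc_sets),
                   dimnames = list(names(st_sets), names(sc_sets)))
  overlap <- scores
  for (i in seq_along(st_sets)) for (j in seq_along(sc_sets)) {
    m <- length(st_sets[[i]]); n <- length(sc_sets[[j]])
    k <- length(intersect(st_sets[[i]], sc_sets[[j]]))
    overlap[i, j] <- k
    scores[i, j] <- .hyper_score(k, m, n, N)
  }
  structure(list(scores = scores, overlap = overlap,
                 st_set_sizes = lengths(st_sets),
                 sc_set_sizes = lengths(sc_sets),
                 universe_size = N),
            class = "mia_enrichment")
}

#' @export
print.mia_enrichment <- function(x, ...) {
  cat(sprintf("<mia_enrichment> %d ST x %d reference clusters (N = %d)\n",
              nrow(x$scores), ncol(x$scores), x$universe_size))
  print(round(x$scores, 2))
  invisible(x)
}

#' Gene-set library for over-representation analysis
#'
#' @param sets named list of gene-symbol vectors.
#' @param universe gene universe; set members outside it are dropped with a
#'   warning.
#' @return a `gene_set_library` object.
#' @export
gene_set_library <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            !is.null(names(sets)), all(nzchar(names(sets))))
  universe <- unique(normalize_gene_symbols(universe))
  if (length(universe) == 0L) .stopf("empty universe")
  sets <- lapply(sets, normalize_gene_symbols)
  dropped <- sum(vapply(sets, function(s)
    sum(!s %in% universe), integer(1)))
  if (dropped > 0L)
    .warnf("%d set gene(s) outside the universe dropped", dropped)
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_library")
}

#' Read / write gene-set libraries in GMT format
#' @param path GMT file (tab-separated: name, description, genes...).
#' @param universe universe passed to [gene_set_library()]; defaults to the
#'   union of all set genes.
#' @return `read_gmt` returns a `gene_set_library`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_library(sets, universe %||%
                     unique(unlist(sets, use.names = FALSE)))
}

#' @rdname read_gmt
#' @param library a `gene_set_library` to write.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(nm)
    paste(c(nm, nm, library$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Local over-representation analysis
#'
#' One-sided hypergeometric enrichment of a query gene set against every
#' set of a library, with Benjamini-Hochberg adjustment across sets.
#' A drop-in local replacement for web-service enrichment: supply any
#' library as GMT via [read_gmt()].
#'
#' @param query character vector of gene symbols; genes outside the library
#'   universe are dropped with a warning, an empty query is an error.
#' @param library a [gene_set_library()].
#' @return data frame (`set`, `set_size`, `overlap`, `p`, `p_adj`) sorted
#'   by ascending `p_adj` then `p`.
#' @export
enrich_gene_sets <- function(query, library) {
  stopifnot(inherits(library, "gene_set_library"))
  query <- unique(normalize_gene_symbols(query))
  outside <- setdiff(query, library$universe)
  if (length(outside) > 0L)
    .warnf("%d query gene(s) outside the universe dropped",
           length(outside))
  query <- setdiff(query, outside)
  if (length(query) == 0L) .stopf("empty query after universe filtering")
  N <- length(library$universe); q <- length(query)
  res <- do.call(rbind, lapply(names(library$sets), function(nm) {
    s <- library$sets[[nm]]
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1L, length(s), N - length(s), q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p_adj, res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
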