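#' Spot positivity for a gene-set panel
#'
#' A spot is positive when at least `k_required` of the panel genes each
#' have raw count >= `min_count` (both from the panel).  Positivity is
#' deliberately called on raw post-QC counts, not normalized values: a
#' nonzero UMI is the only threshold-free reading of a spot "expressing" a
#' gene.  Panel genes absent from the sample are dropped with a warning;
#' if none are present it is an error.
#'
#' @param sample a [spot_matrix()].
#' @param panel a [gene_set_panel()].
#' @return named logical vector (one element per spot).
#' @export
positivity_matrix <- function(sample, panel) {
  stopifnot(inherits(sample, "spot_matrix"),
            inherits(panel, "gene_set_panel"))
  present <- .match_genes(panel$genes, sample$gene_symbols)
  miss <- attr(present, "missing")
  if (length(miss) > 0L)
    .warnf("panel '%s': gene(s) not in sample '%s': %s", panel$name,
           sample$sample_id, paste(miss, collapse = ", "))
  if (length(present) == 0L)
    .stopf("panel '%s': no genes present in sample '%s'", panel$name,
           sample$sample_id)
  sub <- sample$counts[present, , drop = FALSE]
  hits <- Matrix::colSums(sub >= panel$min_count)
  stats::setNames(hits >= panel$k_required, sample$barcodes)
}

# barcodes of a sample falling in a scope
#   "total" | "epidermis" | "dermis" | "other" | "cluster:<id>"
.scope_barcodes <- function(sample, annotation, scope) {
  if (scope == "total") return(sample$barcodes)
  if (is.null(annotation))
    .stopf("scope '%s' requires an annotation", scope)
  a <- annotation[annotation$sample_id == sample$sample_id, , drop = FALSE]
  if (startsWith(scope, "cluster:")) {
    cid <- sub("^cluster:", "", scope)
    a$barcode[a$cluster_id == cid]
  } else {
    a$barcode[a$compartment == scope]
  }
}

.report_row <- function(sample_id, group, panel, scope, num, den) {
  data.frame(sample_id = sample_id, group = group, panel = panel,
             scope = scope,
             percent = if (den > 0) 100 * num / den else NA_real_,
             numerator = as.integer(num), denominator = as.integer(den),
             stringsAsFactors = FALSE)
}

#' Per-sample gene-set positivity percentages
#'
#' The core figure-level statistic: for each sample, the percentage of
#' spots in `scope` that are positive for `panel`.  With
#' `per_gene = TRUE`, each panel gene is reported separately as a
#' one-gene panel (per-gene ISG plots).  Empty scopes yield a
#' missing-value record (`percent = NA`, `denominator = 0`), never a
#' silent zero.
#'
#' @param samples a [sample_set()] or single [spot_matrix()].
#' @param panel a [gene_set_panel()].
#' @param annotation optional `spot_annotation` (required for
#'   non-`"total"` scopes).
#' @param scope `"total"`, `"epidermis"`, `"dermis"`, `"other"` or
#'   `"cluster:<id>"`.
#' @param per_gene report each panel gene separately (default `FALSE`).
#' @param group optional per-sample group labels (taken from the
#'   `sample_set` when available).
#' @return a `score_report` data frame (`sample_id`, `group`, `panel`,
#'   `scope`, `percent`, `numerator`, `denominator`).
#' @export
geneset_percent <- function(samples, panel, annotation = NULL,
                            scope = "total", per_gene = FALSE,
                            group = NULL) {
  if (inherits(samples, "spot_matrix"))
    samples <- sample_set(list(samples), group %||% "sample")
  stopifnot(inherits(samples, "sample_set"))
  panels <- if (per_gene)
    lapply(panel$genes, function(g)
      gene_set_panel(paste0(panel$name, ":", g), g,
                     min_count = panel$min_count))
  else list(panel)
  rows <- list()
  for (sid in names(samples$samples)) {
    s <- samples$samples[[sid]]
    in_scope <- s$barcodes %in% .scope_barcodes(s, annotation, scope)
    for (p in panels) {
      pos <- positivity_matrix(s, p)
      rows[[length(rows) + 1L]] <- .report_row(
        sid, samples$group[[sid]], p$name, scope,
        sum(pos & in_scope), sum(in_scope))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_report", "data.frame")
  out
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %d record(s)\n", nrow(x)))
  NextMethod()
}

#' M1/M2 polarization within anchor-positive spots
#'
#' Classifies the anchor-positive spots of one sample as expressing
#' `setA` only, `setB` only, or both, and reports the three percentages.
#' The default denominator is the anchor-positive spots positive for at
#' least one marker of either set (so the fractions sum to exactly 100,
#' matching stacked-bar displays); `denominator = "all_anchor"` divides by
#' all anchor-positive spots instead.
#'
#' @param sample a [spot_matrix()].
#' @param anchor,setA,setB [gene_set_panel()]s; `setA` and `setB` must not
#'   share genes.
#' @param denominator `"positive"` (default) or `"all_anchor"`.
#' @return data frame with rows `A_only`, `B_only`, `both` and columns
#'   `sample_id`, `category`, `percent`, `numerator`, `denominator`.
#'   Percentages are `NA` when no anchor-positive spot exists.
#' @export
conditional_polarization <- function(sample, anchor, setA, setB,
                                     denominator = c("positive",
                                                     "all_anchor")) {
  denominator <- match.arg(denominator)
  shared <- intersect(setA$genes, setB$genes)
  if (length(shared) > 0L)
    .stopf("setA and setB overlap (%s): classification ambiguous",
           paste(shared, collapse = ", "))
  anc <- positivity_matrix(sample, anchor)
  a <- positivity_matrix(sample, setA)
  b <- positivity_matrix(sample, setB)
  a_only <- sum(anc & a & !b)
  b_only <- sum(anc & !a & b)
  both <- sum(anc & a & b)
  den <- if (denominator == "positive") a_only + b_only + both
         else sum(anc)
  data.frame(
    sample_id = sample$sample_id,
    category = c("A_only", "B_only", "both"),
    percent = if (den > 0) 100 * c(a_only, b_only, both) / den
              else rep(NA_real_, 3L),
    numerator = c(a_only, b_only, both), denominator = den,
    stringsAsFactors = FALSE)
}

#' Conditional positivity percentage
#'
#' Percentage of anchor-positive spots that are also positive for a target
#' panel (e.g. the share of CD68+ spots expressing M1 cytokines, or TGFB1
#' within CD68+ spots).  `scope` restricts the anchor-positive spots to a
#' compartment or cluster first.
#'
#' @param sample a [spot_matrix()].
#' @param anchor,target [gene_set_panel()]s.
#' @param annotation,scope optional scope restriction as in
#'   [geneset_percent()].
#' @return one-row data frame (`sample_id`, `anchor`, `target`, `scope`,
#'   `percent`, `numerator`, `denominator`); `percent` is `NA` when there
#'   are no anchor-positive spots in scope.
#' @export
conditional_percent <- function(sample, anchor, target,
                                annotation = NULL, scope = "total") {
  anc <- positivity_matrix(sample, anchor)
  tgt <- positivity_matrix(sample, target)
  in_scope <- sample$barcodes %in%
    .scope_barcodes(sample, annotation, scope)
  den <- sum(anc & in_scope)
  num <- sum(anc & tgt & in_scope)
  data.frame(sample_id = sample$sample_id, anchor = anchor$name,
             target = target$name, scope = scope,
             percent = if (den > 0) 100 * num / den else NA_real_,
             numerator = num, denominator = den, stringsAsFactors = FALSE)
}

#' Outcome positivity within and outside a conditioning stratum
#'
#' Computes the percentage of `outcome`-positive spots among
#' conditioning-positive spots and, separately, among
#' conditioning-negative spots (e.g. apoptosis-marker positivity within
#' IFN-I inflamed versus non-inflamed spots).
#'
#' @param sample a [spot_matrix()].
#' @param conditioning,outcome [gene_set_panel()]s.
#' @return two-row data frame (`stratum` = `"positive"` / `"negative"`)
#'   with `percent`, `numerator`, `denominator`; empty strata give `NA`.
#' @export
cooccurrence_percent <- function(sample, conditioning, outcome) {
  cond <- positivity_matrix(sample, conditioning)
  out <- positivity_matrix(sample, outcome)
  res <- lapply(c(positive = TRUE, negative = FALSE), function(v) {
    den <- sum(cond == v); num <- sum(cond == v & out)
    c(num = num, den = den)
  })
  data.frame(
    sample_id = sample$sample_id,
    conditioning = conditioning$name, outcome = outcome$name,
    stratum = c("positive", "negative"),
    percent = vapply(res, function(r)
      if (r["den"] > 0) 100 * r["num"] / r["den"] else NA_real_,
      numeric(1)),
    numerator = vapply(res, `[[`, numeric(1), "num"),
    denominator = vapply(res, `[[`, numeric(1), "den"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare per-sample percentages between groups
#'
#' Two-sided comparison of per-sample summary percentages (control versus
#' lesion).  `"student"` is the pooled-variance two-tailed t test (the
#' spreadsheet/Prism default), `"welch"` drops the equal-variance
#' assumption, and `"permutation"` uses the difference in group means as
#' test statistic: all `choose(n1+n2, n1)` relabelings are enumerated when
#' that count is at most `n_perm` (exact mode, p = count / total),
#' otherwise `n_perm` random relabelings give
#' `p = (1 + #{|T| >= |T_obs|}) / (1 + n_perm)`.
#'
#' @param control,lesion numeric vectors of per-sample percentages.
#' @param method `"student"`, `"welch"` or `"permutation"`.
#' @param n_perm permutation budget (default 10000).
#' @param seed seed for sampled permutations.
#' @return a `group_comparison` list: `statistic`, `df`, `p`, `method`,
#'   group means, and for permutation the mode (`"exact"`/`"sampled"`).
#' @export
compare_groups <- function(control, lesion,
                           method = c("student", "welch", "permutation"),
                           n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  control <- as.numeric(control); lesion <- as.numeric(lesion)
  stopifnot(all(is.finite(control)), all(is.finite(lesion)))
  out <- list(method = method,
              mean_control = mean(control), mean_lesion = mean(lesion),
              n_control = length(control), n_lesion = length(lesion))
  if (method %in% c("student", "welch")) {
    if (length(control) < 2L || length(lesion) < 2L)
      .stopf(paste0("t methods need >= 2 samples per group; ",
                    "use method = 'permutation'"))
    if (stats::var(control) == 0 && stats::var(lesion) == 0 &&
        mean(control) == mean(lesion)) {
      out$statistic <- 0; out$p <- 1
      out$df <- length(control) + length(lesion) - 2L
    } else {
      tt <- stats::t.test(control, lesion,
                          var.equal = method == "student")
      out$statistic <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p <- tt$p.value
    }
  } else {
    obs <- mean(control) - mean(lesion)
    pool <- c(control, lesion)
    n1 <- length(control); ntot <- length(pool)
    n_comb <- choose(ntot, n1)
    if (n_comb <= n_perm) {
      combs <- utils::combn(ntot, n1)
      stat <- apply(combs, 2L, function(idx)
        mean(pool[idx]) - mean(pool[-idx]))
      out$p <- sum(abs(stat) >= abs(obs) - 1e-12) / n_comb
      out$mode <- "exact"; out$n_perm <- n_comb
    } else {
      set.seed(seed)
      stat <- replicate(n_perm, {
        idx <- sample.int(ntot, n1)
        mean(pool[idx]) - mean(pool[-idx])
      })
      out$p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (1 + n_perm)
      out$mode <- "sampled"; out$n_perm <- n_perm
    }
    out$statistic <- obs
    out$df <- NA_real_
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: control %.2f vs lesion %.2f, p = %.4g\n",
    x$method, x$mean_control, x$mean_lesion, x$p))
  invisible(x)
}

#' Scatter plot of spot positivity
#'
#' Simple array-coordinate scatter of one sample with positive spots
#' highlighted, the in-silico counterpart of a spatial feature plot.
#'
#' @param sample a [spot_matrix()].
#' @param positive logical per spot (e.g. from [positivity_matrix()]).
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_spots <- function(sample, positive = NULL, main = sample$sample_id) {
  stopifnot(inherits(sample, "spot_matrix"))
  col <- if (is.null(positive)) "grey70"
         else ifelse(positive, "firebrick", "grey85")
  graphics::plot(sample$array_col, -sample$array_row, pch = 16,
                 cex = 0.6, col = col, asp = 1, xlab = "array col",
                 ylab = "array row (flipped)", main = main)
  invisible(NULL)
}
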