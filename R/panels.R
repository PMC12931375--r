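#' Gene-set panel with a k-of-n positivity rule
#'
#' A panel is a named list of gene symbols together with the rule that calls
#' a spot "positive": at least `k_required` of the panel genes must each have
#' a raw count of at least `min_count`.  The default (`k_required = 1`,
#' `min_count = 1`) is the any-of rule used for the six-gene ISG panel;
#' `k_required = 2` or `5` gives the stricter multi-marker apoptosis calls.
#'
#' @param name panel name (single string).
#' @param genes character vector of gene symbols; normalized via
#'   [normalize_gene_symbols()].
#' @param k_required minimum number of panel genes that must be detected for
#'   a spot to be called positive (1 <= k_required <= length(genes)).
#' @param min_count minimum raw count for a gene to count as detected.
#' @return an object of class `gene_set_panel`.
#' @export
#' @examples
#' isg <- gene_set_panel("isg", c("IFIT1", "USP18", "MX1", "IFI27",
#'                                "IFI44L", "OAS1"))
#' isg
gene_set_panel <- function(name, genes, k_required = 1L, min_count = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(normalize_gene_symbols(genes))
  if (length(genes) == 0L) .stopf("panel '%s' has no genes", name)
  if (!.is_count(k_required, 1L) || k_required > length(genes))
    .stopf("panel '%s': k_required must be an integer in [1, %d]",
           name, length(genes))
  if (!.is_count(min_count, 1L))
    .stopf("panel '%s': min_count must be a positive integer", name)
  structure(list(name = name, genes = genes,
                 k_required = as.integer(k_required),
                 min_count = as.integer(min_count)),
            class = "gene_set_panel")
}

#' @export
print.gene_set_panel <- function(x, ...) {
  cat(sprintf("<gene_set_panel> %s: %s (>=%d gene(s) at count >= %d)\n",
              x$name, paste(x$genes, collapse = ", "),
              x$k_required, x$min_count))
  invisible(x)
}

#' Load gene-set panels from YAML
#'
#' Reads a YAML file mapping panel names to `genes` (list), optional
#' `k_required` and `min_count`.  With no `path`, the bundled default panels
#' are loaded: the six-gene ISG panel (IFIT1, USP18, MX1, IFI27, IFI44L,
#' OAS1), the apoptosis panel (CASP3, CASP8, BAX, BAK1, CYCS), necroptosis
#' (RIPK1, MLKL), the CD68 anchor, M1/M2 macrophage marker and cytokine
#' panels, and single-gene panels for IFNB1, ZBP1 and TGFB1.
#'
#' Published sources disagree on the M1/M2 marker orientation: the
#' immunohistochemistry convention treats CD16 (FCGR3A) as an M1 marker and
#' CD163 as M2, while some text passages swap the two pairs.
#' `m_orientation = "ihc"` (default) uses FCGR3A/FCGR1A as M1 and
#' CD163/ARG1 as M2; `"swapped"` reverses them.
#'
#' @param path YAML file; `NULL` for the bundled defaults.
#' @param m_orientation `"ihc"` or `"swapped"` (see Details).
#' @return named list of [gene_set_panel()] objects.
#' @export
load_panels <- function(path = NULL, m_orientation = c("ihc", "swapped")) {
  m_orientation <- match.arg(m_orientation)
  if (is.null(path))
    path <- system.file("extdata", "panels.yaml", package = "spotscore",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  panels <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    gene_set_panel(nm, unlist(p$genes),
                   k_required = p$k_required %||% 1L,
                   min_count = p$min_count %||% 1L)
  })
  names(panels) <- names(raw)
  if (m_orientation == "swapped" &&
      all(c("m1_markers", "m2_markers") %in% names(panels))) {
    g1 <- panels$m1_markers$genes
    g2 <- panels$m2_markers$genes
    panels$m1_markers <- gene_set_panel("m1_markers", g2)
    panels$m2_markers <- gene_set_panel("m2_markers", g1)
  }
  panels
}
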