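`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize gene symbols
#'
#' Uppercases symbols, strips surrounding whitespace, and maps common
#' protein-style aliases (as they appear in figure legends and panel
#' definitions) to HGNC symbols, e.g. `"TNFa"` to `TNF`, `"IL-1b"` to
#' `IL1B`, `"CD16"` to `FCGR3A`, `"TGFb"` to `TGFB1`.
#'
#' @param x character vector of gene names.
#' @return character vector of normalized HGNC-style symbols.
#' @export
#' @examples
#' normalize_gene_symbols(c("TNFa", "il-10", "CD16"))
normalize_gene_symbols <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- toupper(trimws(as.character(x)))
  # Greek letters as they survive text extraction
  x <- gsub("α|Α", "A", x)
  x <- gsub("β|Β", "B", x)
  hit <- match(x, names(.gene_aliases))
  x[!is.na(hit)] <- unname(.gene_aliases[hit[!is.na(hit)]])
  x
}

# protein-style name -> HGNC symbol (keys already uppercased, Greek mapped)
.gene_aliases <- c(
  "IL-1B"  = "IL1B",
  "IL1-B"  = "IL1B",
  "TNFA"   = "TNF",
  "TNF-A"  = "TNF",
  "IL-12"  = "IL12B",
  "IL12"   = "IL12B",
  "IL-18"  = "IL18",
  "IL-10"  = "IL10",
  "ARG"    = "ARG1",
  "TGFB"   = "TGFB1",
  "TGF-B"  = "TGFB1",
  "CD16"   = "FCGR3A",
  "CD64"   = "FCGR1A",
  "IFNB"   = "IFNB1"
)

# Case-insensitive match of panel genes against a gene universe.
# Returns the universe spelling for genes found; attribute "missing" lists
# the panel genes that are absent.
.match_genes <- function(genes, universe) {
  idx <- match(toupper(genes), toupper(universe))
  out <- universe[idx[!is.na(idx)]]
  attr(out, "missing") <- genes[is.na(idx)]
  out
}

.is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

.is_prop <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# md5 of an R object via its serialized JSON (stable across sessions for
# plain lists); used for the pipeline manifest.
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
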