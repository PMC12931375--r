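# Shared fixtures, built in code at test time.

# small but non-trivial simulated dataset (500 spots/sample)
small_sim <- function(seed = 42L, ...) {
  generate_dataset(sim_config(grid_rows = 20L, grid_cols = 25L,
                              n_background_genes = 100L, seed = seed, ...))
}

# tiny hand-written Space Ranger fixture: 2 genes x 3 spots,
# entries (g1,s1)=1, (g2,s2)=2
write_tiny_fixture <- function(dir, gzip = FALSE, old_dialect = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- function(lines, base) {
    path <- file.path(dir, if (gzip) paste0(base, ".gz") else base)
    con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con); close(con)
  }
  wl(c("%%MatrixMarket matrix coordinate integer general",
       "2 3 2", "1 1 1", "2 2 2"), "matrix.mtx")
  wl(c("ENSG01\tGENE1\tGene Expression",
       "ENSG02\tGENE2\tGene Expression"), "features.tsv")
  wl(c("BC1", "BC2", "BC3"), "barcodes.tsv")
  pos <- c("BC1,1,0,0,10,10", "BC2,1,0,2,10,20", "BC3,1,1,1,20,15")
  if (old_dialect) {
    writeLines(pos, file.path(dir, "tissue_positions_list.csv"))
  } else {
    writeLines(c(paste("barcode,in_tissue,array_row,array_col,",
                       "pxl_row_in_fullres,pxl_col_in_fullres", sep = ""),
                 pos),
               file.path(dir, "tissue_positions.csv"))
  }
  dir
}

# spot_matrix built directly from a dense count matrix
toy_sample <- function(counts, symbols = NULL, id = "toy") {
  symbols <- symbols %||% sprintf("G%d", seq_len(nrow(counts)))
  spot_matrix(counts,
              gene_ids = sprintf("ID%d", seq_len(nrow(counts))),
              gene_symbols = symbols,
              barcodes = sprintf("BC%d", seq_len(ncol(counts))),
              array_row = rep(0L, ncol(counts)),
              array_col = seq_len(ncol(counts)) - 1L,
              sample_id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force hypergeometric tail via direct pmf summation
brute_hyper_score <- function(k, m, n, N) {
  pmf <- function(i) choose(m, i) * choose(N - m, n - i) / choose(N, n)
  ks <- 0:min(m, n)
  if (k >= m * n / N) {
    p <- sum(vapply(ks[ks >= k], pmf, numeric(1)))
    -log10(max(p, 1e-300))
  } else {
    p <- sum(vapply(ks[ks <= k], pmf, numeric(1)))
    log10(max(p, 1e-300))
  }
}

# independent exact two-sided rank-sum p by complete enumeration
brute_ranksum_p <- function(x, y) {
  pool <- c(x, y); n1 <- length(x)
  r <- rank(pool)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pool), n1)
  stats <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- n1 * (length(pool) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}
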