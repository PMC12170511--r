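# Small-scale generator configurations and hand-built fixtures used across
# test files. Desk-scale dimensions keep unit tests fast; the acceptance
# suite exercises the full default configuration.

smallConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_rows = 16L, n_cols = 16L, n_genes = 400L,
               n_response_genes_tumor = 30L, n_response_genes_benign = 10L,
               n_subclones = 4L, depth_deep_mean = 20000,
               n_program_genes = 20L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(syntheticConfig, args)
}

# a bare rectangular one-slide hex grid as a plain data.frame
toyGrid <- function(n_rows, n_cols, slide = "s1", region = "tumor") {
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  j <- rep(seq_len(n_cols) - 1L, times = n_rows)
  col <- 2L * j + r %% 2L
  data.frame(barcode = sprintf("%s_R%dC%d", slide, r, col),
             slide_id = slide, array_row = r, array_col = col,
             in_tissue = TRUE, region = region, stringsAsFactors = FALSE)
}

# dense log-matrix fixture with named genes/spots
toyLogMatrix <- function(values, genes, spots) {
  m <- matrix(values, nrow = length(genes), ncol = length(spots),
              dimnames = list(genes, spots))
  Matrix::Matrix(m, sparse = TRUE)
}

# write a minimal MTX triplet to a temp dir; returns the dir
writeToyMtx <- function(entries, nGenes, nSpots,
                        genes = sprintf("G%d", seq_len(nGenes)),
                        barcodes = sprintf("BC%d", seq_len(nSpots)),
                        headerKind = "integer") {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general", headerKind),
               sprintf("%d %d %d", nGenes, nSpots, nrow(entries)),
               sprintf("%s %s %s", entries[, 1], entries[, 2], entries[, 3])),
             file.path(d, "matrix.mtx"))
  writeLines(genes, file.path(d, "features.tsv"))
  writeLines(barcodes, file.path(d, "barcodes.tsv"))
  d
}
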