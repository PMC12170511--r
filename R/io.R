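#' Read a 10x-style Matrix Market count triplet
#'
#' Reads `matrix.mtx` (coordinate format, 1-based indices) together with its
#' companion `features.tsv` and `barcodes.tsv` into a sparse gene-by-spot
#' count matrix. Validation is strict: header dimensions must match the
#' companion files and every entry must be a non-negative integer. Duplicate
#' gene symbols are disambiguated by suffixing (`make.unique`); if the
#' features file carries two or more columns the second is taken as the
#' symbol and the first (typically an Ensembl id) is attached as metadata.
#'
#' @param mtx_path path to the Matrix Market file.
#' @param features_path path to the gene list (TSV, no header).
#' @param barcodes_path path to the barcode list (TSV, no header).
#' @return A `dgCMatrix` with gene symbols as rownames and barcodes as
#'   colnames; attribute `gene_ids` holds the first features column when the
#'   file had several.
#' @export
readCounts <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  header <- readLines(mtx_path, n = 1L)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate\\s+(integer|real)\\s",
             header, ignore.case = TRUE))
    stopf("not a coordinate-format MatrixMarket file: %s", mtx_path)
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feat <- utils::read.table(features_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  bc <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")[[1L]]
  if (nrow(feat) != nrow(m))
    stopf("matrix declares %d genes but features file has %d",
          nrow(m), nrow(feat))
  if (length(bc) != ncol(m))
    stopf("matrix declares %d spots but barcodes file has %d",
          ncol(m), length(bc))
  if (length(m@x)) {
    if (any(m@x < 0)) stopf("negative count entries in %s", mtx_path)
    if (any(m@x != round(m@x)))
      stopf("non-integer count entries in %s", mtx_path)
  }
  symbols <- if (ncol(feat) >= 2L) feat[[2L]] else feat[[1L]]
  if (anyDuplicated(symbols)) {
    message(sprintf("%d duplicate gene symbol(s) disambiguated by suffixing",
                    sum(duplicated(symbols))))
    symbols <- make.unique(symbols)
  }
  if (anyDuplicated(bc)) stopf("duplicate barcodes in %s", barcodes_path)
  dimnames(m) <- list(symbols, bc)
  if (ncol(feat) >= 2L) attr(m, "gene_ids") <- feat[[1L]]
  m
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Emits `matrix.mtx` (coordinate integer, 1-based, column-major entry
#' order), `features.tsv` and `barcodes.tsv` under `dir_path`. Ordering is
#' deterministic so repeated writes are byte-identical.
#'
#' @param m gene-by-spot count matrix with dimnames.
#' @param dir_path output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeCounts <- function(m, dir_path) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("count matrix must carry gene rownames and spot colnames")
  if (anyDuplicated(rownames(m)))
    stopf("duplicate gene symbols: %s",
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m))) stopf("duplicate spot barcodes")
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory %s", dir_path)
  sm <- if (methods::is(m, "sparseMatrix")) methods::as(m, "CsparseMatrix")
        else drop0(Matrix::Matrix(m, sparse = TRUE))
  v <- sm@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stopf("counts must be non-negative integers")
  trip <- Matrix::summary(sm)  # column-major order by construction
  mtx <- file.path(dir_path, "matrix.mtx")
  con <- file(mtx, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(sm), ncol(sm), nrow(trip))), con)
  if (nrow(trip))
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  featp <- file.path(dir_path, "features.tsv")
  ids <- attr(m, "gene_ids")
  if (is.null(ids)) ids <- rownames(m)
  utils::write.table(
    data.frame(ids, rownames(m), "Gene Expression"), featp,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  bcp <- file.path(dir_path, "barcodes.tsv")
  writeLines(colnames(m), bcp)
  invisible(c(mtx, featp, bcp))
}

#' Read Visium spot positions (and optional region annotation)
#'
#' Reads a `tissue_positions.csv`-style table with columns `barcode`,
#' `in_tissue`, `array_row`, `array_col`, `slide_id`, validating the Visium
#' parity convention (`array_row` and `array_col` share parity). An optional
#' region table (`barcode`, `region`) is joined; barcodes without a region
#' entry become `unassigned`.
#'
#' @param csv_path positions CSV.
#' @param regions_path optional region CSV.
#' @return `data.frame` with columns `barcode`, `slide_id`, `array_row`,
#'   `array_col`, `in_tissue`, `region`.
#' @export
readPositions <- function(csv_path, regions_path = NULL) {
  if (!file.exists(csv_path)) stopf("file not found: %s", csv_path)
  pos <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  miss <- setdiff(POSITION_COLUMNS, colnames(pos))
  if (length(miss))
    stopf("positions file is missing column(s): %s", paste(miss, collapse = ", "))
  pos$array_row <- as.integer(pos$array_row)
  pos$array_col <- as.integer(pos$array_col)
  it <- pos$in_tissue
  if (is.character(it)) it <- toupper(trimws(it))
  itl <- rep(NA, length(it))
  itl[it %in% c("TRUE", "T", TRUE)] <- TRUE
  itl[it %in% c("FALSE", "F", FALSE)] <- FALSE
  num <- suppressWarnings(as.numeric(it))
  itl[is.na(itl) & !is.na(num)] <- num[is.na(itl) & !is.na(num)] != 0
  if (anyNA(itl)) stopf("in_tissue column is not interpretable as boolean")
  pos$in_tissue <- as.logical(itl)
  bad <- which(pos$array_row %% 2L != pos$array_col %% 2L)
  if (length(bad))
    stopf("array_row/array_col parity violated for barcode(s): %s",
          paste(utils::head(pos$barcode[bad], 5L), collapse = ", "))
  if (anyDuplicated(pos$barcode)) stopf("duplicate barcodes in %s", csv_path)
  key <- spotKey(pos$slide_id, pos$array_row, pos$array_col)
  if (anyDuplicated(key))
    stopf("duplicate (slide_id, array_row, array_col) positions in %s", csv_path)
  pos$region <- "unassigned"
  if (!is.null(regions_path)) {
    reg <- readRegions(regions_path)
    idx <- match(pos$barcode, reg$barcode)
    pos$region[!is.na(idx)] <- reg$region[idx[!is.na(idx)]]
  }
  pos[, c("barcode", "slide_id", "array_row", "array_col", "in_tissue", "region")]
}

#' Read a barcode-to-region annotation table
#' @param csv_path CSV with columns `barcode`, `region`.
#' @return `data.frame` with those two columns.
#' @export
readRegions <- function(csv_path) {
  if (!file.exists(csv_path)) stopf("file not found: %s", csv_path)
  reg <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "region") %in% colnames(reg)))
    stopf("regions file needs columns barcode, region")
  if (!all(reg$region %in% REGION_LEVELS))
    stopf("unknown region label(s): %s",
          paste(setdiff(unique(reg$region), REGION_LEVELS), collapse = ", "))
  reg[, c("barcode", "region")]
}

#' Write positions / regions tables
#' @param grid spot grid `data.frame` (see [spotGrid()]).
#' @param csv_path output path.
#' @return Invisibly, the path written.
#' @export
writePositions <- function(grid, csv_path) {
  utils::write.csv(
    data.frame(barcode = grid$barcode, in_tissue = as.integer(grid$in_tissue),
               array_row = grid$array_row, array_col = grid$array_col,
               slide_id = grid$slide_id),
    csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' @rdname writePositions
#' @export
writeRegions <- function(grid, csv_path) {
  utils::write.csv(data.frame(barcode = grid$barcode, region = grid$region),
                   csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Assemble a SpotExperiment from files on disk
#'
#' @param counts_dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param positions_path positions CSV.
#' @param regions_path optional regions CSV.
#' @return A [SpotExperiment-class].
#' @export
readSpotExperiment <- function(counts_dir, positions_path, regions_path = NULL) {
  m <- readCounts(file.path(counts_dir, "matrix.mtx"),
                  file.path(counts_dir, "features.tsv"),
                  file.path(counts_dir, "barcodes.tsv"))
  pos <- readPositions(positions_path, regions_path)
  SpotExperiment(m, pos)
}

#' Read / write marker panels as structured text (YAML)
#'
#' The on-disk form is one key per lineage mapping to a list of gene symbols.
#'
#' @param path YAML file path.
#' @return A [MarkerPanel-class].
#' @export
readMarkerPanel <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- yaml::read_yaml(path)
  MarkerPanel(lapply(raw, as.character))
}

#' @rdname readMarkerPanel
#' @param panel a [MarkerPanel-class].
#' @export
writeMarkerPanel <- function(panel, path) {
  yaml::write_yaml(panel@panels, path)
  invisible(path)
}

#' Write niche labels to CSV
#'
#' @param labels `data.frame` from [classifyNiche()] (columns `barcode`,
#'   `label`, `stratum`, optionally `score`).
#' @param csv_path output path.
#' @export
writeNicheLabels <- function(labels, csv_path) {
  utils::write.csv(labels, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Read niche labels written by [writeNicheLabels()]
#' @param csv_path path to the label CSV.
#' @export
readNicheLabels <- function(csv_path) {
  lab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "label", "stratum") %in% colnames(lab)))
    stopf("label file needs columns barcode, label, stratum")
  lab
}
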