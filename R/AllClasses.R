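#' @import methods
#' @importFrom Matrix colSums rowSums t drop0 sparseMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

REGION_LEVELS <- c("tumor", "benign", "unassigned")
POSITION_COLUMNS <- c("barcode", "in_tissue", "array_row", "array_col", "slide_id")

#' SpotExperiment: spot-level spatial expression container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' sparse non-negative integer spot-by-gene count matrix (genes in rows, one
#' column per Visium spot) together with the spatial substrate in `colData`:
#' `slide_id`, `array_row`, `array_col`, `in_tissue` and a `region` label
#' (`tumor`, `benign` or `unassigned`). Spots lie on the Visium hexagonal
#' lattice, where `array_row` and `array_col` share parity; the validity
#' method enforces this convention together with coordinate uniqueness and
#' count integrality.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("SpotExperiment", contains = "SummarizedExperiment")

setValidity("SpotExperiment", function(object) {
  msgs <- character()
  if (!"counts" %in% names(assays(object)))
    msgs <- c(msgs, "assay 'counts' is required")
  cd <- colData(object)
  need <- c("slide_id", "array_row", "array_col", "in_tissue", "region")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("colData is missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "spot ids (colnames) must be unique across slides")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene symbols (rownames) must be unique")
  key <- spotKey(cd$slide_id, cd$array_row, cd$array_col)
  if (anyDuplicated(key))
    msgs <- c(msgs, "(slide_id, array_row, array_col) must be unique")
  bad <- which(cd$array_row %% 2L != cd$array_col %% 2L)
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "array_row/array_col parity violated for spot(s): %s",
      paste(utils::head(colnames(object)[bad], 5L), collapse = ", ")))
  if (any(cd$array_row < 0) || any(cd$array_col < 0))
    msgs <- c(msgs, "array coordinates must be non-negative")
  if (!all(cd$region %in% REGION_LEVELS))
    msgs <- c(msgs, "region must be one of tumor/benign/unassigned")
  if ("counts" %in% names(assays(object))) {
    v <- countValues(assay(object, "counts"))
    if (length(v) && (any(v < 0) || any(v != round(v))))
      msgs <- c(msgs, "counts must be non-negative integers")
  }
  if (length(msgs)) msgs else TRUE
})

# nonzero values of a (possibly sparse) count matrix
countValues <- function(m) {
  if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
}

#' Construct a SpotExperiment
#'
#' @param counts gene-by-spot matrix (dense or [Matrix::sparseMatrix]) of
#'   non-negative integer counts, with gene symbols as rownames and spot
#'   barcodes as colnames.
#' @param positions `data.frame` of spot positions with columns `barcode`,
#'   `in_tissue`, `array_row`, `array_col`, `slide_id` and optionally
#'   `region`; rows are matched to `colnames(counts)` by barcode.
#' @param metadata optional list stored as object metadata.
#' @return A [SpotExperiment-class] object.
#' @examples
#' grid <- generateGrid(syntheticConfig(n_rows = 4, n_cols = 4, slides = 1))
#' counts <- Matrix::Matrix(0L, 3, nrow(grid), sparse = TRUE,
#'                          dimnames = list(paste0("G", 1:3), grid$barcode))
#' se <- SpotExperiment(counts, grid)
#' @export
SpotExperiment <- function(counts, positions, metadata = list()) {
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stopf("counts must carry gene rownames and spot colnames")
  positions <- as.data.frame(positions)
  miss <- setdiff(POSITION_COLUMNS, colnames(positions))
  if (length(miss))
    stopf("positions is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"region" %in% colnames(positions)) positions$region <- "unassigned"
  idx <- match(colnames(counts), positions$barcode)
  if (anyNA(idx))
    stopf("positions lack %d barcode(s) present in counts (e.g. %s)",
          sum(is.na(idx)), colnames(counts)[which(is.na(idx))[1L]])
  positions <- positions[idx, , drop = FALSE]
  cd <- DataFrame(
    slide_id  = as.character(positions$slide_id),
    array_row = as.integer(positions$array_row),
    array_col = as.integer(positions$array_col),
    in_tissue = as.logical(positions$in_tissue),
    region    = as.character(positions$region),
    row.names = colnames(counts))
  if (!methods::is(counts, "sparseMatrix"))
    counts <- drop0(Matrix::Matrix(counts, sparse = TRUE))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = metadata)
  methods::validObject(obj <- methods::new("SpotExperiment", se))
  obj
}

#' @describeIn SpotExperiment raw count assay.
#' @param x,object a `SpotExperiment`.
#' @export
spotCounts <- function(x) assay(x, "counts")

#' @describeIn SpotExperiment log-normalized assay (after [normalizeCounts()]).
#' @export
logCounts <- function(x) {
  if (!"logcounts" %in% names(assays(x)))
    stopf("no 'logcounts' assay; run normalizeCounts() first")
  assay(x, "logcounts")
}

#' @describeIn SpotExperiment the spatial substrate as a plain `data.frame`
#'   with columns `barcode`, `slide_id`, `array_row`, `array_col`,
#'   `in_tissue`, `region`.
#' @export
spotGrid <- function(x) {
  cd <- colData(x)
  data.frame(barcode = rownames(cd), slide_id = cd$slide_id,
             array_row = cd$array_row, array_col = cd$array_col,
             in_tissue = cd$in_tissue, region = cd$region,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @describeIn SpotExperiment barcodes of spots flagged `in_tissue` — the
#'   spots every analysis operation works on.
#' @export
analyzedSpots <- function(x) colnames(x)[colData(x)$in_tissue]

#' @describeIn SpotExperiment per-spot region labels, named by barcode.
#' @export
spotRegions <- function(x) stats::setNames(colData(x)$region, colnames(x))

setMethod("show", "SpotExperiment", function(object) {
  methods::callNextMethod()
  cd <- colData(object)
  cat(sprintf("slides: %s\n", paste(unique(cd$slide_id), collapse = ", ")))
  cat(sprintf("in-tissue spots: %d | regions: %s\n", sum(cd$in_tissue),
              paste(sprintf("%s=%d", names(table(cd$region)),
                            table(cd$region)), collapse = " ")))
})

# ---------------------------------------------------------------------------

#' MarkerPanel: immune lineages mapped to marker gene symbols
#'
#' Named lists of gene symbols, one entry per immune lineage. Spot scoring
#' ([markerScore()]) averages log-normalized expression over the union of all
#' lineages, so symbols must be unique across the whole panel.
#'
#' @slot panels named list of character vectors (lineage -> symbols).
#' @export
setClass("MarkerPanel", representation(panels = "list"))

setValidity("MarkerPanel", function(object) {
  p <- object@panels
  if (!length(p)) return("panel must contain at least one lineage")
  if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
    return("lineage names must be unique and non-empty")
  if (!all(vapply(p, is.character, logical(1L))))
    return("each lineage must be a character vector of gene symbols")
  u <- unlist(p, use.names = FALSE)
  if (anyDuplicated(u))
    return(paste0("gene symbols duplicated across the panel: ",
                  paste(unique(u[duplicated(u)]), collapse = ", ")))
  TRUE
})

#' @describeIn MarkerPanel-class constructor from a named list.
#' @param panels named list, lineage name -> character vector of symbols.
#' @export
MarkerPanel <- function(panels) {
  methods::validObject(obj <- methods::new("MarkerPanel", panels = panels))
  obj
}

#' @describeIn MarkerPanel-class the canonical 23-gene liver immune panel:
#'   Kupffer (CD68, CD163, LYZ, C1QA, AIF1), T (CD3D, CD2, IL7R, TRBC2, CD69),
#'   B/Plasma (IGKC, JCHAIN, CD79A, CD27, CD74) and NK/other (CD4, CD8A,
#'   ITGAM, NKG7, KLRD1, PRF1, CD7, TRDC).
#' @export
defaultMarkerPanel <- function() {
  MarkerPanel(list(
    Kupffer    = c("CD68", "CD163", "LYZ", "C1QA", "AIF1"),
    T          = c("CD3D", "CD2", "IL7R", "TRBC2", "CD69"),
    B_Plasma   = c("IGKC", "JCHAIN", "CD79A", "CD27", "CD74"),
    NK_other   = c("CD4", "CD8A", "ITGAM", "NKG7", "KLRD1", "PRF1", "CD7", "TRDC")))
}

#' @describeIn MarkerPanel-class union of all lineage symbols, in panel order.
#' @param x a `MarkerPanel`.
#' @export
panelGenes <- function(x) unlist(x@panels, use.names = FALSE)

#' @describeIn MarkerPanel-class lineage names.
#' @export
lineages <- function(x) names(x@panels)

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel with %d lineages, %d genes\n",
              length(object@panels), length(panelGenes(object))))
  for (nm in names(object@panels))
    cat(sprintf("  %s: %s\n", nm, paste(object@panels[[nm]], collapse = ", ")))
})
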