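#' Score spots against an immune marker panel
#'
#' The score of a spot is the arithmetic mean of its log-normalized
#' expression over the panel genes present in the matrix. Panel genes absent
#' from the matrix shrink the denominator (they are excluded, not counted as
#' zero); if fewer than `minCoverage` of the panel union is present the call
#' fails, naming the missing symbols.
#'
#' @param x a [SpotExperiment-class] with a `logcounts` assay, or a
#'   log-normalized gene-by-spot matrix.
#' @param panel a [MarkerPanel-class].
#' @param minCoverage minimum fraction of the panel union that must be
#'   present (default 0.5).
#' @return Named numeric vector of scores, one per (in-tissue) spot.
#' @export
markerScore <- function(x, panel = defaultMarkerPanel(), minCoverage = 0.5) {
  stopifnot(methods::is(panel, "MarkerPanel"),
            isFraction(minCoverage, openLeft = TRUE))
  lm <- if (methods::is(x, "SpotExperiment")) {
    logCounts(x)[, analyzedSpots(x), drop = FALSE]
  } else x
  union <- panelGenes(panel)
  present <- intersect(union, rownames(lm))
  if (length(present) / length(union) < minCoverage)
    stopf("only %d/%d panel genes present (below coverage %.2f); missing: %s",
          length(present), length(union), minCoverage,
          paste(setdiff(union, rownames(lm)), collapse = ", "))
  if (length(present) < length(union))
    message(sprintf("%d panel gene(s) absent from matrix; averaging over %d",
                    length(union) - length(present), length(present)))
  Matrix::colSums(lm[present, , drop = FALSE]) / length(present)
}

#' Call immune cell-enriched spots
#'
#' A spot is immune cell-enriched when its marker score is strictly greater
#' than `threshold` (default 0.9 on the log-normalized scale).
#'
#' @param scores named numeric vector from [markerScore()].
#' @param threshold calling threshold; strict inequality.
#' @return Character vector of immune spot barcodes.
#' @export
callImmuneSpots <- function(scores, threshold = 0.9) {
  if (any(!is.finite(scores))) stopf("scores must be finite")
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  names(scores)[scores > threshold]
}

# internal: barcodes of hex neighbors for every spot key ---------------------
HEX_OFFSETS <- cbind(dr = c(0L, 0L, -1L, -1L, 1L, 1L),
                     dc = c(-2L, 2L, -1L, 1L, -1L, 1L))

# n x 6 integer matrix of hex-neighbor row indices (NA where no spot exists)
hexAdjacencyIndex <- function(grid) {
  keys <- spotKey(grid$slide_id, grid$array_row, grid$array_col)
  out <- matrix(NA_integer_, nrow(grid), nrow(HEX_OFFSETS))
  for (k in seq_len(nrow(HEX_OFFSETS))) {
    nk <- spotKey(grid$slide_id,
                  grid$array_row + HEX_OFFSETS[k, "dr"],
                  grid$array_col + HEX_OFFSETS[k, "dc"])
    out[, k] <- match(nk, keys)
  }
  out
}

# For a set of spots (rows of grid indexed by `idx`), return a logical flag
# over all grid rows marking spots having >= 1 hex neighbor inside `idx`.
hexNeighborFlag <- function(grid, idx) {
  keys <- spotKey(grid$slide_id, grid$array_row, grid$array_col)
  flag <- logical(nrow(grid))
  for (k in seq_len(nrow(HEX_OFFSETS))) {
    nk <- spotKey(grid$slide_id[idx],
                  grid$array_row[idx] + HEX_OFFSETS[k, "dr"],
                  grid$array_col[idx] + HEX_OFFSETS[k, "dc"])
    flag[match(nk, keys, nomatch = 0L)] <- TRUE
  }
  flag
}

#' Hexagonal neighbors of a spot
#'
#' On the Visium lattice (row and column share parity) the six contact
#' neighbors of `(r, c)` sit at offsets `(0, +/-2)`, `(+1, +/-1)` and
#' `(-1, +/-1)` on the same slide; only positions occupied by a spot are
#' returned, so edge spots have fewer than six.
#'
#' @param grid spot grid `data.frame` (see [spotGrid()]) or a
#'   [SpotExperiment-class].
#' @param spot barcode of the query spot.
#' @return Character vector of neighbor barcodes (possibly empty).
#' @export
hexNeighbors <- function(grid, spot) {
  if (methods::is(grid, "SpotExperiment")) grid <- spotGrid(grid)
  i <- match(spot, grid$barcode)
  if (is.na(i)) stopf("unknown spot: %s", spot)
  keys <- spotKey(grid$slide_id, grid$array_row, grid$array_col)
  nk <- spotKey(grid$slide_id[i],
                grid$array_row[i] + HEX_OFFSETS[, "dr"],
                grid$array_col[i] + HEX_OFFSETS[, "dc"])
  grid$barcode[stats::na.omit(match(nk, keys))]
}

#' Classify spots into immune / adjacent / away niches
#'
#' Every analyzed (in-tissue) spot receives exactly one label: `immune` if it
#' is in the immune set; else `adjacent` if at least one of its six hex
#' neighbors is immune; else `away`. Immune precedence means two immune
#' spots touching each other both stay `immune`. The region label (tumor /
#' benign) is carried alongside as the stratum.
#'
#' @param grid spot grid `data.frame` or [SpotExperiment-class]; out-of-tissue
#'   spots are dropped.
#' @param immune character vector of immune spot barcodes (subset of the
#'   grid).
#' @param scores optional named score vector to carry into the output.
#' @return `data.frame` with columns `barcode`, `label`, `stratum` and, when
#'   `scores` is given, `score`.
#' @export
classifyNiche <- function(grid, immune, scores = NULL) {
  if (methods::is(grid, "SpotExperiment")) grid <- spotGrid(grid)
  grid <- grid[grid$in_tissue, , drop = FALSE]
  unknown <- setdiff(immune, grid$barcode)
  if (length(unknown))
    stopf("immune set contains unknown or out-of-tissue spot(s): %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  isImm <- grid$barcode %in% immune
  touch <- hexNeighborFlag(grid, which(isImm))
  label <- ifelse(isImm, "immune", ifelse(touch, "adjacent", "away"))
  out <- data.frame(barcode = grid$barcode, label = label,
                    stratum = grid$region, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(scores)) out$score <- unname(scores[out$barcode])
  out
}

#' Build the three niche contrasts
#'
#' The canonical comparisons are (1) tumor spots adjacent to immune spots
#' versus tumor spots away from them, (2) the same within the benign region,
#' and (3) tumor-adjacent versus benign-adjacent spots. Immune spots are
#' excluded from every group.
#'
#' @param labels `data.frame` from [classifyNiche()].
#' @param strict if `TRUE` (default), an empty required group is an error; if
#'   `FALSE`, contrasts that cannot be built are dropped with a warning and
#'   the rest returned.
#' @return Named list of contrasts; each contrast is a list with elements
#'   `name`, `group1`, `group2` (barcode vectors).
#' @export
buildContrasts <- function(labels, strict = TRUE) {
  pick <- function(lab, strat)
    labels$barcode[labels$label == lab & labels$stratum == strat]
  defs <- list(
    tumor_adjacent_vs_away =
      list(g1 = pick("adjacent", "tumor"), g2 = pick("away", "tumor")),
    benign_adjacent_vs_away =
      list(g1 = pick("adjacent", "benign"), g2 = pick("away", "benign")),
    tumor_adjacent_vs_benign_adjacent =
      list(g1 = pick("adjacent", "tumor"), g2 = pick("adjacent", "benign")))
  out <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (!length(d$g1) || !length(d$g2)) {
      msg <- sprintf("contrast '%s' has an empty group", nm)
      if (strict) stopf("%s", msg)
      warning(msg, call. = FALSE)
      next
    }
    out[[nm]] <- list(name = nm, group1 = d$g1, group2 = d$g2)
  }
  out
}
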