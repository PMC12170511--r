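#' Log-normalize counts
#'
#' Deterministic log-CP10K normalization: each count is scaled by its spot's
#' total, multiplied by `scaleFactor` (default 10,000) and transformed as
#' `log1p`, i.e. `value = ln(1 + count * scaleFactor / spot_total)`. Zeros
#' stay zero; within a spot the map is strictly monotone in the raw count and
#' invariant to multiplying all of the spot's counts by a constant.
#'
#' @param x a [SpotExperiment-class] or a gene-by-spot count matrix.
#' @param scaleFactor positive scale constant (counts per `scaleFactor`).
#' @return For a `SpotExperiment`, the object with a `logcounts` assay added;
#'   for a matrix, the sparse log-normalized matrix.
#' @details Spots flagged out-of-tissue are carried through untouched (their
#'   columns are normalized only when their total is positive); analysis
#'   operations ignore them. An in-tissue spot with zero total is an error,
#'   listing the offending barcodes.
#' @examples
#' cfg <- syntheticConfig(n_rows = 6, n_cols = 6, slides = 1, n_genes = 50,
#'                        n_marker_genes = 5, depth_deep_mean = 500)
#' se <- normalizeCounts(simulateDataset(cfg))
#' @export
normalizeCounts <- function(x, scaleFactor = 1e4) {
  stopifnot(is.numeric(scaleFactor), scaleFactor > 0)
  if (methods::is(x, "SpotExperiment")) {
    m <- spotCounts(x)
    tot <- Matrix::colSums(m)
    zero <- colnames(x)[tot == 0 & colData(x)$in_tissue]
    if (length(zero))
      stopf("in-tissue spot(s) with zero total count: %s",
            paste(utils::head(zero, 5L), collapse = ", "))
    assays(x)$logcounts <- .logNorm(m, tot, scaleFactor)
    return(x)
  }
  tot <- Matrix::colSums(x)
  if (any(tot == 0))
    stopf("spot(s) with zero total count: %s",
          paste(utils::head(colnames(x)[tot == 0], 5L), collapse = ", "))
  .logNorm(x, tot, scaleFactor)
}

#' @importFrom SummarizedExperiment assays<-
.logNorm <- function(m, tot, scaleFactor) {
  sm <- if (methods::is(m, "CsparseMatrix")) m else
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  fac <- ifelse(tot > 0, scaleFactor / tot, 0)
  out <- sm
  out@x <- log1p(sm@x * rep.int(fac, diff(sm@p)))
  out
}

#' Rank highly variable genes by binned standardized dispersion
#'
#' Genes are ranked the way early single-cell toolkits did it: per gene, the
#' mean and the dispersion (variance/mean) of the de-logged normalized values
#' are computed; genes are cut into `nBins` equal-occupancy bins by mean, the
#' dispersion is z-scored within each bin, and genes are ordered by that
#' z-score. Genes with zero dispersion (constant or all-zero) always rank
#' last; remaining ties break by gene symbol so the ranking is deterministic.
#'
#' @param x a [SpotExperiment-class] (normalized or not; normalization is
#'   applied internally when missing) or a raw count matrix.
#' @param n number of genes to return (default 3000). If `n` exceeds the gene
#'   count, all genes are returned with a warning.
#' @param nBins number of equal-occupancy mean bins (default 20).
#' @param scaleFactor passed to [normalizeCounts()] when needed.
#' @return Character vector of gene symbols, ranked most to least variable.
#' @export
selectHVG <- function(x, n = 3000, nBins = 20, scaleFactor = 1e4) {
  stopifnot(isCount(n))
  m <- if (methods::is(x, "SpotExperiment"))
    spotCounts(x)[, analyzedSpots(x), drop = FALSE] else x
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stopf("spot(s) with zero total count: %s",
          paste(utils::head(colnames(m)[tot == 0], 5L), collapse = ", "))
  sm <- if (methods::is(m, "CsparseMatrix")) m else
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  nm <- sm
  nm@x <- sm@x * rep.int(scaleFactor / tot, diff(sm@p))
  stat <- .hvgCore(nm, nBins = nBins)
  if (n > nrow(stat)) {
    warning(sprintf("requested %d HVGs but only %d genes present; returning all",
                    n, nrow(stat)))
    n <- nrow(stat)
  }
  stat$gene[seq_len(n)]
}

#' Dispersion statistics behind [selectHVG()]
#'
#' @param lm log-normalized gene-by-spot matrix (values are de-logged
#'   internally, recovering the normalized counts).
#' @param nBins number of equal-occupancy mean bins.
#' @return `data.frame` (gene, mean, dispersion, bin, z, rank), ordered by
#'   rank.
#' @export
hvgStatistics <- function(lm, nBins = 20) {
  dl <- lm
  if (methods::is(dl, "sparseMatrix")) dl@x <- expm1(dl@x) else dl <- expm1(dl)
  .hvgCore(dl, nBins = nBins)
}

# Core ranking on normalized (de-logged) values. Two numerical guards keep
# the ranking deterministic across algebraically equivalent evaluation
# orders: variances below 1e-10 of mean^2 count as zero (a constant gene
# computed in one pass picks up ~1e-15 relative noise), and z-scores are
# snapped to 10 significant digits before ordering so exact cross-bin z ties
# break by gene symbol, not by floating-point dust.
.hvgCore <- function(dl, nBins = 20) {
  nG <- nrow(dl)
  nS <- ncol(dl)
  mu <- Matrix::rowSums(dl) / nS
  ex2 <- Matrix::rowSums(dl^2) / nS
  vv <- pmax(0, (ex2 - mu^2) * nS / max(1, nS - 1))
  vv[vv < mu^2 * 1e-10] <- 0
  disp <- ifelse(mu > 0, vv / mu, 0)
  genes <- rownames(dl)
  nb <- max(1L, min(as.integer(nBins), nG))
  ord <- order(mu, genes, method = "radix")
  bin <- integer(nG)
  bin[ord] <- ceiling(seq_len(nG) * nb / nG)
  z <- numeric(nG)
  for (b in unique(bin)) {
    i <- bin == b
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  z[disp == 0] <- -Inf  # constant / undetected genes rank last
  z <- signif(z, 10)
  rk <- order(-z, genes, method = "radix")
  out <- data.frame(gene = genes, mean = mu, dispersion = disp,
                    bin = bin, z = z, stringsAsFactors = FALSE)[rk, ]
  out$rank <- seq_len(nG)
  rownames(out) <- NULL
  out
}

#' Per-gene detection rates over a spot subset
#'
#' For every gene, the number and fraction of the given spots with at least
#' one count.
#'
#' @param x a [SpotExperiment-class] or gene-by-spot count matrix.
#' @param spots barcodes to analyze; defaults to all in-tissue spots for a
#'   `SpotExperiment`, all columns for a matrix.
#' @return `data.frame` with columns `gene`, `n_spots_detected`,
#'   `pct_detected` (a fraction in \[0,1\]).
#' @export
detectionRates <- function(x, spots = NULL) {
  m <- if (methods::is(x, "SpotExperiment")) spotCounts(x) else x
  if (is.null(spots))
    spots <- if (methods::is(x, "SpotExperiment")) analyzedSpots(x) else colnames(m)
  if (!length(spots)) stopf("spot subset is empty")
  missing <- setdiff(spots, colnames(m))
  if (length(missing))
    stopf("unknown spot(s): %s", paste(utils::head(missing, 5L), collapse = ", "))
  sub <- m[, spots, drop = FALSE]
  det <- Matrix::rowSums(sub > 0)
  data.frame(gene = rownames(m), n_spots_detected = as.integer(det),
             pct_detected = det / length(spots), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a detection table or HVG ranking to TSV
#' @param tab `data.frame` to serialize.
#' @param path output path.
#' @export
writeTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
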