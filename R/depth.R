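#' Binomial thinning of counts to a lower sequencing depth
#'
#' Each count is replaced by a Binomial(count, rate) draw, which emulates
#' resequencing the same library at `rate` times the depth while preserving
#' relative abundances (a Poisson gene stays Poisson with mean scaled by the
#' rate). Alternatively a `targetMeanDepth` may be given, from which the rate
#' is computed as target / current mean depth over analyzed spots.
#'
#' @param x a [SpotExperiment-class] or a gene-by-spot count matrix.
#' @param rate thinning probability in (0, 1].
#' @param targetMeanDepth target mean library size; must not exceed the
#'   current mean depth.
#' @param seed integer seed; thinning is reproducible given the seed.
#' @return Object of the same type as `x` with thinned counts (a
#'   `SpotExperiment` keeps its colData and metadata; any `logcounts` assay
#'   is dropped since it no longer matches).
#' @export
thinCounts <- function(x, rate = NULL, targetMeanDepth = NULL, seed = 0L) {
  m <- if (methods::is(x, "SpotExperiment")) spotCounts(x) else x
  if (is.null(rate) == is.null(targetMeanDepth))
    stopf("give exactly one of rate or targetMeanDepth")
  if (!is.null(targetMeanDepth)) {
    cols <- if (methods::is(x, "SpotExperiment")) analyzedSpots(x) else colnames(m)
    cur <- mean(Matrix::colSums(m[, cols, drop = FALSE]))
    if (targetMeanDepth > cur)
      stopf("targetMeanDepth (%.0f) exceeds current mean depth (%.0f)",
            targetMeanDepth, cur)
    rate <- targetMeanDepth / cur
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1)
    stopf("rate must lie in (0, 1]")
  if (rate == 1) return(x)
  sm <- if (methods::is(m, "CsparseMatrix")) m else
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  thinned <- sm
  thinned@x <- withSeed(seed,
    as.numeric(stats::rbinom(length(sm@x), size = as.integer(sm@x), prob = rate)))
  thinned <- Matrix::drop0(thinned)
  if (methods::is(x, "SpotExperiment")) {
    out <- SpotExperiment(thinned, spotGrid(x), metadata = metadata(x))
    return(out)
  }
  if (methods::is(m, "CsparseMatrix")) thinned else as.matrix(thinned)
}

#' Match gene universes of two detection tables
#'
#' @param deep,standard detection tables from [detectionRates()].
#' @return Character vector of shared gene symbols, with attributes
#'   `only_deep` and `only_standard` listing the unmatched genes.
#' @export
matchGenes <- function(deep, standard) {
  shared <- intersect(deep$gene, standard$gene)
  if (!length(shared)) stopf("no genes shared between the two tables")
  structure(shared,
            only_deep = setdiff(deep$gene, standard$gene),
            only_standard = setdiff(standard$gene, deep$gene))
}

#' Per-gene detection change between depth regimes
#'
#' For every matched gene the difference in detection fraction
#' (`delta = pct_deep - pct_standard`) is computed; a gene counts as
#' "increased in deep" only when the delta is strictly positive. A global
#' two-sample Kolmogorov-Smirnov test compares the two per-gene
#' detection-rate distributions.
#'
#' @param deep,standard detection tables from [detectionRates()].
#' @param matched optional matched gene list (defaults to
#'   [matchGenes()] of the two tables).
#' @return List with `table` (per-gene data.frame), `summary`
#'   (`n_genes_matched`, `n_increased_in_deep`, `fraction_increased`) and
#'   `ks` (`D`, `p`).
#' @export
detectionDelta <- function(deep, standard, matched = NULL) {
  if (is.null(matched)) matched <- matchGenes(deep, standard)
  if (!length(matched)) stopf("matched gene list is empty")
  pd <- deep$pct_detected[match(matched, deep$gene)]
  ps <- standard$pct_detected[match(matched, standard$gene)]
  delta <- pd - ps
  ks <- ksTwoSample(pd, ps)
  list(table = data.frame(gene = matched, pct_deep = pd, pct_standard = ps,
                          delta = delta, stringsAsFactors = FALSE),
       summary = list(n_genes_matched = length(matched),
                      n_increased_in_deep = sum(delta > 0),
                      fraction_increased = sum(delta > 0) / length(matched)),
       ks = ks)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the exact supremum distance between the two empirical
#' CDFs (computed over the pooled support); the p-value comes from the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples (each non-empty).
#' @return List with `D` and `p`.
#' @export
ksTwoSample <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) stopf("both samples must be non-empty")
  u <- sort(unique(c(a, b)))
  Fa <- findInterval(u, sort(a)) / na
  Fb <- findInterval(u, sort(b)) / nb
  D <- max(abs(Fa - Fb))
  ne <- na * nb / (na + nb)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(1, max(p, .Machine$double.xmin)))
}
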