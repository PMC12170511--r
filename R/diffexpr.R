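#' Differential-expression configuration
#'
#' @param min_pct minimum detection fraction required in at least one group
#'   (default 0.10).
#' @param lfc_min minimum absolute log2 fold change (default 0.25).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param pseudocount pseudocount added to de-logged group means in the fold
#'   change (default 1).
#' @return A list of class `DEConfig`.
#' @export
deConfig <- function(min_pct = 0.10, lfc_min = 0.25, alpha = 0.05,
                     pseudocount = 1.0) {
  stopifnot(isFraction(min_pct), is.numeric(lfc_min), lfc_min >= 0,
            isFraction(alpha, openLeft = TRUE, openRight = TRUE),
            is.numeric(pseudocount), pseudocount >= 0)
  structure(list(min_pct = min_pct, lfc_min = lfc_min, alpha = alpha,
                 pseudocount = pseudocount), class = "DEConfig")
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic with average ranks for ties and a
#' two-sided p-value from the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction. When every pooled value is tied
#' the variance is zero and p = 1 by convention.
#'
#' @param x,y numeric samples, each of length >= 3.
#' @return List with elements `U` (statistic for `x`) and `p` in (0, 1].
#' @export
rankSumTest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3L || n2 < 3L)
    stopf("each group needs at least 3 observations (got %d and %d)", n1, n2)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1))
  mu <- n1 * n2 / 2
  dev <- U - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j : p_(j) >= p_(i)} p_(j) * m / j`, capped at 1. The
#' adjustment is monotone: ordering by p orders q non-decreasingly.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Log2 fold change on de-logged means
#'
#' `log2((mean(expm1(v1)) + pc) / (mean(expm1(v2)) + pc))`: testing happens
#' on the log-normalized scale, but the effect size is reported on de-logged
#' (normalized-count) means, stabilised by a pseudocount.
#'
#' @param v1,v2 log-normalized values for the two groups.
#' @param pseudocount stabiliser added to both means.
#' @return Scalar log2 fold change (positive when group 1 is higher).
#' @export
log2FoldChange <- function(v1, v2, pseudocount = 1.0) {
  if (!length(v1) || !length(v2)) stopf("empty group")
  log2((mean(expm1(v1)) + pseudocount) / (mean(expm1(v2)) + pseudocount))
}

#' Two-group differential expression for one contrast
#'
#' Genes failing the detection filter (`min_pct` in both groups) are skipped
#' before testing; the rank-sum test runs per remaining gene on
#' log-normalized values; BH adjustment is computed over tested genes only.
#' A gene is `significant` when `q < alpha`, `|log2fc| >= lfc_min` and its
#' best detection fraction reaches `min_pct`.
#'
#' @param x a [SpotExperiment-class] with `logcounts`, or a log-normalized
#'   gene-by-spot matrix.
#' @param contrast list with `group1`, `group2` barcode vectors (see
#'   [buildContrasts()]); groups must be disjoint, each >= 3 spots.
#' @param config a [deConfig()].
#' @return `data.frame` with one row per gene: `gene`, `log2fc`, `p`, `q`,
#'   `pct_group1`, `pct_group2`, `tested`, `significant`. Untested genes have
#'   `NA` p/q and `significant = FALSE`.
#' @export
deAnalysis <- function(x, contrast, config = deConfig()) {
  stopifnot(inherits(config, "DEConfig"))
  lm <- if (methods::is(x, "SpotExperiment")) logCounts(x) else x
  g1 <- contrast$group1; g2 <- contrast$group2
  if (length(intersect(g1, g2)))
    stopf("contrast groups overlap (%d shared spots)", length(intersect(g1, g2)))
  if (length(g1) < 3L || length(g2) < 3L)
    stopf("each contrast group needs >= 3 spots (got %d and %d)",
          length(g1), length(g2))
  missing <- setdiff(c(g1, g2), colnames(lm))
  if (length(missing))
    stopf("unknown spot(s) in contrast: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  m1 <- lm[, g1, drop = FALSE]
  m2 <- lm[, g2, drop = FALSE]
  pct1 <- Matrix::rowSums(m1 > 0) / length(g1)
  pct2 <- Matrix::rowSums(m2 > 0) / length(g2)
  tested <- pmax(pct1, pct2) >= config$min_pct
  genes <- rownames(lm)
  n <- length(genes)
  pv <- rep(NA_real_, n)
  lfc <- rep(NA_real_, n)
  d1 <- as.matrix(m1[tested, , drop = FALSE])
  d2 <- as.matrix(m2[tested, , drop = FALSE])
  ti <- which(tested)
  mu1 <- rowMeans(expm1(d1))
  mu2 <- rowMeans(expm1(d2))
  lfc[ti] <- log2((mu1 + config$pseudocount) / (mu2 + config$pseudocount))
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  muU <- n1 * n2 / 2
  for (k in seq_along(ti)) {
    r <- rank(c(d1[k, ], d2[k, ]))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    # tie-group sizes: tied values share one (half-integer) average rank
    cnt <- tabulate(as.integer(2 * r), nbins = 2L * N)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(cnt^3 - cnt) / (N * (N - 1)))
    if (sigma2 <= 0) { pv[ti[k]] <- 1; next }
    dev <- U - muU
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    pv[ti[k]] <- max(min(1, 2 * stats::pnorm(-abs(z))), .Machine$double.xmin)
  }
  qv <- rep(NA_real_, n)
  if (length(ti)) qv[ti] <- bhAdjust(pv[ti])
  sig <- !is.na(qv) & qv < config$alpha & abs(lfc) >= config$lfc_min &
    pmax(pct1, pct2) >= config$min_pct
  data.frame(gene = genes, log2fc = lfc, p = pv, q = qv,
             pct_group1 = pct1, pct_group2 = pct2,
             tested = tested, significant = sig,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen DE genes against the highly variable gene list
#'
#' @param deGenes character vector of differentially expressed genes.
#' @param hvg ordered HVG list from [selectHVG()].
#' @param mode `"intersect"` (default, the restrictive reading) or
#'   `"union"`.
#' @return Character vector of screened genes.
#' @export
screenWithHVG <- function(deGenes, hvg, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  if (mode == "intersect") intersect(deGenes, hvg) else union(deGenes, hvg)
}

#' Compare two gene sets
#'
#' @param setA,setB character vectors.
#' @return List with `unique_to_A`, `shared`, `unique_to_B` plus a `counts`
#'   list (including `fraction_A_unique`, `fraction_B_unique`).
#' @export
compareGeneSets <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- intersect(setA, setB)
  ua <- setdiff(setA, setB)
  ub <- setdiff(setB, setA)
  list(unique_to_A = ua, shared = shared, unique_to_B = ub,
       counts = list(
         n_A = length(setA), n_B = length(setB),
         n_unique_to_A = length(ua), n_shared = length(shared),
         n_unique_to_B = length(ub),
         fraction_A_unique = if (length(setA)) length(ua) / length(setA) else 0,
         fraction_B_unique = if (length(setB)) length(ub) / length(setB) else 0))
}

#' Write a DE result table to TSV
#' @param de `data.frame` from [deAnalysis()].
#' @param path output path.
#' @export
writeDEResult <- function(de, path) writeTable(de, path)
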