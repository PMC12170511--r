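# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition, by enumeration where feasible, and share no
# code with the implementation they check.

# exhaustive two-sided permutation p-value for the rank-sum statistic
oracleRankSumP <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  mu <- n1 * n2 / 2
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(uOf(seq_len(n1)) - mu)
  cmb <- utils::combn(N, n1)
  us <- apply(cmb, 2, uOf)
  mean(abs(us - mu) >= obs - 1e-9)
}

# Benjamini-Hochberg from the step-up definition, one gene at a time
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[o][i])
    q[o[i]] <- min(1, min(p[o][js] * m / js))
  }
  q
}

# KS statistic as the sup over pooled points of |ECDF_a - ECDF_b|
oracleKSD <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# one-way pseudo-F from group centroids (classical MANOVA trace ratio)
oracleOneWayPseudoF <- function(X, f) {
  f <- factor(f)
  n <- nrow(X); a <- nlevels(f)
  gm <- colMeans(X)
  ssTot <- sum(sweep(X, 2, gm)^2)
  ssW <- 0
  for (l in levels(f)) {
    Xi <- X[f == l, , drop = FALSE]
    ssW <- ssW + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  ssA <- ssTot - ssW
  (ssA / (a - 1)) / (ssW / (n - a))
}

# HVG ranking computed densely, straight from the documented definition
oracleHVGRank <- function(counts, nBins = 20, scaleFactor = 1e4) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  norm <- t(t(counts) * (scaleFactor / tot))         # de-logged normalized
  mu <- rowMeans(norm)
  vv <- apply(norm, 1, stats::var)
  vv[vv < mu^2 * 1e-10] <- 0      # documented near-zero dispersion guard
  disp <- ifelse(mu > 0, vv / mu, 0)
  genes <- rownames(counts)
  nb <- max(1, min(nBins, length(genes)))
  ord <- order(mu, genes, method = "radix")
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(genes) * nb / length(genes))
  z <- numeric(length(genes))
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[disp == 0] <- -Inf
  z <- signif(z, 10)              # documented tie-snapping rule
  genes[order(-z, genes, method = "radix")]
}
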