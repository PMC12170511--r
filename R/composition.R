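#' Centered log-ratio transform of a composition table
#'
#' Rows are compositions (non-negative, summing to one). Zeros are replaced
#' by `epsilon` and the row re-closed before taking logs; each row is then
#' centered by its mean log, so transformed rows sum to zero and Euclidean
#' geometry becomes appropriate for downstream multivariate tests.
#'
#' @param x numeric matrix or data.frame of compositions, observations in
#'   rows.
#' @param epsilon replacement for zero proportions (default 1e-6).
#' @param tol tolerance for the row-sum-to-one check (default 1e-6).
#' @return Numeric matrix of CLR values, same dimnames as `x`.
#' @export
clrTransform <- function(x, epsilon = 1e-6, tol = 1e-6) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("composition table must be numeric")
  if (any(x < 0)) stopf("negative proportions are not a composition")
  rs <- rowSums(x)
  if (any(abs(rs - 1) > tol))
    stopf("row(s) do not sum to 1 within %g: %s", tol,
          paste(utils::head(which(abs(rs - 1) > tol), 5L), collapse = ", "))
  x[x == 0] <- epsilon
  x <- x / rowSums(x)
  L <- log(x)
  L - rowMeans(L)
}

#' Permutational multivariate ANOVA (one or two crossed factors)
#'
#' Partitions the total sum of squares of the Euclidean distance matrix of
#' `data` sequentially (Type I) into factor A, factor B, their interaction
#' and residual, via trace forms on the Gower-centered inner-product matrix.
#' Pseudo-F for each term uses the full-model residual; p-values come from
#' permuting raw observations (rows of the distance matrix) `nPerm` times.
#'
#' @param data numeric matrix (observations x variables), e.g. CLR-transformed
#'   compositions.
#' @param factorA,factorB factors (or coercible) of length `nrow(data)`;
#'   `factorB = NULL` gives the one-way test.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return `data.frame` with one row per term (`A`, `B`, `A:B`, `Residual`,
#'   `Total`): `df`, `SS`, `F`, `p`; attributes `n_perm` and `seed`.
#' @export
permanova <- function(data, factorA, factorB = NULL, nPerm = 999, seed = 0L) {
  data <- as.matrix(data)
  n <- nrow(data)
  fA <- factor(factorA)
  if (length(fA) != n) stopf("factorA length must match rows of data")
  if (nlevels(fA) < 2L) stopf("factorA needs at least 2 levels")
  twoWay <- !is.null(factorB)
  if (twoWay) {
    fB <- factor(factorB)
    if (length(fB) != n) stopf("factorB length must match rows of data")
    if (nlevels(fB) < 2L) stopf("factorB needs at least 2 levels")
    cell <- table(fA, fB)
    if (any(cell == 0))
      stopf("empty design cell(s); factors are confounded: %s",
            paste(utils::head(which(cell == 0), 3L), collapse = ", "))
    if (any(cell < 2))
      stopf("each design cell needs at least 2 observations")
  }
  # Gower-centered inner-product matrix from squared Euclidean distances
  D2 <- as.matrix(stats::dist(data))^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  one <- matrix(1, n, 1)
  mmA <- stats::model.matrix(~fA)
  Hs <- list(A = hat(mmA))
  dfs <- c(A = nlevels(fA) - 1L)
  if (twoWay) {
    Hs$B <- hat(stats::model.matrix(~ fA + fB))
    Hs$AB <- hat(stats::model.matrix(~ fA * fB))
    dfs <- c(dfs, B = nlevels(fB) - 1L,
             AB = (nlevels(fA) - 1L) * (nlevels(fB) - 1L))
  }
  H0 <- hat(one)
  Hfull <- Hs[[length(Hs)]]
  dfRes <- n - as.integer(round(sum(diag(Hfull))))
  if (dfRes <= 0) stopf("no residual degrees of freedom")
  ssTerms <- function(Gm) {
    tr <- vapply(Hs, function(H) sum(H * Gm), numeric(1))
    tr0 <- sum(H0 * Gm)
    ss <- diff(c(tr0, tr))
    c(ss, Residual = sum(diag(Gm)) - tr[length(tr)])
  }
  obs <- ssTerms(G)
  k <- length(Hs)
  Fobs <- (obs[seq_len(k)] / dfs) / (obs[k + 1L] / dfRes)
  exceed <- numeric(k)
  withSeed(seed, {
    for (i in seq_len(nPerm)) {
      p <- sample.int(n)
      ssp <- ssTerms(G[p, p])
      Fp <- (ssp[seq_len(k)] / dfs) / (ssp[k + 1L] / dfRes)
      exceed <- exceed + (Fp >= Fobs - 1e-12)
    }
  })
  pvals <- (1 + exceed) / (nPerm + 1)
  terms <- names(Hs)
  terms[terms == "AB"] <- "A:B"
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, dfRes, n - 1L),
    SS = c(obs[seq_len(k)], obs[k + 1L], sum(diag(G))),
    F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- nPerm
  attr(out, "seed") <- seed
  out
}
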