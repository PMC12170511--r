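test_that("rankSumTest matches the exhaustive permutation oracle", {
  # spec example: complete separation at n = 3 vs 3
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(oracleRankSumP(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_lt(abs(r$p - 0.1), 0.05)

  # all ties -> p = 1
  expect_equal(rankSumTest(c(1, 1, 1), c(1, 1, 1))$p, 1)

  # symmetry: swapping groups preserves p and reflects U
  x <- c(0.3, 2, 2, 5); y <- c(1, 1, 4, 9, 9)
  a <- rankSumTest(x, y); b <- rankSumTest(y, x)
  expect_equal(a$p, b$p)
  expect_equal(b$U, length(x) * length(y) - a$U)

  expect_error(rankSumTest(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("normal-approximation p stays within 0.05 of the exact oracle for n <= 8", {
  # tie-free: every attainable U at several group-size pairs, exhaustively
  for (sz in list(c(3, 3), c(3, 6), c(4, 5), c(6, 6))) {
    n1 <- sz[1]; n2 <- sz[2]; N <- n1 + n2
    cmb <- utils::combn(N, n1)
    for (ci in seq_len(ncol(cmb))) {
      x <- cmb[, ci]; y <- setdiff(seq_len(N), x)
      expect_lt(abs(rankSumTest(x, y)$p - oracleRankSumP(x, y)), 0.05)
    }
  }
})

test_that("heavily tied tiny samples degrade the approximation only boundedly", {
  cases <- withr::with_seed(42, {
    lapply(1:30, function(i) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      # small value grid forces heavy ties
      list(x = sample(1:5, n1, replace = TRUE),
           y = sample(1:5, n2, replace = TRUE))
    })
  })
  for (cs in cases) {
    approx <- rankSumTest(cs$x, cs$y)$p
    exact <- oracleRankSumP(cs$x, cs$y)
    expect_lt(abs(approx - exact), 0.2)
  }
})

test_that("bhAdjust equals the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  ps <- withr::with_seed(9, replicate(20, {
    n <- sample(1:100, 1)
    stats::runif(n)^sample(1:3, 1)
  }, simplify = FALSE))
  for (p in ps) {
    q <- bhAdjust(p)
    expect_equal(q, oracleBH(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)  # cross-check
    expect_true(all(q >= p - 1e-15))
    expect_false(is.unsorted(q[order(p)]))  # monotone in p
  }
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("log2FoldChange works on de-logged means and is antisymmetric", {
  # de-logged means 3 vs 1 with pseudocount 1 -> log2(4/2) = 1
  v1 <- rep(log(4), 5)  # expm1 -> 3
  v2 <- rep(log(2), 4)  # expm1 -> 1
  expect_equal(log2FoldChange(v1, v2, 1), 1)
  expect_equal(log2FoldChange(v1, v1, 1), 0)
  expect_equal(log2FoldChange(v2, v1, 1), -1)
  expect_error(log2FoldChange(numeric(), v1), "empty")
})

test_that("deAnalysis filters, tests, adjusts and flags as documented", {
  genes <- c("lowdet", "null", "shift")
  spots <- sprintf("s%02d", 1:40)
  lm <- withr::with_seed(5, {
    m <- matrix(abs(rnorm(3 * 40, 1, 0.2)), nrow = 3,
                dimnames = list(genes, spots))
    m["lowdet", ] <- 0
    m["lowdet", 1] <- 2                      # detected in 1/20 per group
    m["shift", 1:20] <- m["shift", 1:20] + 3 # strong planted shift
    m
  })
  ct <- list(name = "toy", group1 = spots[1:20], group2 = spots[21:40])
  de <- deAnalysis(lm, ct, deConfig(min_pct = 0.10))
  expect_false(de$tested[de$gene == "lowdet"])
  expect_true(is.na(de$p[de$gene == "lowdet"]))
  expect_false(de$significant[de$gene == "lowdet"])
  expect_true(de$significant[de$gene == "shift"])
  expect_false(de$significant[de$gene == "null"])
  expect_true(all(de$q >= de$p, na.rm = TRUE))
  # q recomputable from the tested p-values alone
  expect_equal(de$q[de$tested], bhAdjust(de$p[de$tested]))

  expect_error(deAnalysis(lm, list(group1 = spots[1:5], group2 = spots[5:9])),
               "overlap")
  expect_error(deAnalysis(lm, list(group1 = spots[1:2], group2 = spots[3:9])),
               ">= 3 spots")
})

test_that("HVG screening and gene-set comparison follow set semantics", {
  expect_setequal(screenWithHVG(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_length(screenWithHVG(c("a"), c("b")), 0L)
  expect_setequal(screenWithHVG(c("a", "b"), c("a", "b", "c")), c("a", "b"))
  expect_setequal(screenWithHVG(c("a"), c("b"), mode = "union"), c("a", "b"))

  cmp <- compareGeneSets(c("1", "2", "3"), c("2", "3", "4"))
  expect_identical(cmp$counts[c("n_unique_to_A", "n_shared", "n_unique_to_B")],
                   list(n_unique_to_A = 1L, n_shared = 2L, n_unique_to_B = 1L))
  empty <- compareGeneSets(character(), c("x", "y"))
  expect_equal(empty$counts$n_unique_to_B, 2L)
  # partition identity on random sets
  sets <- withr::with_seed(3, replicate(10, list(
    A = sample(letters, sample(0:15, 1)),
    B = sample(letters, sample(0:15, 1))), simplify = FALSE))
  for (s in sets) {
    cc <- compareGeneSets(s$A, s$B)$counts
    expect_equal(cc$n_unique_to_A + cc$n_shared, length(unique(s$A)))
    expect_equal(cc$n_unique_to_B + cc$n_shared, length(unique(s$B)))
  }
})
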