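test_that("thinCounts is identity at rate 1 and entry-wise dominated below it", {
  m <- withr::with_seed(1, Matrix::Matrix(
    matrix(rpois(200, 5), 10, 20,
           dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:20))),
    sparse = TRUE))
  expect_identical(thinCounts(m, rate = 1), m)
  th <- thinCounts(m, rate = 0.3, seed = 7)
  expect_true(all(as.matrix(th) <= as.matrix(m)))
  expect_true(all(th@x >= 0))
  # detection subset law follows entry-wise domination
  expect_true(all(which(as.matrix(th) > 0) %in% which(as.matrix(m) > 0)))
  # reproducible under seed
  expect_identical(th, thinCounts(m, rate = 0.3, seed = 7))
  expect_false(identical(th, thinCounts(m, rate = 0.3, seed = 8)))

  expect_error(thinCounts(m, rate = 1.5), "\\(0, 1\\]")
  expect_error(thinCounts(m, rate = 0.5, targetMeanDepth = 3), "exactly one")
  expect_error(thinCounts(m, targetMeanDepth = 1e6), "exceeds")
})

test_that("thinning has binomial moments and preserves Poisson form", {
  big <- Matrix::Matrix(matrix(10000, 1, 4000,
                               dimnames = list("g", sprintf("s%d", 1:4000))),
                        sparse = TRUE)
  th <- thinCounts(big, rate = 0.5, seed = 3)
  # Binomial(10000, 0.5): mean 5000, sd 50
  expect_lt(abs(mean(th@x) - 5000), 5)
  expect_lt(abs(stats::sd(th@x) - 50), 3)

  # Poisson(8) thinned at 0.3 ~ Poisson(2.4): mean == variance
  pois <- withr::with_seed(11, Matrix::Matrix(
    matrix(rpois(10000, 8), 1, 10000,
           dimnames = list("g", sprintf("s%d", 1:10000))), sparse = TRUE))
  tp <- as.vector(thinCounts(pois, rate = 0.3, seed = 5))
  expect_lt(abs(mean(tp) - 2.4), 0.1)
  expect_lt(abs(stats::var(tp) - 2.4), 0.15)
})

test_that("targetMeanDepth computes the thinning rate from current depth", {
  m <- Matrix::Matrix(matrix(100, 5, 10,
                             dimnames = list(sprintf("g%d", 1:5),
                                             sprintf("s%d", 1:10))), sparse = TRUE)
  th <- thinCounts(m, targetMeanDepth = 100, seed = 2)  # rate = 100/500
  expect_lt(abs(mean(Matrix::colSums(th)) - 100), 20)
})

test_that("matchGenes partitions the two gene universes", {
  dA <- data.frame(gene = c("a", "b", "c"), pct_detected = c(1, 1, 1))
  dB <- data.frame(gene = c("b", "c", "d"), pct_detected = c(1, 1, 1))
  m <- matchGenes(dA, dB)
  expect_setequal(as.character(m), c("b", "c"))
  expect_identical(attr(m, "only_deep"), "a")
  expect_identical(attr(m, "only_standard"), "d")
  expect_equal(length(m) + length(attr(m, "only_deep")), nrow(dA))
  expect_error(matchGenes(dA, data.frame(gene = "z", pct_detected = 1)),
               "no genes shared")
})

test_that("detectionDelta counts strict increases and self-compares to zero", {
  deep <- data.frame(gene = c("up", "same", "down"),
                     pct_detected = c(0.5, 0.3, 0.1))
  std <- data.frame(gene = c("up", "same", "down"),
                    pct_detected = c(0.25, 0.3, 0.2))
  dd <- detectionDelta(deep, std)
  expect_equal(dd$table$delta, c(0.25, 0, -0.1))
  expect_equal(dd$summary$n_increased_in_deep, 1L)  # strict >
  expect_equal(dd$summary$fraction_increased, 1 / 3)

  self <- detectionDelta(deep, deep)
  expect_equal(self$summary$fraction_increased, 0)
  expect_equal(self$ks$D, 0)
})

test_that("ksTwoSample matches the brute-force ECDF supremum", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ksTwoSample(c(1, 3), c(2, 4))$D, 0.5)
  expect_equal(oracleKSD(c(1, 3), c(2, 4)), 0.5)
  expect_equal(ksTwoSample(c(2, 9, 4), c(2, 9, 4))$D, 0)

  cases <- withr::with_seed(21, lapply(1:40, function(i)
    list(a = sample(0:4, sample(1:8, 1), replace = TRUE) / 4,
         b = sample(0:4, sample(1:8, 1), replace = TRUE) / 4)))
  for (cs in cases) {
    ours <- ksTwoSample(cs$a, cs$b)
    expect_equal(ours$D, oracleKSD(cs$a, cs$b), tolerance = 1e-12)
    # D also cross-checked against the standard implementation
    ref <- suppressWarnings(stats::ks.test(cs$a, cs$b))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  }
  expect_error(ksTwoSample(numeric(), 1), "non-empty")
})
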