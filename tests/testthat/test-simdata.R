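test_that("generateGrid applies the Visium parity rule and benign band", {
  cfg <- syntheticConfig(n_rows = 2, n_cols = 3, slides = 1)
  g <- generateGrid(cfg)
  expect_equal(nrow(g), 6L)
  expect_equal(g$array_row, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(g$array_col, c(0L, 2L, 4L, 1L, 3L, 5L))
  expect_true(all(g$array_row %% 2 == g$array_col %% 2))

  # no benign band when the fraction is zero
  g0 <- generateGrid(syntheticConfig(n_rows = 8, n_cols = 8, slides = 1,
                                     benign_fraction_slide1 = 0))
  expect_equal(sum(g0$region == "benign"), 0L)

  # default: 2 slides x 56 x 56 = 6,272 spots, and only slide 1 has benign
  gd <- generateGrid(syntheticConfig())
  expect_equal(nrow(gd), 6272L)
  expect_true(all(gd$region[gd$slide_id == "slide2"] == "tumor"))
  expect_equal(sum(gd$region == "benign"), ceiling(0.3 * 56) * 56)

  expect_error(syntheticConfig(n_rows = 0), "positive")
})

test_that("plantTruth places the configured number of immune spots and keeps gene sets disjoint", {
  cfg <- syntheticConfig()
  g <- generateGrid(cfg)
  tr <- plantTruth(g, cfg)
  expect_equal(length(tr$immune_spot_ids), ceiling(0.046 * 6272))  # 289
  expect_true(all(tr$immune_spot_ids %in% g$barcode))
  markers <- panelGenes(defaultMarkerPanel())
  expect_length(intersect(names(tr$response_genes_tumor), markers), 0)
  expect_length(intersect(names(tr$response_genes_benign), markers), 0)
  expect_length(intersect(names(tr$response_genes_tumor),
                          names(tr$response_genes_benign)), 0)
  expect_equal(unname(sort(unique(abs(tr$response_genes_tumor)))),
               cfg$response_log2fc)

  # subclone patches: tumor spots partitioned, benign spots are patch 0
  pa <- tr$subclone_assignment
  expect_false(anyNA(pa))
  expect_true(all(pa[g$barcode[g$region == "benign"]] == 0L))
  expect_gt(length(unique(pa[pa > 0])), 1L)
})

test_that("subclone patches are spatially contiguous on the hex lattice", {
  cfg <- smallConfig(seed = 8)
  g <- generateGrid(cfg)
  tr <- plantTruth(g, cfg)
  pa <- tr$subclone_assignment[g$barcode]
  for (k in unique(pa[pa > 0])) {
    members <- g$barcode[which(pa == k)]
    if (length(members) == 1L) next
    # breadth-first flood within the patch must reach every member
    seen <- members[1L]
    repeat {
      nb <- unique(unlist(lapply(seen, function(b) hexNeighbors(g, b))))
      grown <- union(seen, intersect(nb, members))
      if (length(grown) == length(seen)) break
      seen <- grown
    }
    expect_setequal(seen, members)
  }
})

test_that("unbiased immune placement is spatially homogeneous; determinism holds", {
  cfg <- smallConfig(immune_benign_bias = 1, immune_spot_fraction = 0.08)
  g <- generateGrid(cfg)
  benignIdx <- which(g$region == "benign")
  nearFlags <- rep(FALSE, nrow(g))
  nearFlags[benignIdx] <- TRUE
  for (i in 1:2) {
    nb <- unique(unlist(lapply(g$barcode[nearFlags], function(b) hexNeighbors(g, b))))
    nearFlags[g$barcode %in% nb] <- TRUE
  }
  near <- 0; far <- 0
  for (s in 1:20) {
    cs <- smallConfig(seed = s, immune_benign_bias = 1, immune_spot_fraction = 0.08)
    tr <- plantTruth(g, cs)
    imm <- g$barcode %in% tr$immune_spot_ids
    near <- near + sum(imm & nearFlags)
    far <- far + sum(imm & !nearFlags)
  }
  tot <- table(nearFlags)
  chi <- suppressWarnings(stats::chisq.test(
    c(near, far), p = c(tot[["TRUE"]], tot[["FALSE"]]) / nrow(g)))
  expect_gt(chi$p.value, 0.01)

  # determinism: same config -> identical truth
  expect_identical(plantTruth(g, cfg), plantTruth(g, cfg))
})

test_that("simulateCounts hits the depth target and calibrated marker scale", {
  cfg <- smallConfig(seed = 5)
  g <- generateGrid(cfg)
  tr <- plantTruth(g, cfg)
  m <- simulateCounts(g, tr, cfg, "deep")
  expect_true(all(m@x >= 0))
  expect_true(all(m@x == round(m@x)))
  expect_identical(dim(m), c(400L, nrow(g)))

  # lognormal library sizes: empirical mean within 10% of the target
  expect_lt(abs(mean(Matrix::colSums(m)) / cfg$depth_deep_mean - 1), 0.10)
  ms <- simulateCounts(g, tr, cfg, "standard")
  expect_lt(abs(mean(Matrix::colSums(ms)) / cfg$depth_standard_mean - 1), 0.10)

  # markers are calibrated so immune spots score near the configured target
  lm <- normalizeCounts(m)
  sc <- markerScore(lm[, tr$immune_spot_ids])
  expect_lt(abs(mean(sc) - cfg$immune_marker_lognorm_target), 0.25)

  # determinism and regime independence of the planted structure
  expect_identical(m, simulateCounts(g, tr, cfg, "deep"))
  expect_error(simulateCounts(g, tr, cfg, "shallow"))
})

test_that("planted adjacency effects are confined to the right stratum", {
  cfg <- smallConfig(seed = 11, immune_spot_fraction = 0.08)
  se <- normalizeCounts(simulateDataset(cfg))
  tr <- S4Vectors::metadata(se)$truth
  g <- spotGrid(se)
  lab <- classifyNiche(g, tr$immune_spot_ids)
  lm <- logCounts(se)
  up <- names(which(tr$response_genes_tumor > 0))
  adjT <- lab$barcode[lab$label == "adjacent" & lab$stratum == "tumor"]
  awayT <- lab$barcode[lab$label == "away" & lab$stratum == "tumor"]
  adjB <- lab$barcode[lab$label == "adjacent" & lab$stratum == "benign"]
  awayB <- lab$barcode[lab$label == "away" & lab$stratum == "benign"]
  # up-shifted tumor-response genes are higher in tumor-adjacent spots...
  expect_gt(mean(as.matrix(lm[up, adjT])) - mean(as.matrix(lm[up, awayT])), 0.1)
  # ...and unshifted in the benign stratum
  expect_lt(abs(mean(as.matrix(lm[up, adjB])) - mean(as.matrix(lm[up, awayB]))),
            0.1)
})

test_that("simulated composition tables live on the simplex and respect planted nulls", {
  tab <- simulateComposition(nPerCell = 10, seed = 4)
  mac <- as.matrix(tab[, grep("^Mac", colnames(tab))])
  expect_equal(rowSums(mac), rep(1, nrow(mac)), tolerance = 1e-12)
  expect_true(all(mac >= 0))
  expect_equal(nrow(tab), 40L)
  expect_identical(tab, simulateComposition(nPerCell = 10, seed = 4))
  # type 5 dominance
  expect_equal(names(which.max(colMeans(mac))), "Mac5")
})
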