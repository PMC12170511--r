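test_that("markerScore averages panel genes present in the matrix", {
  panel <- MarkerPanel(list(L1 = c("M1", "M2"), L2 = c("M3", "M4")))
  lm <- toyLogMatrix(c(1.0, 0.8, 0.0, 0.2,
                       0.0, 0.0, 0.0, 0.0),
                     genes = c("M1", "M2", "M3", "M4"), spots = c("sp1", "sp2"))
  sc <- markerScore(lm, panel, minCoverage = 0.5)
  expect_equal(unname(sc["sp1"]), 0.5)
  expect_equal(unname(sc["sp2"]), 0)

  # absent markers shrink the denominator instead of counting as zero
  lm3 <- lm[c("M1", "M2", "M3"), , drop = FALSE]
  expect_message(sc3 <- markerScore(lm3, panel, minCoverage = 0.5), "absent")
  expect_equal(unname(sc3["sp1"]), mean(c(1.0, 0.8, 0.0)))

  # below the coverage floor the call fails, naming missing symbols
  lm1 <- lm["M1", , drop = FALSE]
  expect_error(markerScore(lm1, panel, minCoverage = 0.5), "M4")
})

test_that("immune calling uses a strict threshold", {
  sc <- c(a = 0.95, b = 0.9, c = 0.1)
  called <- callImmuneSpots(sc, threshold = 0.9)
  expect_identical(called, "a")          # 0.95 called, exactly 0.9 not
  expect_setequal(callImmuneSpots(sc, threshold = -1e9), c("a", "b", "c"))
  expect_error(callImmuneSpots(c(a = NaN), 0.9), "finite")
  # monotone: raising the threshold never adds spots
  for (th in c(0, 0.5, 0.9, 0.94)) {
    expect_true(all(callImmuneSpots(sc, 0.95) %in% callImmuneSpots(sc, th)))
  }
})

test_that("hexNeighbors implements the six-offset contact rule", {
  g <- toyGrid(5, 5)
  nb <- hexNeighbors(g, "s1_R2C4")
  expect_setequal(nb, c("s1_R2C2", "s1_R2C6", "s1_R1C3", "s1_R1C5",
                        "s1_R3C3", "s1_R3C5"))
  # corner spot in a 2-row grid keeps only the two existing neighbors
  g2 <- toyGrid(2, 3)
  expect_setequal(hexNeighbors(g2, "s1_R0C0"), c("s1_R0C2", "s1_R1C1"))
  expect_error(hexNeighbors(g, "missing"), "unknown")

  # symmetry, exhaustively on a 10 x 10 grid
  g10 <- toyGrid(10, 10)
  adj <- lapply(g10$barcode, function(b) hexNeighbors(g10, b))
  names(adj) <- g10$barcode
  for (b in g10$barcode) {
    for (n in adj[[b]]) expect_true(b %in% adj[[n]])
    expect_lte(length(adj[[b]]), 6L)
  }
})

test_that("classifyNiche partitions spots with immune precedence", {
  g <- toyGrid(5, 5)
  lab <- classifyNiche(g, "s1_R2C4")
  expect_equal(sum(lab$label == "adjacent"), 6L)
  expect_equal(sum(lab$label == "immune"), 1L)
  expect_equal(sum(lab$label == "away"), nrow(g) - 7L)
  # labels always partition the analyzed spots
  expect_equal(nrow(lab), nrow(g))

  # two touching immune spots both stay immune
  lab2 <- classifyNiche(g, c("s1_R2C4", "s1_R2C6"))
  expect_identical(lab2$label[lab2$barcode %in% c("s1_R2C4", "s1_R2C6")],
                   c("immune", "immune"))

  # empty immune set -> everything away
  lab0 <- classifyNiche(g, character())
  expect_true(all(lab0$label == "away"))

  # adjacency is real: every adjacent spot touches an immune spot, no away spot does
  imm <- c("s1_R1C3", "s1_R4C4")
  lab3 <- classifyNiche(g, imm)
  for (i in seq_len(nrow(lab3))) {
    hasImm <- length(intersect(hexNeighbors(g, lab3$barcode[i]), imm)) > 0
    if (lab3$label[i] == "adjacent") expect_true(hasImm)
    if (lab3$label[i] == "away") expect_false(hasImm)
  }
  expect_error(classifyNiche(g, "nope"), "unknown")
})

test_that("buildContrasts excludes immune spots and honours the partial-failure contract", {
  g <- toyGrid(6, 6)
  g$region[g$array_row < 2] <- "benign"
  imm <- c("s1_R0C2", "s1_R3C5")
  lab <- classifyNiche(g, imm)
  cts <- buildContrasts(lab)
  expect_named(cts, c("tumor_adjacent_vs_away", "benign_adjacent_vs_away",
                      "tumor_adjacent_vs_benign_adjacent"))
  allGroups <- unlist(lapply(cts, function(ct) c(ct$group1, ct$group2)))
  expect_length(intersect(allGroups, imm), 0L)
  ct1 <- cts$tumor_adjacent_vs_away
  expect_equal(length(ct1$group1),
               sum(lab$label == "adjacent" & lab$stratum == "tumor"))

  # all-tumor grid: benign contrasts fail, tumor contrast survives
  gt <- toyGrid(6, 6)
  labT <- classifyNiche(gt, imm)
  expect_error(buildContrasts(labT, strict = TRUE), "benign")
  ctsT <- suppressWarnings(buildContrasts(labT, strict = FALSE))
  expect_named(ctsT, "tumor_adjacent_vs_away")
})
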