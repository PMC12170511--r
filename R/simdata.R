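#' Configuration for the synthetic Visium-like generator
#'
#' Defines the study conditions the generator emulates: a two-slide
#' hexagonal-lattice case (~6,272 spots at the 56x56 default) with a benign
#' band on slide 1, contiguous tumor subclone patches, a small fraction of
#' immune cell-enriched spots biased toward the benign margin, planted
#' adjacency-response gene programs that are broader in tumor than benign
#' (about 3:1), and two sequencing-depth regimes about 35-fold apart.
#'
#' @param seed master integer seed; all generator randomness derives from it.
#' @param slides number of slides (default 2).
#' @param n_rows,n_cols hex-grid dimensions per slide (default 56 x 56).
#' @param benign_fraction_slide1 fraction of slide-1 rows forming the
#'   contiguous benign band (default 0.3).
#' @param n_subclones number of contiguous tumor patches (default 15).
#' @param n_genes total gene count (default 5000).
#' @param n_marker_genes immune marker genes, drawn from the default panel
#'   (default 23).
#' @param immune_spot_fraction fraction of analyzed spots planted as immune
#'   cell-enriched (default 0.046).
#' @param immune_benign_bias sampling-weight multiplier for spots within two
#'   hex steps of the benign region (default 4).
#' @param immune_marker_lognorm_target mean log-normalized marker expression
#'   aimed for in immune spots (default 1.2; must exceed the 0.9 calling
#'   threshold).
#' @param n_response_genes_tumor,n_response_genes_benign planted
#'   adjacency-response genes per stratum (defaults 200 and 67).
#' @param response_log2fc planted |log2 fold change| of response genes in
#'   spots adjacent to immune spots (default 1; signs are drawn per gene).
#' @param nb_dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2; default 0.1).
#' @param depth_deep_mean,depth_standard_mean target mean library sizes
#'   (lognormal across spots) for the two regimes; defaults 20,000 and
#'   20,000/35.
#' @param library_size_sdlog lognormal sd of per-spot library sizes
#'   (default 0.35).
#' @param marker_baseline_lognorm mean log-normalized marker expression in
#'   non-immune spots (default 0.12).
#' @param response_baseline_lognorm mean log-normalized expression of
#'   response genes outside adjacent spots (default 0.6).
#' @param n_program_genes genes per subclone expression program (default 40).
#' @param program_sdlog2 sd of subclone-program log2 effects (default 0.35).
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L,
                            slides = 2L,
                            n_rows = 56L, n_cols = 56L,
                            benign_fraction_slide1 = 0.3,
                            n_subclones = 15L,
                            n_genes = 5000L,
                            n_marker_genes = 23L,
                            immune_spot_fraction = 0.046,
                            immune_benign_bias = 4,
                            immune_marker_lognorm_target = 1.2,
                            n_response_genes_tumor = 200L,
                            n_response_genes_benign = 67L,
                            response_log2fc = 1,
                            nb_dispersion = 0.1,
                            depth_deep_mean = 20000,
                            depth_standard_mean = depth_deep_mean / 35,
                            library_size_sdlog = 0.35,
                            marker_baseline_lognorm = 0.12,
                            response_baseline_lognorm = 0.6,
                            n_program_genes = 40L,
                            program_sdlog2 = 0.35) {
  cfg <- list(seed = as.integer(seed), slides = as.integer(slides),
              n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              benign_fraction_slide1 = benign_fraction_slide1,
              n_subclones = as.integer(n_subclones),
              n_genes = as.integer(n_genes),
              n_marker_genes = as.integer(n_marker_genes),
              immune_spot_fraction = immune_spot_fraction,
              immune_benign_bias = immune_benign_bias,
              immune_marker_lognorm_target = immune_marker_lognorm_target,
              n_response_genes_tumor = as.integer(n_response_genes_tumor),
              n_response_genes_benign = as.integer(n_response_genes_benign),
              response_log2fc = response_log2fc,
              nb_dispersion = nb_dispersion,
              depth_deep_mean = depth_deep_mean,
              depth_standard_mean = depth_standard_mean,
              library_size_sdlog = library_size_sdlog,
              marker_baseline_lognorm = marker_baseline_lognorm,
              response_baseline_lognorm = response_baseline_lognorm,
              n_program_genes = as.integer(n_program_genes),
              program_sdlog2 = program_sdlog2)
  if (cfg$n_rows < 1L || cfg$n_cols < 1L || cfg$slides < 1L)
    stopf("grid dimensions and slide count must be positive")
  if (!isFraction(cfg$immune_spot_fraction, openLeft = TRUE, openRight = TRUE))
    stopf("immune_spot_fraction must lie in (0, 1)")
  if (!isFraction(cfg$benign_fraction_slide1))
    stopf("benign_fraction_slide1 must lie in [0, 1]")
  if (cfg$depth_deep_mean <= cfg$depth_standard_mean)
    stopf("depth_deep_mean must exceed depth_standard_mean")
  if (cfg$n_response_genes_tumor + cfg$n_response_genes_benign +
      cfg$n_marker_genes > cfg$n_genes)
    stopf("response + marker genes exceed n_genes")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (cfg$n_subclones < 1L) stopf("n_subclones must be >= 1")
  structure(cfg, class = "SyntheticConfig")
}

#' Read a SyntheticConfig from a structured text (YAML) file
#' @param path YAML file whose keys are [syntheticConfig()] arguments.
#' @export
readSyntheticConfig <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  do.call(syntheticConfig, yaml::read_yaml(path))
}

# gene universe: marker symbols first, then synthetic symbols ---------------
geneUniverse <- function(config) {
  panel <- panelGenes(defaultMarkerPanel())
  nm <- config$n_marker_genes
  markers <- if (nm <= length(panel)) panel[seq_len(nm)] else
    c(panel, sprintf("MARKER%03d", seq_len(nm - length(panel))))
  c(markers, sprintf("GENE%05d", seq_len(config$n_genes - nm)))
}

#' Generate the two-slide hexagonal spot grid
#'
#' Spots sit at array positions `(r, 2j + r mod 2)` (Visium parity
#' convention). Slide 1 carries a contiguous benign band of
#' `ceiling(benign_fraction_slide1 * n_rows)` rows; every other spot is
#' tumor. Deterministic: no randomness is consumed.
#'
#' @param config a [syntheticConfig()].
#' @return Spot grid `data.frame` (`barcode`, `slide_id`, `array_row`,
#'   `array_col`, `in_tissue`, `region`).
#' @export
generateGrid <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  nBenignRows <- ceiling(config$benign_fraction_slide1 * config$n_rows)
  out <- vector("list", config$slides)
  for (s in seq_len(config$slides)) {
    r <- rep(seq_len(config$n_rows) - 1L, each = config$n_cols)
    j <- rep(seq_len(config$n_cols) - 1L, times = config$n_rows)
    col <- 2L * j + r %% 2L
    region <- if (s == 1L) ifelse(r < nBenignRows, "benign", "tumor")
              else rep("tumor", length(r))
    out[[s]] <- data.frame(
      barcode = sprintf("S%d_R%03dC%03d", s, r, col),
      slide_id = sprintf("slide%d", s),
      array_row = r, array_col = col,
      in_tissue = TRUE, region = region,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant the ground truth on a grid
#'
#' Samples the immune cell-enriched spots (weight `immune_benign_bias` for
#' spots within two hex steps of the benign region, weight 1 elsewhere),
#' grows contiguous tumor subclone patches by multi-source region growing on
#' the hex lattice, draws the disjoint tumor/benign adjacency-response gene
#' sets with signed effects, and fixes the per-gene expression structure
#' (baseline abundances, subclone programs) shared by every depth regime.
#'
#' @param grid spot grid from [generateGrid()] (regions required).
#' @param config the matching [syntheticConfig()].
#' @return A list of class `GroundTruth` with elements `immune_spot_ids`,
#'   `response_genes_tumor` / `response_genes_benign` (named signed log2
#'   effects), `subclone_assignment` (named integer; benign = 0),
#'   `subclone_programs`, and the fixed gene-level structure.
#' @export
plantTruth <- function(grid, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!"region" %in% colnames(grid)) stopf("grid has no region labels")
  g <- grid[grid$in_tissue, , drop = FALSE]
  N <- nrow(g)
  nImmune <- ceiling(config$immune_spot_fraction * N)
  if (nImmune > N) stopf("requested %d immune spots but only %d spots", nImmune, N)
  genes <- geneUniverse(config)
  markers <- genes[seq_len(config$n_marker_genes)]
  withSeed(deriveSeed(config$seed, 11L), {
    # immune spots, biased toward the benign margin (<= 2 hex steps)
    benignIdx <- which(g$region == "benign")
    ring1 <- hexNeighborFlag(g, benignIdx) | g$region == "benign"
    ring2 <- hexNeighborFlag(g, which(ring1)) | ring1
    w <- ifelse(ring2, config$immune_benign_bias, 1)
    immune <- sample(g$barcode, nImmune, prob = w)

    # contiguous subclone patches on the tumor spots (benign = patch 0)
    patch <- stats::setNames(rep(NA_integer_, N), g$barcode)
    patch[g$region == "benign"] <- 0L
    tumorIdx <- which(g$region == "tumor")
    K <- min(config$n_subclones, length(tumorIdx))
    if (K > 0L) {
      adj <- hexAdjacencyIndex(g)
      seeds <- sample(tumorIdx, K)
      patch[seeds] <- seq_len(K)
      repeat {
        un <- which(is.na(patch))
        if (!length(un)) break
        assigned <- !is.na(patch) & patch > 0L
        hasNb <- rowSums(matrix(assigned[adj[un, , drop = FALSE]],
                                nrow = length(un)), na.rm = TRUE) > 0
        frontier <- un[hasNb]
        if (!length(frontier)) { patch[un] <- 1L; break }  # disconnected remnant
        for (i in frontier[sample.int(length(frontier))]) {
          pv <- patch[adj[i, ]]
          pv <- pv[!is.na(pv) & pv > 0L]
          if (length(pv)) patch[i] <- pv[sample.int(length(pv), 1L)]
        }
      }
    }

    # disjoint response gene sets with signed planted effects
    pool <- setdiff(genes, markers)
    respT <- sample(pool, config$n_response_genes_tumor)
    respB <- sample(setdiff(pool, respT), config$n_response_genes_benign)
    effT <- stats::setNames(
      sample(c(-1, 1), length(respT), replace = TRUE) * config$response_log2fc, respT)
    effB <- stats::setNames(
      sample(c(-1, 1), length(respB), replace = TRUE) * config$response_log2fc, respB)

    # fixed gene-level structure shared across depth regimes
    sf <- 1e4
    free <- setdiff(pool, c(respT, respB))
    baseW <- stats::setNames(stats::rlnorm(length(free), 0, 1.5), free)
    aLo <- (exp(config$marker_baseline_lognorm) - 1) / sf
    aHi <- (exp(config$immune_marker_lognorm_target) - 1) / sf
    markerLow <- stats::setNames(aLo * stats::rlnorm(length(markers), 0, 0.3), markers)
    markerHigh <- stats::setNames(rep(aHi, length(markers)), markers)
    aResp <- (exp(config$response_baseline_lognorm) - 1) / sf
    respBase <- stats::setNames(
      aResp * stats::rlnorm(length(c(respT, respB)), 0, 0.3), c(respT, respB))
    programs <- list()
    for (k in 0:max(0L, K)) {
      pg <- sample(free, min(config$n_program_genes, length(free)))
      programs[[as.character(k)]] <-
        stats::setNames(stats::rnorm(length(pg), 0, config$program_sdlog2), pg)
    }
    structure(list(
      immune_spot_ids = immune,
      response_genes_tumor = effT,
      response_genes_benign = effB,
      subclone_assignment = patch,
      subclone_programs = programs,
      gene_base_weights = baseW,
      marker_props_low = markerLow,
      marker_props_high = markerHigh,
      response_props = respBase,
      genes = genes,
      seed = config$seed), class = "GroundTruth")
  })
}

#' Simulate a count matrix for one depth regime
#'
#' Library sizes are lognormal around the regime's depth target; counts are
#' negative binomial around `library_size * relative_abundance`. Marker genes
#' are held at calibrated relative abundances so immune spots land near the
#' configured mean log-normalized marker expression; response genes are
#' shifted by their signed planted log2 effect in non-immune spots
#' hex-adjacent to an immune spot (tumor-response genes in tumor spots,
#' benign-response genes in benign spots); the remaining genes follow the
#' baseline weights modulated by the subclone program of the spot's patch.
#'
#' @param grid spot grid from [generateGrid()].
#' @param truth a `GroundTruth` from [plantTruth()].
#' @param config the matching [syntheticConfig()].
#' @param depth `"deep"` or `"standard"`.
#' @return Sparse gene-by-spot integer count matrix.
#' @export
simulateCounts <- function(grid, truth, config, depth = c("deep", "standard")) {
  stopifnot(inherits(config, "SyntheticConfig"), inherits(truth, "GroundTruth"))
  depth <- match.arg(depth)
  g <- grid[grid$in_tissue, , drop = FALSE]
  if (!all(truth$immune_spot_ids %in% g$barcode))
    stopf("truth immune spots are not a subset of the grid")
  genes <- truth$genes
  nG <- length(genes); nS <- nrow(g)
  depthMean <- if (depth == "deep") config$depth_deep_mean else config$depth_standard_mean

  isImm <- g$barcode %in% truth$immune_spot_ids
  touch <- hexNeighborFlag(g, which(isImm)) & !isImm
  adjT <- touch & g$region == "tumor"
  adjB <- touch & g$region == "benign"
  patch <- truth$subclone_assignment[g$barcode]

  markers <- names(truth$marker_props_low)
  respT <- names(truth$response_genes_tumor)
  respB <- names(truth$response_genes_benign)
  free <- names(truth$gene_base_weights)

  # calibrated proportion mass per spot (markers + response genes)
  cm <- ifelse(isImm, sum(truth$marker_props_high), sum(truth$marker_props_low))
  crBase <- sum(truth$response_props)
  bumpT <- sum(truth$response_props[respT] * (2^truth$response_genes_tumor - 1))
  bumpB <- sum(truth$response_props[respB] * (2^truth$response_genes_benign - 1))
  cr <- crBase + ifelse(adjT, bumpT, 0) + ifelse(adjB, bumpB, 0)
  calMass <- cm + cr

  # free-gene weights: baseline x subclone-program multiplier, per patch
  wFree <- truth$gene_base_weights
  patchIds <- sort(unique(patch))
  mult <- matrix(1, nrow = length(free), ncol = length(patchIds),
                 dimnames = list(free, as.character(patchIds)))
  for (pid in patchIds) {
    prog <- truth$subclone_programs[[as.character(pid)]]
    if (!is.null(prog)) mult[names(prog), as.character(pid)] <- 2^prog
  }
  wSumPerPatch <- colSums(wFree * mult)
  freeSum <- wSumPerPatch[as.character(patch)]

  withSeed(deriveSeed(config$seed, if (depth == "deep") 21L else 22L), {
    L <- stats::rlnorm(nS,
                       meanlog = log(depthMean) - config$library_size_sdlog^2 / 2,
                       sdlog = config$library_size_sdlog)
    mu <- matrix(0, nrow = nG, ncol = nS, dimnames = list(genes, g$barcode))
    # free genes: share the remaining (1 - calibrated) mass, patch by patch
    scale <- L * (1 - calMass) / freeSum
    freeIdx <- match(free, genes)
    for (pid in patchIds) {
      cols <- which(patch == pid)
      if (length(cols))
        mu[freeIdx, cols] <- outer(wFree * mult[, as.character(pid)], scale[cols])
    }
    # markers at calibrated proportions
    mu[markers, ] <- outer(truth$marker_props_low, L)
    if (any(isImm))
      mu[markers, isImm] <- outer(truth$marker_props_high, L[isImm])
    # response genes at calibrated proportions, shifted in adjacent spots
    mu[c(respT, respB), ] <- outer(truth$response_props, L)
    if (any(adjT))
      mu[respT, adjT] <- outer(truth$response_props[respT] *
                                 2^truth$response_genes_tumor, L[adjT])
    if (any(adjB))
      mu[respB, adjB] <- outer(truth$response_props[respB] *
                                 2^truth$response_genes_benign, L[adjB])
    counts <- stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    dim(counts) <- dim(mu)
    dimnames(counts) <- dimnames(mu)
    Matrix::drop0(Matrix::Matrix(counts, sparse = TRUE))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: grid + truth + counts at the requested depth,
#' packaged as a [SpotExperiment-class] with the truth and config in
#' `metadata()`.
#'
#' @param config a [syntheticConfig()].
#' @param depth `"deep"` or `"standard"`.
#' @return A [SpotExperiment-class].
#' @export
simulateDataset <- function(config = syntheticConfig(), depth = "deep") {
  grid <- generateGrid(config)
  truth <- plantTruth(grid, config)
  counts <- simulateCounts(grid, truth, config, depth)
  SpotExperiment(counts, grid,
                 metadata = list(truth = truth, config = config, depth = depth))
}

#' Simulate a myeloid composition table with planted factor effects
#'
#' Emulates deconvolved macrophage subtype compositions (Mac1..Mac6, with a
#' dominant type 5) of immune spots in a crossed depth x region design.
#' Rows are Dirichlet draws; the depth effect multiplies the Mac1/Mac2
#' concentrations in the deep regime, the region effect multiplies Mac3/Mac4
#' in HCC, and an optional interaction multiplies Mac1 in deep-HCC cells.
#' Effect values of 1 plant no effect (the null).
#'
#' @param nPerCell observations per design cell (default 20).
#' @param depthEffect,regionEffect,interactionEffect multiplicative
#'   concentration effects (default 2, 2.5, 1).
#' @param concentration total Dirichlet concentration (default 40).
#' @param seed integer seed.
#' @return `data.frame` with `sample_id`, factors `depth` and `region`, and
#'   columns `Mac1`..`Mac6` summing to one per row.
#' @export
simulateComposition <- function(nPerCell = 20, depthEffect = 2,
                                regionEffect = 2.5, interactionEffect = 1,
                                concentration = 40, seed = 1L) {
  stopifnot(isCount(nPerCell), nPerCell >= 2)
  base <- c(Mac1 = 0.07, Mac2 = 0.07, Mac3 = 0.10, Mac4 = 0.12,
            Mac5 = 0.46, Mac6 = 0.18)
  design <- expand.grid(depth = c("deep", "standard"),
                        region = c("HCC", "benign"),
                        stringsAsFactors = FALSE)
  withSeed(deriveSeed(seed, 31L), {
    rows <- list()
    for (d in seq_len(nrow(design))) {
      alpha <- base * concentration
      if (design$depth[d] == "deep")
        alpha[c("Mac1", "Mac2")] <- alpha[c("Mac1", "Mac2")] * depthEffect
      if (design$region[d] == "HCC")
        alpha[c("Mac3", "Mac4")] <- alpha[c("Mac3", "Mac4")] * regionEffect
      if (design$depth[d] == "deep" && design$region[d] == "HCC")
        alpha["Mac1"] <- alpha["Mac1"] * interactionEffect
      gm <- matrix(stats::rgamma(nPerCell * length(alpha),
                                 shape = rep(alpha, each = nPerCell)),
                   nrow = nPerCell)
      gm <- gm / rowSums(gm)
      colnames(gm) <- names(alpha)
      rows[[d]] <- data.frame(
        sample_id = sprintf("%s_%s_%02d", design$depth[d], design$region[d],
                            seq_len(nPerCell)),
        depth = design$depth[d], region = design$region[d], gm,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Write a simulated dataset in the standard on-disk layout
#'
#' Emits the count triplet (`matrix.mtx`, `features.tsv`, `barcodes.tsv`),
#' `tissue_positions.csv`, `regions.csv` and, when a truth is present,
#' `truth.json`.
#'
#' @param se a [SpotExperiment-class] (e.g. from [simulateDataset()]).
#' @param dir_path output directory.
#' @return Invisibly, the directory path.
#' @export
writeDataset <- function(se, dir_path) {
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory %s", dir_path)
  writeCounts(spotCounts(se), dir_path)
  grid <- spotGrid(se)
  writePositions(grid, file.path(dir_path, "tissue_positions.csv"))
  writeRegions(grid, file.path(dir_path, "regions.csv"))
  truth <- metadata(se)$truth
  if (!is.null(truth)) {
    tr <- list(
      immune_spot_ids = truth$immune_spot_ids,
      response_genes_tumor = as.list(truth$response_genes_tumor),
      response_genes_benign = as.list(truth$response_genes_benign),
      subclone_assignment = as.list(truth$subclone_assignment),
      seed = truth$seed)
    jsonlite::write_json(tr, file.path(dir_path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir_path)
}
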