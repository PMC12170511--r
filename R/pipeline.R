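#' Pipeline configuration
#'
#' Exactly one of `paths` (existing data on disk) or `simulate` (a
#' [syntheticConfig()]) supplies the input. The remaining blocks tune the
#' analysis stages; the single `seed` derives every stage seed by fixed
#' offsets.
#'
#' @param paths `NULL`, or list with `counts_dir`, `positions`, and optional
#'   `regions` paths.
#' @param simulate `NULL`, or a [syntheticConfig()].
#' @param niche list with `score_threshold` (default 0.9) and
#'   `min_marker_coverage` (default 0.5).
#' @param de a [deConfig()].
#' @param depth list with `rate` (binomial thinning rate, default 1/35) or
#'   `target_mean_depth`.
#' @param composition `NULL` to skip, a path to a composition CSV (columns:
#'   id, category proportions, factor columns `depth` and `region`), or a
#'   list of [simulateComposition()] arguments.
#' @param hvg_n highly-variable-gene list size (default 3000).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param output_dir directory for all artifacts.
#' @param seed master integer seed.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(paths = NULL, simulate = NULL,
                           niche = list(score_threshold = 0.9,
                                        min_marker_coverage = 0.5),
                           de = deConfig(),
                           depth = list(rate = 1 / 35),
                           composition = list(),
                           hvg_n = 3000, n_perm = 999,
                           output_dir = tempfile("hexniche_run_"),
                           seed = 1L) {
  if (is.null(paths) == is.null(simulate))
    stopf("exactly one of 'paths' or 'simulate' must be provided")
  if (!is.null(paths) &&
      !all(c("counts_dir", "positions") %in% names(paths)))
    stopf("paths must name counts_dir and positions")
  if (!is.null(simulate) && !inherits(simulate, "SyntheticConfig"))
    stopf("simulate must be a syntheticConfig()")
  stopifnot(inherits(de, "DEConfig"))
  if (is.null(niche$score_threshold)) niche$score_threshold <- 0.9
  if (is.null(niche$min_marker_coverage)) niche$min_marker_coverage <- 0.5
  if (is.null(depth$rate) && is.null(depth$target_mean_depth))
    stopf("depth block needs rate or target_mean_depth")
  structure(list(paths = paths, simulate = simulate, niche = niche, de = de,
                 depth = depth, composition = composition, hvg_n = hvg_n,
                 n_perm = n_perm, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a PipelineConfig from a structured text (YAML) file
#'
#' Top-level keys mirror [pipelineConfig()] arguments; a `simulate` section
#' is passed to [syntheticConfig()], a `de` section to [deConfig()].
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(syntheticConfig, raw$simulate)
  if (!is.null(raw$de)) raw$de <- do.call(deConfig, raw$de)
  do.call(pipelineConfig, raw)
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  plain <- rapply(unclass(cfg), function(x) x, how = "replace")
  plain$output_dir <- NULL  # where results land must not change what they are
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

nicheCountBlock <- function(labels) {
  tab <- table(factor(labels$label, levels = c("immune", "adjacent", "away")))
  strat <- table(factor(labels$label, levels = c("immune", "adjacent", "away")),
                 factor(labels$stratum, levels = c("tumor", "benign")))
  list(total_analyzed = nrow(labels),
       immune = as.integer(tab[["immune"]]),
       adjacent = as.integer(tab[["adjacent"]]),
       away = as.integer(tab[["away"]]),
       adjacent_tumor = as.integer(strat["adjacent", "tumor"]),
       adjacent_benign = as.integer(strat["adjacent", "benign"]),
       away_tumor = as.integer(strat["away", "tumor"]),
       away_benign = as.integer(strat["away", "benign"]))
}

deSummaryBlock <- function(deTables) {
  lapply(deTables, function(de) list(
    n_tested = sum(de$tested),
    n_significant = sum(de$significant),
    n_up = sum(de$significant & de$log2fc > 0),
    n_down = sum(de$significant & de$log2fc < 0)))
}

#' Run the full spatial immune-niche pipeline
#'
#' Stages, in order: load or simulate the deep dataset; log-normalize; rank
#' highly variable genes; score spots against the marker panel and call
#' immune cell-enriched spots; classify every spot as immune / adjacent /
#' away; run the three niche contrasts; thin the counts to the standard
#' depth regime and repeat niche calling (for the depth effect on the immune
#' count) and differential expression on the deep-called labels (so the two
#' depth runs compare identical spot groups); compare per-gene detection
#' between regimes; overlap the deep and standard significant gene sets per
#' contrast; and test the myeloid composition table by CLR + PERMANOVA.
#' Every artifact lands under `output_dir`; a second run with the same
#' config reproduces the report bit for bit.
#'
#' @param cfg a [pipelineConfig()].
#' @param panel a [MarkerPanel-class] (default [defaultMarkerPanel()]).
#' @return The report, invisibly also written as `report.json` (plus a
#'   human-readable `report.txt`) under `output_dir`.
#' @export
runPipeline <- function(cfg, panel = defaultMarkerPanel()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  outDir <- cfg$output_dir
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", outDir)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    r
  }

  se <- stage("input", {
    if (!is.null(cfg$simulate)) simulateDataset(cfg$simulate, depth = "deep")
    else readSpotExperiment(cfg$paths$counts_dir, cfg$paths$positions,
                            cfg$paths$regions)
  })
  truth <- metadata(se)$truth
  se <- stage("normalize", normalizeCounts(se))
  hvg <- stage("hvg", selectHVG(se, n = cfg$hvg_n))

  nicheDeep <- stage("niche_deep", {
    sc <- markerScore(se, panel, cfg$niche$min_marker_coverage)
    imm <- callImmuneSpots(sc, cfg$niche$score_threshold)
    classifyNiche(se, imm, scores = sc)
  })
  writeNicheLabels(nicheDeep, file.path(outDir, "niche_labels_deep.csv"))
  contrasts <- stage("contrasts", buildContrasts(nicheDeep, strict = FALSE))

  deDeep <- stage("de_deep", lapply(contrasts, function(ct)
    deAnalysis(se, ct, cfg$de)))
  for (nm in names(deDeep))
    writeDEResult(deDeep[[nm]], file.path(outDir, sprintf("de_deep_%s.tsv", nm)))

  seStd <- stage("thin", thinCounts(
    se, rate = cfg$depth$rate,
    targetMeanDepth = cfg$depth$target_mean_depth,
    seed = deriveSeed(cfg$seed, 41L)))
  seStd <- normalizeCounts(seStd)
  nicheStd <- stage("niche_standard", {
    sc <- markerScore(seStd, panel, cfg$niche$min_marker_coverage)
    imm <- callImmuneSpots(sc, cfg$niche$score_threshold)
    classifyNiche(seStd, imm, scores = sc)
  })
  writeNicheLabels(nicheStd, file.path(outDir, "niche_labels_standard.csv"))
  deStd <- stage("de_standard", lapply(contrasts, function(ct)
    deAnalysis(seStd, ct, cfg$de)))
  for (nm in names(deStd))
    writeDEResult(deStd[[nm]], file.path(outDir, sprintf("de_standard_%s.tsv", nm)))

  depthCmp <- stage("depth_compare", {
    dDeep <- detectionRates(se)
    dStd <- detectionRates(seStd)
    detectionDelta(dDeep, dStd)
  })
  writeTable(depthCmp$table, file.path(outDir, "detection_delta.tsv"))

  overlaps <- stage("overlaps", {
    ov <- lapply(names(deDeep), function(nm) {
      sigD <- deDeep[[nm]]$gene[deDeep[[nm]]$significant]
      sigS <- if (nm %in% names(deStd)) deStd[[nm]]$gene[deStd[[nm]]$significant]
              else character()
      compareGeneSets(sigD, sigS)
    })
    names(ov) <- names(deDeep)
    ov
  })
  jsonlite::write_json(overlaps, file.path(outDir, "gene_set_overlaps.json"),
                       auto_unbox = TRUE, digits = NA)

  compRes <- NULL
  if (!is.null(cfg$composition)) {
    compRes <- stage("composition", {
      tab <- if (is.character(cfg$composition)) {
        utils::read.csv(cfg$composition, stringsAsFactors = FALSE)
      } else {
        args <- cfg$composition
        if (is.null(args$seed)) args$seed <- deriveSeed(cfg$seed, 42L)
        do.call(simulateComposition, args)
      }
      catCols <- grep("^Mac", colnames(tab), value = TRUE)
      clr <- clrTransform(tab[, catCols])
      res <- permanova(clr, tab$depth, tab$region, nPerm = cfg$n_perm,
                       seed = deriveSeed(cfg$seed, 43L))
      list(terms = res, factors = c("depth", "region"))
    })
  }

  report <- list(
    provenance = list(package = "hexniche",
                      version = as.character(utils::packageVersion("hexniche")),
                      seed = cfg$seed, config_hash = configHash(cfg),
                      simulated = !is.null(cfg$simulate)),
    spots = list(deep = nicheCountBlock(nicheDeep),
                 standard = nicheCountBlock(nicheStd)),
    hvg = list(n = length(hvg), top10 = utils::head(hvg, 10L)),
    de = list(deep = deSummaryBlock(deDeep), standard = deSummaryBlock(deStd)),
    depth = list(summary = depthCmp$summary,
                 ks = list(D = depthCmp$ks$D, p = depthCmp$ks$p)),
    overlaps = lapply(overlaps, function(o) o$counts),
    composition = if (!is.null(compRes)) {
      tm <- compRes$terms
      stats::setNames(
        lapply(seq_len(nrow(tm)), function(i)
          list(df = tm$df[i], SS = tm$SS[i],
               F = if (is.na(tm$F[i])) NULL else tm$F[i],
               p = if (is.na(tm$p[i])) NULL else tm$p[i])),
        tm$term)
    } else NULL)
  if (!is.null(truth)) {
    called <- nicheDeep$barcode[nicheDeep$label == "immune"]
    tp <- length(intersect(called, truth$immune_spot_ids))
    nonImm <- setdiff(nicheDeep$barcode, truth$immune_spot_ids)
    sigT <- deDeep$tumor_adjacent_vs_away
    recov <- if (!is.null(sigT)) {
      sig <- sigT$gene[sigT$significant]
      trueT <- names(truth$response_genes_tumor)
      list(de_sensitivity_tumor = length(intersect(sig, trueT)) / length(trueT),
           de_fdp_tumor = if (length(sig))
             length(setdiff(sig, c(trueT, names(truth$response_genes_benign)))) /
               length(sig) else 0)
    } else list()
    report$truth_recovery <- c(list(
      immune_recall = tp / length(truth$immune_spot_ids),
      immune_fpr = length(setdiff(called, truth$immune_spot_ids)) /
        length(nonImm)), recov)
  }
  writeReport(report, file.path(outDir, "report.json"))
  invisible(report)
}

#' Write / read the pipeline report
#'
#' JSON with stable key order plus a short human-readable summary alongside
#' (`.txt` with the same stem).
#'
#' @param report report list from [runPipeline()].
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  txt <- sub("\\.json$", ".txt", path)
  lines <- c(
    sprintf("hexniche report (seed %s, config %s)",
            report$provenance$seed, report$provenance$config_hash),
    sprintf("spots analyzed: %d | immune %d / adjacent %d / away %d (deep)",
            report$spots$deep$total_analyzed, report$spots$deep$immune,
            report$spots$deep$adjacent, report$spots$deep$away),
    sprintf("immune spots at standard depth: %d", report$spots$standard$immune),
    vapply(names(report$de$deep), function(nm)
      sprintf("DE %s: %d significant (deep) vs %d (standard)", nm,
              report$de$deep[[nm]]$n_significant,
              if (nm %in% names(report$de$standard))
                report$de$standard[[nm]]$n_significant else NA_integer_),
      character(1)),
    sprintf("genes with higher detection at deep depth: %d of %d (%.1f%%)",
            report$depth$summary$n_increased_in_deep,
            report$depth$summary$n_genes_matched,
            100 * report$depth$summary$fraction_increased))
  if (!is.null(report$composition)) {
    pv <- vapply(report$composition, function(x)
      if (is.null(x$p)) NA_real_ else x$p, numeric(1))
    pv <- pv[!is.na(pv)]
    lines <- c(lines, sprintf("PERMANOVA: %s",
      paste(sprintf("%s p=%.3f", names(pv), pv), collapse = ", ")))
  }
  writeLines(lines, txt)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
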