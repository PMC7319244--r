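## Category summaries, homogeneity tests, and the one-call pipeline.

.COLLAPSED <- c(invariable = "invariable_like",
                possibly_variable = "invariable_like",
                mosaic = "mosaic_like",
                possibly_chimeric = "mosaic_like",
                chimeric = "chimeric")

#' Summarize colony classifications per stratum
#'
#' Counts and proportions of the five categories per site, per group, or
#' overall, together with the collapsed three-way counts (invariable +
#' possibly variable | mosaic + possibly chimeric | chimeric) and the
#' variable fraction.
#'
#' @param classification result of [classifyDataset()].
#' @param by `"overall"`, `"site"` or `"group"`. A stratified call always
#'   appends an overall row.
#' @return data.frame with one row per stratum: `stratum`, `n`, one count
#'   and one proportion column per category (`n_<cat>`, `p_<cat>`),
#'   collapsed counts `n_invariable_like`, `n_mosaic_like`, `n_chimeric_c`,
#'   and `p_variable`.
#' @export
summarizeClassifications <- function(classification,
                                     by = c("overall", "site", "group")) {
  by <- match.arg(by)
  stopIfNot(nrow(classification) > 0, "empty classification")
  strata <- if (by == "overall") list(overall = classification)
            else split(classification, classification[[by]])
  if (by != "overall") strata$overall <- classification
  rows <- lapply(names(strata), function(nm) {
    cl <- strata[[nm]]
    cnt <- table(factor(cl$category, levels = .CATEGORIES))
    col <- tapply(as.integer(cnt), .COLLAPSED[names(cnt)], sum)
    out <- data.frame(stratum = nm, n = nrow(cl))
    for (cat in .CATEGORIES) out[[paste0("n_", cat)]] <- as.integer(cnt[cat])
    for (cat in .CATEGORIES)
      out[[paste0("p_", cat)]] <- as.numeric(cnt[cat]) / nrow(cl)
    out$n_invariable_like <- as.integer(col["invariable_like"])
    out$n_mosaic_like <- as.integer(col["mosaic_like"])
    out$n_chimeric_c <- as.integer(col["chimeric"])
    out$p_variable <- 1 - (cnt["invariable"] + cnt["possibly_variable"]) /
      nrow(cl)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher exact homogeneity test of category composition across strata
#'
#' Builds the 3 x k contingency of collapsed category counts (invariable +
#' possibly variable | mosaic + possibly chimeric | chimeric) across the
#' chosen strata and tests homogeneity with Fisher's exact test. The exact
#' (network-algorithm) p value is used where feasible; for larger tables a
#' seeded Monte-Carlo estimate with `B` replicates is substituted and the
#' method is recorded.
#'
#' @param classification result of [classifyDataset()].
#' @param by `"site"` or `"group"`.
#' @param minN strata with fewer colonies are dropped with a warning
#'   (default 3).
#' @param B Monte-Carlo replicates for the fallback (default `1e5`).
#' @return list with `p.value`, `method`, `table`.
#' @export
homogeneityTest <- function(classification, by = c("site", "group"),
                            minN = 3L, B = 1e5) {
  by <- match.arg(by)
  strat <- classification[[by]]
  sizes <- table(strat)
  small <- names(sizes)[sizes < minN]
  if (length(small)) {
    warning("dropping stratum(a) with fewer than ", minN, " colonies: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !strat %in% small
    classification <- classification[keep, , drop = FALSE]
    strat <- strat[keep]
  }
  stopIfNot(length(unique(strat)) >= 2, "need >= 2 strata to test")
  collapsed <- factor(.COLLAPSED[as.character(classification$category)],
                      levels = c("invariable_like", "mosaic_like",
                                 "chimeric"))
  tab <- table(collapsed, strat)
  ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                 error = function(e) NULL)
  if (is.null(ft)) {
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
    method <- sprintf("Fisher exact, Monte-Carlo (B = %g)", B)
  } else method <- "Fisher exact (network algorithm)"
  list(p.value = ft$p.value, method = method, table = tab)
}

#' Run the whole IGV pipeline
#'
#' Drives every stage on one dataset: optional locus dropping, distance
#' computation, threshold fitting (or fixed thresholds), classification,
#' threshold sensitivity, clone sharing, per-stratum summaries and
#' homogeneity tests; writes all artifacts plus a JSON manifest to
#' `outDir`.
#'
#' @param x a [MicrosatDataset-class]; alternatively supply `genotypeFile`
#'   + `locusConfigFile` or a `simConfig` to generate data.
#' @param genotypeFile,locusConfigFile input paths (used when `x` is
#'   missing).
#' @param simConfig a [simulationConfig()] (used when neither `x` nor
#'   `genotypeFile` is given); the truth table is then written too.
#' @param thresholds a [ThresholdSet-class] for a fixed-threshold run, or
#'   `NULL` (default) to fit thresholds from the data.
#' @param dropLociNames loci to discard before analysis (e.g. a locus with
#'   suspected genotyping errors).
#' @param outDir output directory.
#' @param seed seed for stochastic steps (simulation, Monte-Carlo tests).
#' @param maxFn false-negative bound for threshold fitting.
#' @return Invisibly, a list with all in-memory results
#'   (`data`, `thresholds`, `classification`, `summaries`, `tests`, ...).
#' @export
runPipeline <- function(x = NULL, genotypeFile = NULL,
                        locusConfigFile = NULL, simConfig = NULL,
                        thresholds = NULL, dropLociNames = character(0),
                        outDir, seed = 1L, maxFn = 0.20) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  truth <- NULL
  if (is.null(x)) {
    if (!is.null(genotypeFile)) {
      x <- readGenotypeTable(genotypeFile, readLocusConfig(locusConfigFile))
    } else if (!is.null(simConfig)) {
      sim <- generateDataset(simConfig, seed = seed)
      x <- sim$data
      truth <- sim$truth
      utils::write.table(truth$colonies, file.path(outDir, "truth.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else stop("supply x, genotypeFile or simConfig", call. = FALSE)
  }
  if (length(dropLociNames)) x <- dropLoci(x, dropLociNames)
  x <- dropEmptyNubbins(x)

  ip <- intracolonialPairs(x)
  writePairwiseTSV(ip, file.path(outDir, "pairs_intracolonial.tsv"))
  ap <- allPairwise(x, requireComplete = TRUE)
  writePairwiseTSV(ap, file.path(outDir, "pairs_complete_all.tsv"))

  fitted <- is.null(thresholds)
  fitInfo <- NULL
  if (fitted) {
    thresholds <- fitThresholds(x, maxFn = maxFn)
    fitInfo <- attr(thresholds, "fit")
    writeFNCurveTSV(fitInfo$curve, file.path(outDir, "fn_curve.tsv"))
  }

  cls <- classifyDataset(x, thresholds)
  writeClassificationTSV(cls, file.path(outDir, "classification.tsv"))
  sens <- sensitivityAnalysis(x, thresholds)
  utils::write.table(sens, file.path(outDir, "sensitivity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  shared <- sharedMLGsAcrossColonies(x, cls)
  utils::write.table(shared, file.path(outDir, "shared_mlgs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  summaries <- list(
    overall = summarizeClassifications(cls, "overall"),
    site = summarizeClassifications(cls, "site"),
    group = summarizeClassifications(cls, "group"))
  for (nm in c("site", "group"))
    utils::write.table(summaries[[nm]],
                       file.path(outDir, paste0("summary_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  tests <- list()
  for (nm in c("site", "group")) {
    tests[[nm]] <- tryCatch(
      withCallingHandlers(
        homogeneityTest(cls, by = nm),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) list(p.value = NA_real_, method = conditionMessage(e),
                               table = NULL))
  }

  manifest <- list(
    package = "colonyIGV",
    version = as.character(utils::packageVersion("colonyIGV")),
    seed = seed,
    n_colonies = length(colonyIds(x)),
    n_nubbins = nNubbins(x),
    n_loci = nLoci(x),
    dropped_loci = dropLociNames,
    thresholds = list(mode = if (fitted) "fitted" else "fixed",
                      N_L_min = thresholds@nLMin,
                      N_A_chi_mos = thresholds@nAChiMos,
                      D_chi_mos = thresholds@dChiMos),
    excluded_colonies = attr(cls, "excluded"),
    fisher_p = lapply(tests, `[[`, "p.value"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(data = x, truth = truth, pairs = ip, allPairs = ap,
                 thresholds = thresholds, fit = fitInfo,
                 classification = cls, sensitivity = sens,
                 shared = shared, summaries = summaries, tests = tests,
                 manifest = manifest))
}
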