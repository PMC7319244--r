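## Five-category classification of colonies from their intracolonial
## pairwise comparisons.
##
## Decision cascade per colony (evaluable pairs only):
##   1. variable iff some pair has N_A >= 1 (equivalently D > 0);
##   2. non-variable colonies split on min N_L: invariable (>= nLMin)
##      vs possibly_variable;
##   3. variable colonies are chimeric iff some pair exceeds BOTH cutoffs
##      strictly (N_A > nAChiMos AND D > dChiMos); equality at either
##      cutoff, or a discordant pair (one index above, one at/below), is
##      mosaic;
##   4. non-chimeric variable colonies split on min N_L: mosaic vs
##      possibly_chimeric;
##   5. a chimeric colony is also mosaic when some other pair differs
##      mildly (0 < N_A <= nAChiMos or 0 < D <= dChiMos);
##   6. QC flag when the colony is variable at exactly one locus (the
##      single differing locus would be re-amplified to exclude
##      genotyping error; surfaced as a flag only).

.CATEGORIES <- c("invariable", "possibly_variable", "mosaic",
                 "possibly_chimeric", "chimeric")

#' Classify one colony from its pairwise comparisons
#'
#' @param pairs data.frame of one colony's intracolonial comparisons
#'   (columns `N_L`, `N_A`, `D`, `evaluable`, and optionally
#'   `n_diff_loci` for the QC flag).
#' @param thresholds a [ThresholdSet-class].
#' @param dTol absolute tolerance applied to comparisons against the `D`
#'   cutoff, absorbing floating-point noise (default `1e-9`; `D` values
#'   are ratios of dyadic rationals, so this is safety only).
#' @return one-row data.frame with columns `category`, `also_mosaic`,
#'   `qc_single_locus_flag`, `min_NL`, `max_NA`, `max_D`.
#' @export
classifyColony <- function(pairs, thresholds, dTol = 1e-9) {
  ev <- pairs[pairs$evaluable, , drop = FALSE]
  stopIfNot(nrow(ev) >= 1, "no evaluable pair; colony cannot be classified")
  nlOK <- min(ev$N_L) >= thresholds@nLMin
  variable <- any(ev$N_A >= 1)
  chiPair <- ev$N_A > thresholds@nAChiMos &
    ev$D > thresholds@dChiMos + dTol
  if (!variable) {
    category <- if (nlOK) "invariable" else "possibly_variable"
    alsoMosaic <- FALSE
  } else if (any(chiPair)) {
    category <- "chimeric"
    mildPair <- ev$N_A >= 1 &
      (ev$N_A <= thresholds@nAChiMos | ev$D <= thresholds@dChiMos + dTol)
    alsoMosaic <- any(mildPair)
  } else {
    category <- if (nlOK) "mosaic" else "possibly_chimeric"
    alsoMosaic <- FALSE
  }
  qc <- variable && !is.null(ev$n_diff_loci) &&
    max(ev$n_diff_loci) == 1L
  data.frame(category = factor(category, levels = .CATEGORIES),
             also_mosaic = alsoMosaic,
             qc_single_locus_flag = isTRUE(qc),
             min_NL = min(ev$N_L), max_NA = max(ev$N_A),
             max_D = max(ev$D))
}

## connected components of the "identical on comparable loci" relation
## (N_A == 0 edges) among nubbins with at least one evaluable pair
.distinctMLGs <- function(ids, pairs) {
  ev <- pairs[pairs$evaluable, , drop = FALSE]
  keep <- ids[ids %in% c(ev$id_a, ev$id_b)]
  if (!length(keep)) return(NA_integer_)
  parent <- stats::setNames(seq_along(keep), keep)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  same <- ev[ev$N_A == 0, , drop = FALSE]
  for (k in seq_len(nrow(same))) {
    a <- find(match(same$id_a[k], keep))
    b <- find(match(same$id_b[k], keep))
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(keep), find, integer(1))))
}

#' Number of distinct multilocus genotypes within a colony
#'
#' Equivalence classes of nubbins under `N_A = 0` on comparable loci
#' (connected components, since missing data can make the relation
#' non-transitive). Nubbins with no evaluable pair are excluded.
#'
#' @param x a [MicrosatDataset-class].
#' @param colonyId colony identifier.
#' @return Integer count.
#' @export
countDistinctMLGs <- function(x, colonyId) {
  sub <- x[x@samples$colony_id == colonyId, ]
  stopIfNot(nNubbins(sub) >= 2, "colony needs >= 2 nubbins")
  .distinctMLGs(nubbinIds(sub), intracolonialPairs(sub))
}

#' Classify every colony of a dataset
#'
#' Runs the decision cascade on each colony's intracolonial comparisons.
#' Colonies with no evaluable pair are excluded (listed in attribute
#' `"excluded"` and reported), mirroring the removal of colonies in which
#' no nubbin pair shares a locus.
#'
#' @param x a [MicrosatDataset-class].
#' @param thresholds a [ThresholdSet-class].
#' @param dTol see [classifyColony()].
#' @return data.frame with one row per retained colony: `colony_id`,
#'   `site`, `group`, `category`, `also_mosaic`, `n_distinct_mlgs`,
#'   `qc_single_locus_flag`, `min_NL`, `max_NA`, `max_D`. The pair table
#'   is attached as attribute `"pairs"`.
#' @export
classifyDataset <- function(x, thresholds, dTol = 1e-9) {
  ip <- intracolonialPairs(x)
  excluded <- attr(ip, "excluded")
  rows <- list()
  for (cl in unique(ip$colony_id)) {
    if (cl %in% excluded) next
    sub <- ip[ip$colony_id == cl, , drop = FALSE]
    cls <- classifyColony(sub, thresholds, dTol = dTol)
    meta <- x@samples[match(cl, x@samples$colony_id), ]
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(colony_id = cl, site = meta$site, group = meta$group,
                 stringsAsFactors = FALSE),
      cls[, c("category", "also_mosaic")],
      n_distinct_mlgs = .distinctMLGs(
        nubbinIds(x)[x@samples$colony_id == cl], sub),
      cls[, c("qc_single_locus_flag", "min_NL", "max_NA", "max_D")])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "pairs") <- ip
  out
}

#' Threshold sensitivity of the chimera count
#'
#' Re-runs the chimera/mosaic split of the cascade under perturbed
#' thresholds, holding the classification pipeline otherwise fixed, and
#' reports the resulting chimera counts — the chimera count is monotone
#' non-increasing in each threshold component.
#'
#' @param x a [MicrosatDataset-class].
#' @param thresholds baseline [ThresholdSet-class].
#' @param deltaNA integer offsets applied to the `N_A` cutoff (default
#'   `-1:1`); perturbations leaving the cutoff below 1 are skipped with a
#'   warning.
#' @param dValues alternative `D` cutoffs to evaluate at the baseline
#'   `N_A` cutoff (default none).
#' @return data.frame with columns `n_a_chi_mos`, `d_chi_mos`,
#'   `n_chimeric`, `n_variable`, `frac_of_variable`.
#' @export
sensitivityAnalysis <- function(x, thresholds, deltaNA = -1:1,
                                dValues = NULL) {
  grid <- data.frame(
    nA = c(thresholds@nAChiMos + deltaNA,
           rep(thresholds@nAChiMos, length(dValues))),
    d = c(rep(thresholds@dChiMos, length(deltaNA)), dValues))
  bad <- grid$nA < 1
  if (any(bad)) {
    warning("skipping perturbation(s) with N_A cutoff < 1", call. = FALSE)
    grid <- grid[!bad, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cl <- classifyDataset(
      x, thresholdSet(thresholds@nLMin, grid$nA[k], grid$d[k]))
    nVar <- sum(!cl$category %in% c("invariable", "possibly_variable"))
    nChi <- sum(cl$category == "chimeric")
    data.frame(n_a_chi_mos = grid$nA[k], d_chi_mos = grid$d[k],
               n_chimeric = nChi, n_variable = nVar,
               frac_of_variable = if (nVar) nChi / nVar else NA_real_)
  })
  do.call(rbind, rows)
}

#' Complete genotypes shared among variable colonies
#'
#' Cross-references clone matching with the classification: reports every
#' complete multilocus genotype that occurs in two or more variable
#' (mosaic, possibly-chimeric or chimeric) colonies.
#'
#' @param x a [MicrosatDataset-class].
#' @param classification result of [classifyDataset()].
#' @return data.frame with columns `clone_id`, `n_colonies`, `colony_ids`,
#'   `categories`, `sites` (comma-separated lists); zero rows when no
#'   genotype is shared.
#' @export
sharedMLGsAcrossColonies <- function(x, classification) {
  cm <- cloneMatch(x)
  varIds <- classification$colony_id[
    !classification$category %in% c("invariable", "possibly_variable")]
  cm <- cm[cm$colony_id %in% varIds, , drop = FALSE]
  rows <- list()
  for (cid in unique(cm$clone_id)) {
    cols <- unique(cm$colony_id[cm$clone_id == cid])
    if (length(cols) < 2) next
    m <- match(cols, classification$colony_id)
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = cid, n_colonies = length(cols),
      colony_ids = paste(cols, collapse = ","),
      categories = paste(classification$category[m], collapse = ","),
      sites = paste(classification$site[m], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(clone_id = character(0), n_colonies = integer(0),
                      colony_ids = character(0), categories = character(0),
                      sites = character(0)))
  do.call(rbind, rows)
}

#' Write a classification table as TSV
#'
#' @param classification result of [classifyDataset()].
#' @param path output path.
#' @export
writeClassificationTSV <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
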