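## Data-driven decision thresholds.
##
## Two pieces: (1) the minimum number of comparable loci N_L below which an
## all-zero comparison cannot be trusted, chosen from an exact
## combinatorial "false negative" analysis of locus removal; (2) the
## mosaic/chimera cutoffs, placed at the first antimode of the pairwise
## N_A (exact integer histogram) and D (Gaussian KDE) distributions.

#' Locate modes and antimodes of a distance distribution
#'
#' For `kind = "integer"` the exact histogram over the full integer range
#' is scanned: plateaus are collapsed and each interior run lower than both
#' neighbours is an antimode (reported as an interval, e.g. "between 4 and
#' 5"), each run higher than both neighbours a mode. For
#' `kind = "continuous"` the extrema of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth by default, evaluated on a
#' 1000-point grid) are located. The first antimode is the lowest-location
#' local minimum flanked by a mode on each side.
#'
#' @param values numeric observations (e.g. pairwise `N_A` or `D`).
#' @param kind `"integer"` or `"continuous"`.
#' @param bw kernel bandwidth for the continuous kind: a number or a
#'   `stats::density` rule name (default `"nrd0"`, Silverman's rule).
#' @param gridN KDE grid size (default 1000).
#' @param minProminence minimum relative density contrast between
#'   neighbouring extrema (default 0.05): an adjacent mode/antimode pair
#'   whose densities differ by less than this fraction of the larger of
#'   the two — numerical ripples of the KDE, single-count histogram noise
#'   — is merged away before reporting (persistence pruning). A genuine
#'   antimode separating two modes has contrast near 1.
#' @return An object of class `"ModeProfile"`: list with data.frames
#'   `modes` (`location`, `density`) and `antimodes` (`lo`, `hi`,
#'   `location`, `density`), plus `firstAntimode` (numeric location, `NA`
#'   if none), `kind`, `bw`.
#' @export
findModesAntimodes <- function(values, kind = c("integer", "continuous"),
                               bw = "nrd0", gridN = 1000L,
                               minProminence = 0.05) {
  kind <- match.arg(kind)
  stopIfNot(length(values) >= 2 && all(is.finite(values)),
            "need >= 2 finite observations")
  if (kind == "integer") {
    v <- as.integer(round(values))
    rng <- seq(min(v), max(v))
    y <- as.numeric(table(factor(v, levels = rng)))
    x <- as.numeric(rng)
    usedBw <- NA_real_
  } else {
    d <- stats::density(values, bw = bw, n = gridN)
    x <- d$x; y <- d$y
    usedBw <- d$bw
  }

  ## collapse equal-valued runs and classify each run as a local maximum,
  ## local minimum, or neither (shoulder)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  K <- length(r$values)
  ext <- data.frame(kind = character(0), lo = numeric(0), hi = numeric(0),
                    density = numeric(0))
  for (k in seq_len(K)) {
    left <- if (k > 1) r$values[k - 1] else -Inf
    right <- if (k < K) r$values[k + 1] else -Inf
    kind <- if (r$values[k] > left && r$values[k] > right) "mode"
            else if (k > 1 && k < K && r$values[k] < left &&
                     r$values[k] < right) "antimode" else NA
    if (!is.na(kind))
      ext <- rbind(ext, data.frame(kind = kind, lo = x[starts[k]],
                                   hi = x[ends[k]],
                                   density = r$values[k]))
  }
  ## persistence pruning: repeatedly merge the adjacent mode/antimode pair
  ## with the smallest relative density contrast while it falls below the
  ## prominence floor; removes KDE ripples and histogram noise while
  ## leaving genuinely multimodal structure (even a small secondary mode
  ## over a deep gap) untouched
  while (nrow(ext) >= 3) {
    d <- ext$density
    contrast <- abs(diff(d)) / pmax(d[-1], d[-length(d)])
    k <- which.min(contrast)
    if (contrast[k] >= minProminence) break
    ext <- ext[-c(k, k + 1L), , drop = FALSE]
  }
  modes <- ext[ext$kind == "mode", c("lo", "hi", "density"), drop = FALSE]
  modes <- data.frame(location = (modes$lo + modes$hi) / 2,
                      density = modes$density)
  anti <- ext[ext$kind == "antimode", , drop = FALSE]
  anti <- data.frame(lo = anti$lo, hi = anti$hi,
                     location = (anti$lo + anti$hi) / 2,
                     density = anti$density)
  ## an antimode must be flanked by a mode on each side
  if (nrow(anti)) {
    flanked <- vapply(seq_len(nrow(anti)), function(a) {
      any(modes$location < anti$lo[a]) && any(modes$location > anti$hi[a])
    }, logical(1))
    anti <- anti[flanked, , drop = FALSE]
  }
  first <- if (nrow(anti)) anti$location[which.min(anti$location)]
           else NA_real_
  structure(list(modes = modes, antimodes = anti, firstAntimode = first,
                 kind = kind, bw = usedBw),
            class = "ModeProfile")
}

#' @export
print.ModeProfile <- function(x, ...) {
  cat("ModeProfile (", x$kind, ")\n", sep = "")
  cat("  modes at:", paste(signif(x$modes$location, 4), collapse = ", "),
      "\n")
  if (nrow(x$antimodes)) {
    iv <- ifelse(x$antimodes$lo == x$antimodes$hi,
                 signif(x$antimodes$lo, 4),
                 paste0("(", signif(x$antimodes$lo, 4), ", ",
                        signif(x$antimodes$hi, 4), ")"))
    cat("  antimodes at:", paste(iv, collapse = ", "), "\n")
  } else cat("  no antimode (unimodal)\n")
  invisible(x)
}

#' Closed-form locus-removal false-negative probability
#'
#' For a genotype pair differing at exactly `d` of `lTotal` loci, the
#' probability that a uniformly chosen subset of `nL` retained loci misses
#' every differing locus: `choose(lTotal - d, nL) / choose(lTotal, nL)`.
#'
#' @param d number of differing loci (`> 0`).
#' @param nL number of retained (comparable) loci.
#' @param lTotal panel size.
#' @return Probability in `[0, 1]`; vectorized over `d` and `nL`.
#' @export
fnClosedForm <- function(d, nL, lTotal) {
  choose(lTotal - d, nL) / choose(lTotal, nL)
}

#' False-negative curve from exhaustive locus removal
#'
#' Given genotype pairs that are complete at all `lTotal` panel loci and
#' truly variable (`N_A > 0`), estimates for each `N_L` the probability
#' that a pair becomes invariable once `lTotal - N_L` loci are removed:
#' all removal combinations are considered for every pair, and the
#' probability is the number of (pair, combination) events leaving zero
#' detectable difference over the total enumerated. Combinations are
#' enumerated explicitly while `choose(lTotal, lTotal - N_L) <= maxEnum`;
#' beyond that the per-pair closed form [fnClosedForm()] is used, which is
#' exact because detectability depends only on how many differing loci
#' survive.
#'
#' @param x a [MicrosatDataset-class].
#' @param pairs data.frame with columns `id_a`, `id_b`; defaults to all
#'   variable, complete intracolonial pairs of `x`.
#' @param method `"auto"` (default), `"enumerate"` or `"closed_form"`.
#' @param maxEnum enumeration budget per `N_L` (default `1e6`).
#' @return data.frame (class `"FalseNegativeCurve"`) with columns `N_L`,
#'   `probability`, `n_enumerated` (`NA` when the closed form was used),
#'   for `N_L = 1 .. lTotal`; `probability` is checked to be non-increasing
#'   and is exactly 0 at `N_L = lTotal`. Attribute `"n_pairs"` holds the
#'   pair count.
#' @export
falseNegativeCurve <- function(x, pairs = NULL,
                               method = c("auto", "enumerate",
                                          "closed_form"),
                               maxEnum = 1e6) {
  method <- match.arg(method)
  L <- nLoci(x)
  if (is.null(pairs)) {
    ip <- intracolonialPairs(x)
    pairs <- ip[ip$evaluable & ip$N_L == L & ip$N_A > 0,
                c("id_a", "id_b"), drop = FALSE]
  }
  stopIfNot(nrow(pairs) >= 1, "no eligible (complete, variable) pair")

  ## per-pair differing-locus indicators
  ia <- .idx(x, pairs$id_a); ib <- .idx(x, pairs$id_b)
  diffLoci <- matrix(FALSE, nrow(pairs), L)
  for (l in seq_len(L)) {
    p <- x@alleleA[ia, l]; q <- x@alleleB[ia, l]
    r <- x@alleleA[ib, l]; s <- x@alleleB[ib, l]
    if (anyNA(c(p, q, r, s)))
      stop("input pair incomplete at locus ", lociNames(x)[l],
           call. = FALSE)
    diffLoci[, l] <- pmax((p == r) + (q == s), (p == s) + (q == r)) < 2L
  }
  d <- rowSums(diffLoci)
  if (any(d == 0)) stop("non-variable input pair", call. = FALSE)

  res <- data.frame(N_L = seq_len(L), probability = NA_real_,
                    n_enumerated = NA_real_)
  for (nl in seq_len(L)) {
    nRemove <- L - nl
    nComb <- choose(L, nRemove)
    enumerate <- method == "enumerate" ||
      (method == "auto" && nComb <= maxEnum)
    if (enumerate) {
      removals <- utils::combn(L, nRemove)    # nRemove x nComb (or empty)
      miss <- 0L
      for (pr in seq_len(nrow(pairs))) {
        w <- which(diffLoci[pr, ])
        if (nRemove == 0) next
        ## invariable iff the removal covers every differing locus
        covered <- apply(removals, 2, function(rm) all(w %in% rm))
        miss <- miss + sum(covered)
      }
      res$probability[nl] <- miss / (nComb * nrow(pairs))
      res$n_enumerated[nl] <- nComb * nrow(pairs)
    } else {
      res$probability[nl] <- mean(fnClosedForm(d, nl, L))
    }
  }
  stopIfNot(all(diff(res$probability) <= 1e-12),
            "false-negative curve must be non-increasing in N_L")
  stopIfNot(res$probability[L] == 0,
            "false-negative probability must vanish at the full panel")
  attr(res, "n_pairs") <- nrow(pairs)
  attr(res, "L_total") <- L
  class(res) <- c("FalseNegativeCurve", "data.frame")
  res
}

#' Select the comparable-loci threshold N_L_min
#'
#' The smallest `N_L` whose false-negative probability does not exceed
#' `maxFn` (default 20%). When the `N_L` values observed among invariable
#' comparisons are supplied, the first antimode of their distribution is
#' reported alongside as a concordance diagnostic (attribute
#' `"NL_antimode"`).
#'
#' @param curve a [falseNegativeCurve()] result.
#' @param nlValues optional integer vector of observed `N_L` values.
#' @param maxFn tolerated false-negative probability, in (0, 1).
#' @return Integer `N_L_min`.
#' @export
selectNLThreshold <- function(curve, nlValues = NULL, maxFn = 0.20) {
  stopIfNot(maxFn > 0 && maxFn < 1, "maxFn must be in (0, 1)")
  ok <- which(curve$probability <= maxFn)
  if (!length(ok))
    stop("no N_L meets the false-negative bound; a larger locus panel is ",
         "needed", call. = FALSE)
  out <- as.integer(curve$N_L[min(ok)])
  if (!is.null(nlValues) && length(nlValues) >= 2) {
    prof <- findModesAntimodes(nlValues, kind = "integer")
    attr(out, "NL_antimode") <- prof$firstAntimode
  }
  out
}

#' Mosaic/chimera cutoffs from the first antimodes
#'
#' Fits the two genetic-differentiation cutoffs on pairwise comparisons of
#' complete genotypes, restricted to within-cluster strata (`intracolony`
#' and `intracluster`); intercluster and inter-SSH pairs sit at higher
#' distances (putatively unviable chimerism) and are excluded from the
#' fit. The `N_A` cutoff is the floor of the first antimode interval of
#' the exact integer histogram (chimerism requires `N_A` strictly
#' greater); the `D` cutoff is the first-antimode location of the Gaussian
#' KDE. Identical pairs (`N_A = 0`, typically clonemates) are excluded by
#' default: the sought antimode separates mosaic-scale from chimera-scale
#' differentiation, and a large clonal spike at zero can otherwise mask
#' the mosaic mode.
#'
#' @param pairs data.frame from [allPairwise()] (complete genotypes).
#' @param bw KDE bandwidth for `D` (default Silverman's rule `"nrd0"`).
#' @param includeZero keep identical (`N_A = 0`) pairs in the fit
#'   (default `FALSE`).
#' @return list with elements `nAChiMos`, `dChiMos`, and the two
#'   `ModeProfile`s (`profileNA`, `profileD`). If either distribution is
#'   unimodal the corresponding cutoff is `NA` and a warning instructs
#'   supplying thresholds manually.
#' @export
selectChiMosThresholds <- function(pairs, bw = "nrd0",
                                   includeZero = FALSE) {
  keep <- pairs$evaluable &
    pairs$stratum %in% c("intracolony", "intracluster")
  if (!includeZero) keep <- keep & pairs$N_A > 0
  stopIfNot(sum(keep) >= 2, "need >= 2 within-cluster pairs")
  pNA <- findModesAntimodes(pairs$N_A[keep], kind = "integer")
  pD <- findModesAntimodes(pairs$D[keep], kind = "continuous", bw = bw)
  nA <- if (nrow(pNA$antimodes)) floor(pNA$antimodes$lo[1]) else NA_real_
  dT <- pD$firstAntimode
  if (is.na(nA) || is.na(dT))
    warning("unimodal distance distribution: supply thresholds manually",
            call. = FALSE)
  list(nAChiMos = nA, dChiMos = dT, profileNA = pNA, profileD = pD)
}

#' Fit the full threshold set from a dataset
#'
#' Convenience wrapper running the two fitting procedures: the
#' false-negative curve on complete variable intracolonial pairs (yielding
#' `nLMin` at the `maxFn` bound, with the antimode of the invariable-pair
#' `N_L` distribution as a diagnostic) and the antimode cutoffs on all
#' pairwise comparisons of complete genotypes.
#'
#' @param x a [MicrosatDataset-class].
#' @param maxFn false-negative bound for `nLMin` (default 0.20).
#' @param bw KDE bandwidth for the `D` cutoff.
#' @return A [ThresholdSet-class]; fitting diagnostics in attribute
#'   `"fit"` (the curve and mode profiles).
#' @export
fitThresholds <- function(x, maxFn = 0.20, bw = "nrd0") {
  ip <- intracolonialPairs(x)
  curve <- falseNegativeCurve(x)
  invarNL <- ip$N_L[ip$evaluable & ip$N_A == 0]
  nlMin <- selectNLThreshold(curve, nlValues = invarNL, maxFn = maxFn)
  ap <- allPairwise(x, requireComplete = TRUE)
  cm <- selectChiMosThresholds(ap, bw = bw)
  if (is.na(cm$nAChiMos) || is.na(cm$dChiMos))
    stop("could not locate an antimode; supply a ThresholdSet manually",
         call. = FALSE)
  ts <- thresholdSet(nlMin, cm$nAChiMos, cm$dChiMos)
  attr(ts, "fit") <- list(curve = curve, NL_antimode = attr(nlMin,
                          "NL_antimode"), profileNA = cm$profileNA,
                          profileD = cm$profileD)
  ts
}

#' Write a false-negative curve as TSV
#'
#' @param curve a [falseNegativeCurve()] result.
#' @param path output path.
#' @export
writeFNCurveTSV <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
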