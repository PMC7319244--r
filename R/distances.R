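## Pairwise multilocus-genotype differentiation under the two mutation
## models:
##   N_L — number of comparable loci (non-missing in both genotypes),
##   N_A — number of different alleles over comparable loci (infinite
##         allele model),
##   D   — Bruvo's distance (stepwise mutation model): per-allele
##         contribution 1 - 2^(-x) with x the repeat-step difference,
##         summed under the minimum-cost diploid allele pairing and
##         normalized by 2 * N_L.

## Vectorized core: pair statistics for index vectors i, j (same length).
## Loops over loci (small) rather than pairs (large). Per locus the two
## diploid 2-multisets are compared via both within-locus bijections:
## multiset-intersection size = max matches, Bruvo cost = min pairing cost.
.pairStats <- function(x, i, j) {
  A1 <- x@alleleA; A2 <- x@alleleB
  P <- length(i)
  NL <- integer(P); NAcc <- integer(P); S <- numeric(P)
  nDiffLoci <- integer(P)
  for (l in seq_len(ncol(A1))) {
    p <- A1[i, l]; q <- A2[i, l]; r <- A1[j, l]; s <- A2[j, l]
    comp <- !is.na(p) & !is.na(r)
    if (!any(comp)) next
    m1 <- (p == r) + (q == s)
    m2 <- (p == s) + (q == r)
    nal <- 2L - pmax(m1, m2)
    c1 <- bruvoStep(abs(p - r)) + bruvoStep(abs(q - s))
    c2 <- bruvoStep(abs(p - s)) + bruvoStep(abs(q - r))
    cost <- pmin(c1, c2)
    NL <- NL + comp
    add <- comp & nal > 0L
    NAcc[comp] <- NAcc[comp] + nal[comp]
    S[comp] <- S[comp] + cost[comp]
    nDiffLoci <- nDiffLoci + add
  }
  evaluable <- NL > 0L
  data.frame(
    N_L = NL,
    N_A = ifelse(evaluable, NAcc, NA_integer_),
    D = ifelse(evaluable, S / (2 * NL), NA_real_),
    evaluable = evaluable,
    n_diff_loci = ifelse(evaluable, nDiffLoci, NA_integer_))
}

.idx <- function(x, id) {
  i <- if (is.character(id)) match(id, nubbinIds(x)) else id
  if (anyNA(i)) stop("unknown nubbin id", call. = FALSE)
  i
}

#' Number of comparable loci between two nubbins
#'
#' Loci that amplified (are non-missing) in both genotypes.
#'
#' @param x a [MicrosatDataset-class].
#' @param idA,idB nubbin ids (or row indices).
#' @return Integer `N_L` (0 is legal; such a pair is non-evaluable
#'   downstream).
#' @export
comparableLoci <- function(x, idA, idB) {
  .pairStats(x, .idx(x, idA), .idx(x, idB))$N_L
}

#' Number of different alleles between two nubbins (IAM index)
#'
#' Over comparable loci, sums `2 - |multiset intersection|` of the two
#' diploid allele multisets, so a shared homozygote/heterozygote is counted
#' correctly. `NA` with a warning when no locus is comparable.
#'
#' @inheritParams comparableLoci
#' @return Integer `N_A` in `[0, 2 * N_L]`, or `NA` if non-evaluable.
#' @export
nDifferentAlleles <- function(x, idA, idB) {
  st <- .pairStats(x, .idx(x, idA), .idx(x, idB))
  if (!st$evaluable) warning("no comparable locus; pair is non-evaluable",
                             call. = FALSE)
  st$N_A
}

#' Mutation steps between two alleles
#'
#' The number of stepwise-mutation-model steps separating two alleles of
#' one locus: the absolute repeat-count difference. For bp-encoded alleles
#' the bp difference is divided by the motif length; off-ladder differences
#' are an error under the strict policy and are rounded half away from zero
#' (with a warning) under the tolerant policy.
#'
#' @param alleleA,alleleB allele values (repeat counts, or bp sizes when
#'   `encoding = "bp_size"`); vectorized.
#' @param motifLength repeat motif length in bp (used for `bp_size` only).
#' @param encoding `"repeat_count"` (default) or `"bp_size"`.
#' @param policy `"strict"` or `"tolerant"`.
#' @return Non-negative integer step count(s).
#' @export
mutationSteps <- function(alleleA, alleleB, motifLength = 1L,
                          encoding = c("repeat_count", "bp_size"),
                          policy = c("strict", "tolerant")) {
  encoding <- match.arg(encoding)
  policy <- match.arg(policy)
  stopIfNot(!anyNA(alleleA) && !anyNA(alleleB),
            "both alleles must be present")
  d <- abs(alleleA - alleleB)
  if (encoding == "bp_size") d <- d / motifLength
  off <- abs(d - round(d)) > 1e-8
  if (any(off)) {
    if (policy == "strict")
      stop("allele difference not a whole number of ", motifLength,
           " bp repeats; use policy = 'tolerant' to round", call. = FALSE)
    warning(sum(off), " off-ladder difference(s) rounded to the nearest ",
            "repeat", call. = FALSE)
    d <- roundHalfAway(d)
  }
  as.integer(round(d))
}

#' Bruvo's distance between two nubbins (SMM index)
#'
#' For each comparable locus the two diploid genotypes' alleles are paired
#' by the minimum-total-distance bijection (two candidates for diploids);
#' each paired-allele contribution is `1 - 2^(-x)` with `x` the repeat-step
#' difference; the distance is the summed contribution divided by
#' `2 * N_L`, hence in `[0, 1]`.
#'
#' @inheritParams comparableLoci
#' @return Numeric `D`, or `NA` with a warning if no locus is comparable.
#' @export
bruvoDistance <- function(x, idA, idB) {
  st <- .pairStats(x, .idx(x, idA), .idx(x, idB))
  if (!st$evaluable) warning("no comparable locus; pair is non-evaluable",
                             call. = FALSE)
  st$D
}

## stratum of each pair from colony / cluster / SSH labels
.strata <- function(x, i, j) {
  sm <- x@samples
  ssh <- sshLabels(x)
  out <- rep("inter_SSH", length(i))
  out[ssh[i] == ssh[j]] <- "intercluster"
  out[sm$group[i] == sm$group[j]] <- "intracluster"
  out[sm$colony_id[i] == sm$colony_id[j]] <- "intracolony"
  factor(out, levels = c("intracolony", "intracluster", "intercluster",
                         "inter_SSH"))
}

.pairTable <- function(x, i, j) {
  st <- .pairStats(x, i, j)
  data.frame(id_a = nubbinIds(x)[i], id_b = nubbinIds(x)[j],
             colony_a = x@samples$colony_id[i],
             colony_b = x@samples$colony_id[j],
             stratum = .strata(x, i, j), st,
             stringsAsFactors = FALSE)
}

#' All pairwise comparisons among nubbins, stratified
#'
#' Enumerates every unordered nubbin pair (by default restricted to
#' complete genotypes, i.e. no missing locus) and tags each with its
#' stratum: `intracolony` (same colony), `intracluster` (same group label),
#' `intercluster` (same SSH, different group) or `inter_SSH`. Per-stratum
#' counts are attached as attribute `"counts"`. Note that intracolony pairs
#' are, a fortiori, within-cluster: include them when tallying
#' within-cluster comparisons.
#'
#' @param x a [MicrosatDataset-class].
#' @param requireComplete only nubbins with no missing locus enter
#'   (default `TRUE`).
#' @return data.frame with columns `id_a`, `id_b`, `colony_a`, `colony_b`,
#'   `stratum`, `N_L`, `N_A`, `D`, `evaluable`, `n_diff_loci`.
#' @export
allPairwise <- function(x, requireComplete = TRUE) {
  keep <- if (requireComplete) which(isComplete(x)) else seq_len(nNubbins(x))
  n <- length(keep)
  if (n < 2) {
    warning("fewer than 2 eligible nubbins; no pairs", call. = FALSE)
    out <- .pairTable(x, integer(0), integer(0))
    attr(out, "counts") <- table(out$stratum)
    return(out)
  }
  cmb <- utils::combn(keep, 2)
  out <- .pairTable(x, cmb[1, ], cmb[2, ])
  attr(out, "counts") <- table(out$stratum)
  out
}

#' Intracolonial pairwise comparisons
#'
#' All `choose(n, 2)` comparisons between nubbins of the same colony, for
#' every colony. Pairs with no comparable locus are flagged
#' `evaluable = FALSE`; colonies in which no pair is evaluable are listed
#' in attribute `"excluded"` (and reported), since no intracolonial
#' comparison is possible for them.
#'
#' @param x a [MicrosatDataset-class].
#' @return data.frame as in [allPairwise()] (all rows `intracolony`), with
#'   a `colony_id` column first.
#' @export
intracolonialPairs <- function(x) {
  cid <- x@samples$colony_id
  ii <- integer(0); jj <- integer(0)
  for (cl in unique(cid)) {
    w <- which(cid == cl)
    if (length(w) < 2) next
    cmb <- utils::combn(w, 2)
    ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ])
  }
  out <- .pairTable(x, ii, jj)
  out <- cbind(colony_id = out$colony_a, out)
  ev <- tapply(out$evaluable, out$colony_id, any)
  excluded <- names(ev)[!ev]
  if (length(excluded))
    message("colony(ies) with no evaluable nubbin pair: ",
            paste(excluded, collapse = ", "))
  attr(out, "excluded") <- excluded
  out
}

#' Group complete genotypes into clones
#'
#' Exact per-locus multiset equality over the full panel (GenClone-style
#' matching); only complete genotypes participate.
#'
#' @param x a [MicrosatDataset-class].
#' @return data.frame with columns `nubbin_id`, `colony_id`, `clone_id`
#'   (clones numbered by decreasing size, `MLG1` the most frequent);
#'   attribute `"sizes"` holds the clone size table.
#' @export
cloneMatch <- function(x) {
  keep <- which(isComplete(x))
  key <- apply(cbind(x@alleleA[keep, , drop = FALSE],
                     x@alleleB[keep, , drop = FALSE]), 1, paste,
               collapse = "/")
  sizes <- sort(table(key), decreasing = TRUE)
  clone <- paste0("MLG", match(key, names(sizes)))
  out <- data.frame(nubbin_id = nubbinIds(x)[keep],
                    colony_id = x@samples$colony_id[keep],
                    clone_id = clone, stringsAsFactors = FALSE)
  szs <- as.integer(sizes)
  names(szs) <- paste0("MLG", seq_along(sizes))
  attr(out, "sizes") <- szs
  out
}

#' Write a pairwise comparison table as TSV
#'
#' Columns `id_a, id_b, stratum, N_L, N_A, D, evaluable`, with `D` printed
#' at 6 decimals.
#'
#' @param pairs data.frame from [allPairwise()] or [intracolonialPairs()].
#' @param path output path.
#' @export
writePairwiseTSV <- function(pairs, path) {
  out <- pairs[, c("id_a", "id_b", "stratum", "N_L", "N_A", "D",
                   "evaluable")]
  out$D <- ifelse(is.na(out$D), NA, sprintf("%.6f", out$D))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
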