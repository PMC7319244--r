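#' @import methods
NULL

#' MicrosatDataset: replicate-sampled microsatellite genotypes
#'
#' Central container for a panel of diploid microsatellite loci genotyped on
#' nubbins (replicate samples) of colonies. Alleles are stored internally as
#' integer repeat counts in two aligned matrices (`alleleA` <= `alleleB`
#' columnwise within a nubbin); a missing locus has `NA` in both matrices.
#' Half-called genotypes (one readable allele) are coerced to missing at
#' construction, mirroring the treatment of ambiguous peak profiles as
#' missing data wholesale.
#'
#' @slot alleleA,alleleB integer matrices, nubbins x loci, of repeat counts;
#'   `alleleA[i, l] <= alleleB[i, l]` wherever present, both `NA` when the
#'   locus is missing for that nubbin.
#' @slot loci data.frame with columns `name`, `motif_length`, `encoding`
#'   (`"bp_size"` or `"repeat_count"`, recording how the source file encoded
#'   alleles); row order matches the matrix columns.
#' @slot samples data.frame with columns `nubbin_id`, `colony_id`, `site`,
#'   `group` (species/cluster label, e.g. `"SSH05c-1"`) and optional `color`;
#'   row order matches the matrix rows.
#'
#' @export
setClass("MicrosatDataset",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    loci    = "data.frame",
    samples = "data.frame"
  )
)

setValidity("MicrosatDataset", function(object) {
  msgs <- character()
  a <- object@alleleA; b <- object@alleleB
  if (!identical(dim(a), dim(b)))
    msgs <- c(msgs, "alleleA and alleleB must have identical dimensions")
  if (nrow(object@samples) != nrow(a))
    msgs <- c(msgs, "samples rows must match allele matrix rows")
  if (nrow(object@loci) != ncol(a))
    msgs <- c(msgs, "loci rows must match allele matrix columns")
  req <- c("nubbin_id", "colony_id", "site", "group")
  if (!all(req %in% names(object@samples)))
    msgs <- c(msgs, paste("samples must contain columns:",
                          paste(req, collapse = ", ")))
  lreq <- c("name", "motif_length", "encoding")
  if (!all(lreq %in% names(object@loci)))
    msgs <- c(msgs, paste("loci must contain columns:",
                          paste(lreq, collapse = ", ")))
  if (length(msgs)) return(msgs)

  if (anyDuplicated(object@samples$nubbin_id))
    msgs <- c(msgs, "nubbin ids must be unique")
  if (anyDuplicated(object@loci$name))
    msgs <- c(msgs, "locus names must be unique")
  if (any(object@loci$motif_length < 1))
    msgs <- c(msgs, "motif_length must be >= 1")
  if (!all(object@loci$encoding %in% c("bp_size", "repeat_count")))
    msgs <- c(msgs, "locus encoding must be 'bp_size' or 'repeat_count'")
  if (!identical(is.na(a), is.na(b)))
    msgs <- c(msgs, "a locus must be missing in both alleles or neither")
  if (any(a > b, na.rm = TRUE))
    msgs <- c(msgs, "alleleA must be <= alleleB wherever present")
  ## a colony's group label is colony-level metadata: all nubbins must agree
  grp <- tapply(object@samples$group, object@samples$colony_id,
                function(g) length(unique(g)))
  if (any(grp > 1))
    msgs <- c(msgs, paste0("conflicting group labels within colony: ",
      paste(names(grp)[grp > 1], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

## internal constructor: sorts allele pairs, coerces half-calls to missing
newMicrosatDataset <- function(alleleA, alleleB, loci, samples,
                               warnHalfCalls = TRUE) {
  alleleA <- as.matrix(alleleA); alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"; storage.mode(alleleB) <- "integer"
  half <- xor(is.na(alleleA), is.na(alleleB))
  if (any(half)) {
    if (warnHalfCalls)
      warning(sum(half), " half-called genotype(s) coerced to missing",
              call. = FALSE)
    alleleA[half] <- NA_integer_
    alleleB[half] <- NA_integer_
  }
  lo <- pmin(alleleA, alleleB); hi <- pmax(alleleA, alleleB)
  dimnames(lo) <- dimnames(hi) <-
    list(as.character(samples$nubbin_id), as.character(loci$name))
  rownames(samples) <- NULL
  rownames(loci) <- NULL
  new("MicrosatDataset", alleleA = lo, alleleB = hi,
      loci = loci, samples = samples)
}

#' Construct a MicrosatDataset from allele matrices
#'
#' @param alleleA,alleleB numeric matrices (nubbins x loci) of allele values
#'   as integer repeat counts; `NA` marks a missing allele. Pairs are sorted
#'   internally and half-calls are coerced to missing with a warning.
#' @param loci data.frame with columns `name`, `motif_length`, `encoding`;
#'   a character vector of names is accepted and expanded with
#'   `motif_length = 1`, `encoding = "repeat_count"`.
#' @param samples data.frame with columns `nubbin_id`, `colony_id`, `site`,
#'   `group` (and optionally `color`).
#' @return A [MicrosatDataset-class] object.
#' @export
microsatDataset <- function(alleleA, alleleB, loci, samples) {
  if (is.character(loci))
    loci <- data.frame(name = loci, motif_length = 1L,
                       encoding = "repeat_count")
  if (is.null(samples$color)) samples$color <- NA_character_
  newMicrosatDataset(alleleA, alleleB, loci, samples)
}

setMethod("show", "MicrosatDataset", function(object) {
  ns <- nrow(object@samples)
  nc <- length(unique(object@samples$colony_id))
  nl <- nrow(object@loci)
  miss <- mean(is.na(object@alleleA))
  cat("MicrosatDataset:", ns, "nubbins in", nc, "colonies,",
      nl, "loci\n")
  cat("  sites: ", paste(unique(object@samples$site), collapse = ", "), "\n",
      sep = "")
  cat("  groups: ", paste(unique(object@samples$group), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  missing data: %.1f%% of genotype calls\n", 100 * miss))
})

#' ThresholdSet: decision thresholds for the IGV classifier
#'
#' Bundles the three thresholds of the classification cascade: the minimum
#' number of comparable loci `nLMin` below which an all-zero comparison is
#' only "possibly" informative, and the mosaic/chimera cutoffs
#' `nAChiMos` (number of different alleles; chimerism requires strictly
#' more) and `dChiMos` (Bruvo's distance; chimerism requires strictly
#' greater).
#'
#' @slot nLMin integer >= 1.
#' @slot nAChiMos integer >= 1.
#' @slot dChiMos numeric in (0, 1).
#' @export
setClass("ThresholdSet",
  representation(nLMin = "integer", nAChiMos = "integer",
                 dChiMos = "numeric"))

setValidity("ThresholdSet", function(object) {
  msgs <- character()
  if (length(object@nLMin) != 1 || object@nLMin < 1)
    msgs <- c(msgs, "nLMin must be a single integer >= 1")
  if (length(object@nAChiMos) != 1 || object@nAChiMos < 1)
    msgs <- c(msgs, "nAChiMos must be a single integer >= 1")
  if (length(object@dChiMos) != 1 ||
      object@dChiMos <= 0 || object@dChiMos >= 1)
    msgs <- c(msgs, "dChiMos must lie strictly between 0 and 1")
  if (length(msgs)) msgs else TRUE
})

#' Create a ThresholdSet
#'
#' @param nLMin minimum number of comparable loci for a confident
#'   invariable/mosaic call (default 9).
#' @param nAChiMos allele-count cutoff: chimeric pairs have `N_A > nAChiMos`
#'   (default 4).
#' @param dChiMos Bruvo-distance cutoff: chimeric pairs have `D > dChiMos`
#'   (default 0.12).
#' @return A [ThresholdSet-class] object.
#' @export
thresholdSet <- function(nLMin = 9L, nAChiMos = 4L, dChiMos = 0.12) {
  new("ThresholdSet", nLMin = as.integer(nLMin),
      nAChiMos = as.integer(nAChiMos), dChiMos = as.numeric(dChiMos))
}

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet\n")
  cat("  N_L minimum          :", object@nLMin, "loci\n")
  cat("  N_A chimera/mosaic   : >", object@nAChiMos, "alleles\n")
  cat("  D   chimera/mosaic   : >", format(object@dChiMos), "\n")
})
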