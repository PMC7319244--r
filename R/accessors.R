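#' @describeIn MicrosatDataset-class number of nubbins
#' @param x a `MicrosatDataset`
#' @export
nNubbins <- function(x) nrow(x@samples)

#' @describeIn MicrosatDataset-class number of loci in the panel
#' @export
nLoci <- function(x) nrow(x@loci)

#' @describeIn MicrosatDataset-class locus names
#' @export
lociNames <- function(x) x@loci$name

#' @describeIn MicrosatDataset-class nubbin identifiers
#' @export
nubbinIds <- function(x) x@samples$nubbin_id

#' @describeIn MicrosatDataset-class unique colony identifiers
#' @export
colonyIds <- function(x) unique(x@samples$colony_id)

#' @describeIn MicrosatDataset-class per-nubbin metadata data.frame
#' @export
sampleData <- function(x) x@samples

#' @describeIn MicrosatDataset-class locus panel data.frame
#' @export
locusTable <- function(x) x@loci

#' @describeIn MicrosatDataset-class list with the two allele matrices
#'   (`a` and `b`, repeat counts, `a <= b`)
#' @export
alleleMatrices <- function(x) list(a = x@alleleA, b = x@alleleB)

#' @describeIn MicrosatDataset-class logical matrix marking missing loci
#' @export
isMissing <- function(x) is.na(x@alleleA)

#' @describeIn MicrosatDataset-class logical vector: nubbins with no missing
#'   locus
#' @export
isComplete <- function(x) rowSums(is.na(x@alleleA)) == 0L

#' @describeIn MicrosatDataset-class species-hypothesis label per nubbin. If
#'   the samples table carries an `ssh` column it is used; otherwise the SSH
#'   is the group label with any `-`/`_`-separated cluster suffix removed
#'   (e.g. `"SSH05c-1"` -> `"SSH05c"`).
#' @export
sshLabels <- function(x) {
  if (!is.null(x@samples$ssh)) return(x@samples$ssh)
  sub("[-_][^-_]*$", "", x@samples$group)
}

#' Subset a MicrosatDataset by nubbins and/or loci
#'
#' @param x a `MicrosatDataset`.
#' @param i nubbin selector (indices, logical, or nubbin ids).
#' @param j locus selector (indices, logical, or locus names).
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "MicrosatDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nNubbins(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, x@samples$nubbin_id)
  if (is.character(j)) j <- match(j, x@loci$name)
  if (anyNA(i)) stop("unknown nubbin id in subset")
  if (anyNA(j)) stop("unknown locus name in subset")
  new("MicrosatDataset",
      alleleA = x@alleleA[i, j, drop = FALSE],
      alleleB = x@alleleB[i, j, drop = FALSE],
      loci = x@loci[j, , drop = FALSE],
      samples = x@samples[i, , drop = FALSE])
})

#' Mark loci of selected nubbins as missing
#'
#' Utility for masking genotype calls after the fact, e.g. to emulate
#' additional locus dropout in sensitivity experiments.
#'
#' @param x a `MicrosatDataset`.
#' @param nubbins nubbin ids (or indices) to mask.
#' @param loci locus names (or indices) to mask, applied to every selected
#'   nubbin.
#' @return The modified dataset.
#' @export
setMissing <- function(x, nubbins, loci) {
  i <- if (is.character(nubbins)) match(nubbins, x@samples$nubbin_id)
       else nubbins
  j <- if (is.character(loci)) match(loci, x@loci$name) else loci
  if (anyNA(i)) stop("unknown nubbin id")
  if (anyNA(j)) stop("unknown locus name")
  x@alleleA[i, j] <- NA_integer_
  x@alleleB[i, j] <- NA_integer_
  x
}
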