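## Genotype table and locus-configuration I/O.
##
## CSV dialect: UTF-8, comma-separated, header row. Metadata columns
## `colony_id,nubbin_id,site,group,color` are followed by two columns per
## locus, `<locus>_1` and `<locus>_2`, holding integer allele values (bp
## fragment sizes or repeat counts, per the locus config). Missing = empty
## cell or 0; one row per nubbin.

#' Read a locus configuration file
#'
#' A locus config is a CSV with header `name,motif_length,encoding`, one row
#' per locus. `encoding` is `"bp_size"` (alleles are fragment sizes in bp)
#' or `"repeat_count"`.
#'
#' @param path file path.
#' @return data.frame with columns `name`, `motif_length`, `encoding`.
#' @export
readLocusConfig <- function(path) {
  cfg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  req <- c("name", "motif_length", "encoding")
  stopIfNot(all(req %in% names(cfg)),
            "locus config must have columns name, motif_length, encoding")
  cfg$name <- as.character(cfg$name)
  cfg$motif_length <- as.integer(cfg$motif_length)
  stopIfNot(!anyDuplicated(cfg$name), "duplicate locus names in config")
  stopIfNot(all(cfg$motif_length >= 1L), "motif_length must be >= 1")
  stopIfNot(all(cfg$encoding %in% c("bp_size", "repeat_count")),
            "encoding must be bp_size or repeat_count")
  cfg[, req]
}

#' Write a locus configuration file
#'
#' @param loci data.frame as returned by [readLocusConfig()] or
#'   [locusTable()].
#' @param path file path.
#' @export
writeLocusConfig <- function(loci, path) {
  utils::write.csv(loci[, c("name", "motif_length", "encoding")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## convert one locus's allele sizes to repeat counts under a ladder policy;
## the anchor (smallest observed size) makes step differences integral and
## is kept so that writing restores the original bp sizes
.toRepeats <- function(sizes, motif, policy, locus) {
  if (all(is.na(sizes)))
    return(list(rep = sizes, anchor = NA_integer_))
  anchor <- min(sizes, na.rm = TRUE)
  steps <- (sizes - anchor) / motif
  off <- !is.na(steps) & abs(steps - round(steps)) > 1e-8
  if (any(off)) {
    if (policy == "strict")
      stop("allele size(s) off the ", motif, " bp motif ladder at locus ",
           locus, " (e.g. ", sizes[off][1], " vs anchor ", anchor,
           "); use policy = 'tolerant' to round", call. = FALSE)
    warning(sum(off), " off-ladder allele size(s) at locus ", locus,
            " rounded to the nearest repeat", call. = FALSE)
    steps <- roundHalfAway(steps)
  }
  list(rep = as.integer(anchor %/% motif + round(steps)), anchor = anchor)
}

#' Read a genotype table
#'
#' Reads the genotype CSV dialect described above, converts bp-encoded
#' alleles to repeat counts via each locus's motif length, coerces
#' half-called genotypes to missing, groups nubbins into colonies, and
#' checks that all nubbins of a colony carry the same group label.
#' Per-locus missing-data proportions are reported via `message()`.
#'
#' @param path genotype CSV path.
#' @param locusConfig data.frame from [readLocusConfig()], listing every
#'   locus column pair present in the file.
#' @param policy `"strict"` (default): allele sizes not on the motif ladder
#'   are an error; `"tolerant"`: they are rounded to the nearest repeat
#'   (half away from zero) with a warning.
#' @return A [MicrosatDataset-class].
#' @export
readGenotypeTable <- function(path, locusConfig,
                              policy = c("strict", "tolerant")) {
  policy <- match.arg(policy)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA"), strip.white = TRUE)
  meta <- c("colony_id", "nubbin_id", "site", "group")
  stopIfNot(all(meta %in% names(raw)),
            paste("genotype table must have columns:",
                  paste(meta, collapse = ", ")))
  locCols <- setdiff(names(raw), c(meta, "color"))
  wanted <- as.vector(rbind(paste0(locusConfig$name, "_1"),
                            paste0(locusConfig$name, "_2")))
  unknown <- setdiff(locCols, wanted)
  if (length(unknown))
    stop("unknown locus column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(wanted, locCols)
  if (length(absent))
    stop("locus column(s) missing from file: ",
         paste(absent, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  L <- nrow(locusConfig)
  A <- matrix(NA_integer_, n, L)
  B <- matrix(NA_integer_, n, L)
  anchors <- rep(NA_integer_, L)
  for (l in seq_len(L)) {
    a <- suppressWarnings(as.numeric(raw[[paste0(locusConfig$name[l], "_1")]]))
    b <- suppressWarnings(as.numeric(raw[[paste0(locusConfig$name[l], "_2")]]))
    a[!is.na(a) & a == 0] <- NA
    b[!is.na(b) & b == 0] <- NA
    if (locusConfig$encoding[l] == "bp_size") {
      conv <- .toRepeats(c(a, b), locusConfig$motif_length[l], policy,
                         locusConfig$name[l])
      a <- conv$rep[seq_len(n)]
      b <- conv$rep[n + seq_len(n)]
      anchors[l] <- conv$anchor
    }
    A[, l] <- as.integer(a)
    B[, l] <- as.integer(b)
  }

  loci <- locusConfig
  loci$bp_anchor <- anchors
  samples <- data.frame(nubbin_id = as.character(raw$nubbin_id),
                        colony_id = as.character(raw$colony_id),
                        site = as.character(raw$site),
                        group = as.character(raw$group),
                        color = if (is.null(raw$color)) NA_character_
                                else as.character(raw$color),
                        stringsAsFactors = FALSE)
  x <- newMicrosatDataset(A, B, loci, samples)
  mr <- missingnessReport(x)
  message("read ", nNubbins(x), " nubbins / ",
          length(colonyIds(x)), " colonies; per-locus missingness ",
          paste0(sprintf("%s=%.1f%%", mr$locus, 100 * mr$proportion),
                 collapse = ", "))
  x
}

#' Write a genotype table
#'
#' Inverse of [readGenotypeTable()]: emits the same CSV dialect, converting
#' repeat counts back to bp sizes for `bp_size` loci. Homozygotes are
#' written as two equal allele values and missing loci as empty cells, so a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param x a [MicrosatDataset-class].
#' @param path output CSV path.
#' @export
writeGenotypeTable <- function(x, path) {
  out <- x@samples[, c("colony_id", "nubbin_id", "site", "group", "color")]
  for (l in seq_len(nLoci(x))) {
    a <- x@alleleA[, l]; b <- x@alleleB[, l]
    if (x@loci$encoding[l] == "bp_size" && !is.null(x@loci$bp_anchor) &&
        !is.na(x@loci$bp_anchor[l])) {
      motif <- x@loci$motif_length[l]
      anchorRep <- x@loci$bp_anchor[l] %/% motif
      a <- x@loci$bp_anchor[l] + (a - anchorRep) * motif
      b <- x@loci$bp_anchor[l] + (b - anchorRep) * motif
    }
    out[[paste0(x@loci$name[l], "_1")]] <- a
    out[[paste0(x@loci$name[l], "_2")]] <- b
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a GenePop file
#'
#' Convenience reader for the classical GenePop text format with 2- or
#' 3-digit diploid allele codes (`00`/`000` = missing). GenePop carries no
#' colony metadata, so the mapping is conventional: the colony id is the
#' sample id with a trailing `-` or `_` suffix removed (e.g. `C01_a` ->
#' colony `C01`), and each population block supplies both `site` and
#' `group`, labelled `pop1`, `pop2`, ... Adjust [sampleData()] afterwards
#' if other metadata apply.
#'
#' @param path GenePop file path.
#' @param locusConfig optional locus config; defaults to
#'   `repeat_count` encoding with motif length 1 for every locus.
#' @return A [MicrosatDataset-class].
#' @export
readGenePop <- function(path, locusConfig = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stopIfNot(length(lines) >= 3, "GenePop file too short")
  body <- lines[-1]                     # drop title line
  popAt <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  stopIfNot(length(popAt) >= 1, "no 'Pop' line found")
  locLines <- body[seq_len(popAt[1] - 1)]
  locNames <- trimws(unlist(strsplit(locLines, ",")))
  locNames <- locNames[nzchar(locNames)]
  if (is.null(locusConfig))
    locusConfig <- data.frame(name = locNames, motif_length = 1L,
                              encoding = "repeat_count")
  stopIfNot(identical(sort(locusConfig$name), sort(locNames)),
            "locusConfig loci do not match GenePop locus names")
  locusConfig <- locusConfig[match(locNames, locusConfig$name), ]

  ids <- character(); pops <- character(); rows <- list()
  popNo <- 0L
  for (k in seq(popAt[1], length(body))) {
    ln <- body[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      popNo <- popNo + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    stopIfNot(length(parts) == 2, paste("malformed GenePop line:", ln))
    id <- trimws(parts[1])
    gts <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    stopIfNot(length(gts) == length(locNames),
              paste("wrong number of genotypes for sample", id))
    w <- nchar(gts[1]) / 2
    stopIfNot(w %in% c(2, 3), "allele codes must be 2 or 3 digits")
    a <- as.integer(substr(gts, 1, w))
    b <- as.integer(substr(gts, w + 1, 2 * w))
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, paste0("pop", popNo))
    rows[[length(rows) + 1L]] <- list(a = a, b = b)
  }
  A <- do.call(rbind, lapply(rows, `[[`, "a"))
  B <- do.call(rbind, lapply(rows, `[[`, "b"))
  samples <- data.frame(nubbin_id = ids,
                        colony_id = sub("[-_][^-_]*$", "", ids),
                        site = pops, group = pops,
                        color = NA_character_, stringsAsFactors = FALSE)
  newMicrosatDataset(A, B, locusConfig, samples)
}

#' Drop loci from the panel
#'
#' Removes the named loci everywhere (panel and all genotypes), e.g. to
#' discard a locus with suspected genotyping errors before analysis.
#'
#' @param x a [MicrosatDataset-class].
#' @param names character vector of locus names (may be empty).
#' @return The reduced dataset.
#' @export
dropLoci <- function(x, names) {
  if (length(names) == 0) return(x)
  bad <- setdiff(names, lociNames(x))
  if (length(bad))
    stop("unknown locus name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  keep <- setdiff(lociNames(x), names)
  if (length(keep) == 0) stop("cannot drop every locus", call. = FALSE)
  x[, keep]
}

#' Per-locus missing-data report
#'
#' @param x a [MicrosatDataset-class].
#' @return data.frame with columns `locus`, `n_missing`, `n_total`,
#'   `proportion` (missing nubbins over all nubbins, in `[0, 1]`).
#' @export
missingnessReport <- function(x) {
  stopIfNot(nNubbins(x) > 0, "empty dataset")
  nm <- colSums(is.na(x@alleleA))
  data.frame(locus = lociNames(x), n_missing = as.integer(nm),
             n_total = nNubbins(x), proportion = nm / nNubbins(x),
             row.names = NULL)
}

#' Remove nubbins with no readable locus
#'
#' Samples with missing data at every locus cannot enter any comparison and
#' are removed (and reported via `message()`), mirroring the exclusion of
#' unreadable samples during genotyping QC.
#'
#' @param x a [MicrosatDataset-class].
#' @return The filtered dataset; removed nubbin ids in attribute
#'   `"removed"`.
#' @export
dropEmptyNubbins <- function(x) {
  empty <- rowSums(!is.na(x@alleleA)) == 0L
  if (any(empty)) {
    message("removed ", sum(empty), " nubbin(s) with no readable locus: ",
            paste(nubbinIds(x)[empty], collapse = ", "))
    out <- x[!empty, ]
  } else out <- x
  attr(out, "removed") <- nubbinIds(x)[empty]
  out
}
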