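## Ground-truthed synthetic colony generator.
##
## Emulates the study design the analysis assumes: several sites of
## threefold-sampled colonies, a microsatellite panel of ~12 loci, two
## sympatric genetic clusters with shifted allele frequencies (producing a
## multimodal pairwise-distance structure), somatic mutations of 1-2 steps
## creating mosaics, within-cluster fusions creating chimeras, optional
## clonal over-representation of one genotype, and per-locus amplification
## dropout. Every stochastic choice is driven by the configured seed, so a
## fixed config yields a byte-identical dataset.

#' Simulation configuration
#'
#' Defaults reflect the sampling design the pipeline targets: 3 sites x 32
#' colonies x 3 nubbins on a 12-locus panel; two clusters of one species
#' hypothesis with weights 0.85/0.15 and allele-frequency means offset by
#' 5 repeat units; mosaics in 40% of colonies (1-2 mutated alleles of 1-2
#' steps); chimeras in 10% (within-cluster fusions with `N_A > 4` and
#' `D > 0.12` between genets); per-locus dropout rates drawn uniformly in
#' 11.8%-41.7%.
#'
#' @param nSites number of sites.
#' @param coloniesPerSite colonies per site.
#' @param nubbinsPerColony nubbins (replicate samples) per colony.
#' @param nLoci panel size.
#' @param motifLengths integer vector of repeat motif lengths (recycled).
#' @param clusterWeights named numeric vector of cluster sampling weights
#'   (must sum to 1); names are the group labels.
#' @param alleleSD within-cluster SD (repeat units) of the
#'   discretized-normal allele distribution at each locus; the default of
#'   1 repeat unit places within-cluster genet-pair differentiation at the
#'   moderate scale (Bruvo distance around 0.3-0.4) that separates cleanly
#'   from mosaic-scale differences.
#' @param interClusterOffset shift (repeat units) between consecutive
#'   clusters' allele-frequency means.
#' @param cloneFreq probability that a cluster-1 colony is founded by the
#'   cluster's dominant clonal genotype (0 disables clonality).
#' @param mosaicRate per-colony mosaicism probability.
#' @param mosaicAlleles possible numbers of mutated alleles (uniform draw).
#' @param mosaicSteps possible mutation step sizes (uniform draw; sign
#'   random).
#' @param chimeraRate per-colony chimerism probability.
#' @param chimeraMinNA fusion partners are redrawn until their `N_A`
#'   strictly exceeds this.
#' @param chimeraMinD fusion partners are redrawn until their `D` strictly
#'   exceeds this.
#' @param chimeraSplit `"2+1"` (two genets) or `"1+1+1"` (three genets,
#'   needs >= 3 nubbins).
#' @param dropout length-2 range of per-locus missing-call rates; each
#'   locus's rate is drawn uniformly in the range, then applied
#'   independently per nubbin.
#' @param seed integer seed.
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nSites = 3L, coloniesPerSite = 32L,
                             nubbinsPerColony = 3L, nLoci = 12L,
                             motifLengths = c(2L, 3L),
                             clusterWeights = c("SSH05c-1" = 0.85,
                                                "SSH05c-2" = 0.15),
                             alleleSD = 1, interClusterOffset = 5L,
                             cloneFreq = 0, mosaicRate = 0.4,
                             mosaicAlleles = 1:2, mosaicSteps = 1:2,
                             chimeraRate = 0.1, chimeraMinNA = 4L,
                             chimeraMinD = 0.12, chimeraSplit = "2+1",
                             dropout = c(0.118, 0.417), seed = 1L) {
  stopIfNot(abs(sum(clusterWeights) - 1) < 1e-8,
            "cluster weights must sum to 1")
  stopIfNot(all(c(mosaicRate, chimeraRate, dropout) >= 0) &&
            all(c(mosaicRate, chimeraRate, dropout) <= 1) &&
            mosaicRate + chimeraRate <= 1,
            "rates must be probabilities with mosaic + chimera <= 1")
  stopIfNot(chimeraSplit %in% c("2+1", "1+1+1"),
            "chimeraSplit must be '2+1' or '1+1+1'")
  structure(list(
    nSites = as.integer(nSites),
    coloniesPerSite = as.integer(coloniesPerSite),
    nubbinsPerColony = as.integer(nubbinsPerColony),
    nLoci = as.integer(nLoci),
    motifLengths = rep_len(as.integer(motifLengths), nLoci),
    clusterWeights = clusterWeights,
    alleleSD = alleleSD,
    interClusterOffset = as.integer(interClusterOffset),
    cloneFreq = cloneFreq,
    mosaicRate = mosaicRate,
    mosaicAlleles = as.integer(mosaicAlleles),
    mosaicSteps = as.integer(mosaicSteps),
    chimeraRate = chimeraRate,
    chimeraMinNA = as.integer(chimeraMinNA),
    chimeraMinD = chimeraMinD,
    chimeraSplit = chimeraSplit,
    dropout = dropout,
    seed = as.integer(seed)), class = "SimulationConfig")
}

## draw one diploid MLG (2 x nLoci repeat counts) from a cluster's
## discretized-normal allele distributions
.drawMLG <- function(means, sd, nLoci) {
  a <- pmax(2L, as.integer(round(stats::rnorm(nLoci, means, sd))))
  b <- pmax(2L, as.integer(round(stats::rnorm(nLoci, means, sd))))
  rbind(a, b)
}

## N_A and D between two founder MLGs (complete, so N_L = nLoci)
.mlgDist <- function(g1, g2) {
  p <- pmin(g1[1, ], g1[2, ]); q <- pmax(g1[1, ], g1[2, ])
  r <- pmin(g2[1, ], g2[2, ]); s <- pmax(g2[1, ], g2[2, ])
  nA <- sum(2L - pmax((p == r) + (q == s), (p == s) + (q == r)))
  cost <- pmin(bruvoStep(abs(p - r)) + bruvoStep(abs(q - s)),
               bruvoStep(abs(p - s)) + bruvoStep(abs(q - r)))
  c(N_A = nA, D = sum(cost) / (2 * length(p)))
}

#' Generate a synthetic colony dataset with ground truth
#'
#' Builds colonies as follows: a cluster is drawn from the configured
#' weights and the founder genotype from that cluster's per-locus
#' discretized-normal allele distributions (or, with probability
#' `cloneFreq` in cluster 1, the cluster's dominant clone). Mosaic
#' colonies copy the founder to all nubbins, then inject the configured
#' somatic mutations into one randomly chosen nubbin; chimeric colonies
#' draw a second same-cluster founder, redrawing (bounded) until the
#' genet pair satisfies `N_A > chimeraMinNA` and `D > chimeraMinD`, and
#' split the nubbins between the genets; the rest are invariable.
#' Per-locus dropout is applied independently per nubbin at the end.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed` if given.
#' @return list with elements `data` (a [MicrosatDataset-class]), `truth`
#'   (list of data.frames `colonies`, `mutations`, `fusions`) and
#'   `config`.
#' @export
generateDataset <- function(config, seed = config$seed) {
  stopIfNot(inherits(config, "SimulationConfig"), "need a SimulationConfig")
  set.seed(seed)
  L <- config$nLoci
  nPer <- config$nubbinsPerColony
  nCol <- config$nSites * config$coloniesPerSite
  clusters <- names(config$clusterWeights)

  ## cluster allele-frequency means: a common random ladder, shifted per
  ## cluster by the configured offset
  baseMeans <- sample(15:45, L, replace = TRUE)
  clusterMeans <- lapply(seq_along(clusters), function(k)
    baseMeans + (k - 1L) * config$interClusterOffset)
  names(clusterMeans) <- clusters
  dominantClone <- if (config$cloneFreq > 0)
    .drawMLG(clusterMeans[[1]], config$alleleSD, L) else NULL
  dropoutRates <- stats::runif(L, config$dropout[1], config$dropout[2])

  A <- matrix(NA_integer_, nCol * nPer, L)
  B <- matrix(NA_integer_, nCol * nPer, L)
  samples <- data.frame(nubbin_id = character(nCol * nPer),
                        colony_id = character(nCol * nPer),
                        site = character(nCol * nPer),
                        group = character(nCol * nPer),
                        color = NA_character_, stringsAsFactors = FALSE)
  truthCol <- list(); truthMut <- list(); truthFus <- list()

  row <- 0L
  for (s in seq_len(config$nSites)) {
    for (c in seq_len(config$coloniesPerSite)) {
      colonyId <- sprintf("S%d_C%02d", s, c)
      cluster <- sample(clusters, 1, prob = config$clusterWeights)
      means <- clusterMeans[[cluster]]
      clonal <- cluster == clusters[1] && config$cloneFreq > 0 &&
        stats::runif(1) < config$cloneFreq
      founder <- if (clonal) dominantClone
                 else .drawMLG(means, config$alleleSD, L)
      u <- stats::runif(1)
      category <- if (u < config$chimeraRate) "chimeric"
                  else if (u < config$chimeraRate + config$mosaicRate)
                    "mosaic" else "invariable"

      geno <- replicate(nPer, founder, simplify = FALSE)
      if (category == "mosaic") {
        mutNubbin <- sample.int(nPer, 1)
        nMut <- if (length(config$mosaicAlleles) == 1) config$mosaicAlleles
                else sample(config$mosaicAlleles, 1)
        ## distinct (locus, allele-index) slots
        slots <- sample.int(2L * L, nMut)
        for (slot in slots) {
          loc <- ((slot - 1L) %/% 2L) + 1L
          ai <- ((slot - 1L) %% 2L) + 1L
          step <- (if (length(config$mosaicSteps) == 1) config$mosaicSteps
                   else sample(config$mosaicSteps, 1)) *
            sample(c(-1L, 1L), 1)
          geno[[mutNubbin]][ai, loc] <- geno[[mutNubbin]][ai, loc] + step
          truthMut[[length(truthMut) + 1L]] <- data.frame(
            colony_id = colonyId, nubbin = mutNubbin, locus = loc,
            allele_index = ai, step = step)
        }
      } else if (category == "chimeric") {
        partner <- NULL
        for (try in seq_len(100L)) {
          cand <- .drawMLG(means, config$alleleSD, L)
          dd <- .mlgDist(founder, cand)
          if (dd["N_A"] > config$chimeraMinNA &&
              dd["D"] > config$chimeraMinD) { partner <- cand; break }
        }
        if (is.null(partner))
          stop("could not draw a fusion partner with N_A > ",
               config$chimeraMinNA, " and D > ", config$chimeraMinD,
               " within 100 tries; cluster diversity too low",
               call. = FALSE)
        if (config$chimeraSplit == "1+1+1" && nPer >= 3) {
          third <- .drawMLG(means, config$alleleSD, L)
          geno[[2L]] <- partner
          geno[[3L]] <- third
        } else {
          geno[[nPer]] <- partner
        }
        dd <- .mlgDist(founder, partner)
        truthFus[[length(truthFus) + 1L]] <- data.frame(
          colony_id = colonyId, N_A = dd["N_A"], D = dd["D"],
          row.names = NULL)
      }

      for (nb in seq_len(nPer)) {
        row <- row + 1L
        drop <- stats::runif(L) < dropoutRates
        g <- geno[[nb]]
        g[, drop] <- NA_integer_
        A[row, ] <- g[1, ]; B[row, ] <- g[2, ]
        samples$nubbin_id[row] <- sprintf("%s_n%d", colonyId, nb)
        samples$colony_id[row] <- colonyId
        samples$site[row] <- paste0("S", s)
        samples$group[row] <- cluster
      }
      truthCol[[length(truthCol) + 1L]] <- data.frame(
        colony_id = colonyId, site = paste0("S", s), cluster = cluster,
        category = category, clonal_founder = clonal,
        stringsAsFactors = FALSE)
    }
  }

  loci <- data.frame(name = sprintf("L%02d", seq_len(L)),
                     motif_length = config$motifLengths,
                     encoding = "repeat_count",
                     stringsAsFactors = FALSE)
  emptyMut <- data.frame(colony_id = character(0), nubbin = integer(0),
                         locus = integer(0), allele_index = integer(0),
                         step = integer(0))
  emptyFus <- data.frame(colony_id = character(0), N_A = integer(0),
                         D = numeric(0))
  list(data = newMicrosatDataset(A, B, loci, samples,
                                 warnHalfCalls = FALSE),
       truth = list(
         colonies = do.call(rbind, truthCol),
         mutations = if (length(truthMut)) do.call(rbind, truthMut)
                     else emptyMut,
         fusions = if (length(truthFus)) do.call(rbind, truthFus)
                   else emptyFus),
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the genotype CSV and locus config consumed by
#' [readGenotypeTable()], the ground-truth colony table as TSV, and a JSON
#' run manifest echoing the seed and file paths.
#'
#' @param sim result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genotypes = file.path(dir, "genotypes.csv"),
                loci = file.path(dir, "loci.csv"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.json"))
  writeGenotypeTable(sim$data, paths$genotypes)
  writeLocusConfig(locusTable(sim$data), paths$loci)
  utils::write.table(sim$truth$colonies, paths$truth, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = sim$config$seed, files = lapply(paths, basename),
         n_colonies = nrow(sim$truth$colonies),
         n_loci = sim$config$nLoci),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths$manifest)
}

#' Confusion matrix of called vs true colony categories
#'
#' Compares a classification against the generator's ground truth,
#' reporting the truth-by-called contingency over the five categories,
#' sensitivity and specificity of chimera detection, and the empirical
#' miss rate of variability detection stratified by each colony's
#' realized minimum `N_L` (which validates the combinatorial
#' false-negative construction).
#'
#' @param classification result of [classifyDataset()].
#' @param truth `truth$colonies` from [generateDataset()].
#' @return list with `matrix` (5x5 table), `chimeraSensitivity`,
#'   `chimeraSpecificity`, and `fnByNL` (data.frame `min_NL`, `n`,
#'   `miss_rate` over truly variable colonies).
#' @export
truthConfusion <- function(classification, truth) {
  m <- match(classification$colony_id, truth$colony_id)
  if (anyNA(m)) stop("colony ids do not match ground truth", call. = FALSE)
  trueCat <- factor(truth$category[m], levels = .CATEGORIES)
  calledCat <- factor(classification$category, levels = .CATEGORIES)
  tab <- table(truth = trueCat, called = calledCat)
  trueChi <- trueCat == "chimeric"
  calledChi <- calledCat == "chimeric"
  sens <- if (any(trueChi)) mean(calledChi[trueChi]) else NA_real_
  spec <- if (any(!trueChi)) mean(!calledChi[!trueChi]) else NA_real_
  varTruth <- trueCat %in% c("mosaic", "chimeric")
  missed <- calledCat %in% c("invariable", "possibly_variable")
  fn <- if (any(varTruth)) {
    agg <- stats::aggregate(missed[varTruth],
                            by = list(min_NL = classification$min_NL[varTruth]),
                            FUN = mean)
    n <- as.integer(table(classification$min_NL[varTruth]))
    data.frame(min_NL = agg$min_NL, n = n, miss_rate = agg$x)
  } else data.frame(min_NL = integer(0), n = integer(0),
                    miss_rate = numeric(0))
  list(matrix = tab, chimeraSensitivity = sens, chimeraSpecificity = spec,
       fnByNL = fn)
}
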