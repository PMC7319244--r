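# pair-table builder for direct cascade checks
mkPairs <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(N_L = r[1], N_A = r[2], D = r[3], evaluable = TRUE)))
  out$n_diff_loci <- NA_integer_
  out
}
thr <- thresholdSet(9, 4, 0.12)

test_that("the decision cascade assigns the five categories", {
  # identical complete genotypes -> invariable
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 0, 0), c(12, 0, 0), c(12, 0, 0)), thr)$category),
    "invariable")
  # all-zero pairs but one with too few comparable loci -> possibly variable
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 0, 0), c(7, 0, 0), c(12, 0, 0)), thr)$category),
    "possibly_variable")
  # mildly variable at full N_L -> mosaic
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 2, 0.05), c(12, 0, 0), c(12, 2, 0.05)), thr)$category),
    "mosaic")
  # mildly variable with a short comparison -> possibly chimeric
  expect_equal(as.character(classifyColony(
    mkPairs(c(8, 2, 0.05), c(8, 0, 0), c(8, 2, 0.05)), thr)$category),
    "possibly_chimeric")
  # strongly differentiated pair -> chimeric
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 11, 0.33), c(12, 0, 0), c(12, 11, 0.33)), thr)$category),
    "chimeric")
})

test_that("chimerism needs both indices strictly above their cutoffs", {
  # discordant: D above its cutoff but N_A exactly at the allele cutoff
  disc <- classifyColony(mkPairs(c(12, 4, 0.15)), thr)
  expect_equal(as.character(disc$category), "mosaic")
  # equality at the D cutoff is mosaic too
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 6, 0.12)), thr)$category), "mosaic")
  # equality at both
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 4, 0.12)), thr)$category), "mosaic")
  # strictly above both
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 5, 0.1201)), thr)$category), "chimeric")
  # N_A above but D at the cutoff: mosaic (AND rule)
  expect_equal(as.character(classifyColony(
    mkPairs(c(12, 9, 0.12)), thr)$category), "mosaic")
})

test_that("a chimera with a mildly differing third nubbin is also mosaic", {
  cls <- classifyColony(mkPairs(c(12, 11, 0.33), c(12, 1, 0.02),
                                c(12, 11, 0.33)), thr)
  expect_equal(as.character(cls$category), "chimeric")
  expect_true(cls$also_mosaic)
  # without the mild pair the flag stays off
  cls2 <- classifyColony(mkPairs(c(12, 11, 0.33), c(12, 0, 0),
                                 c(12, 11, 0.33)), thr)
  expect_false(cls2$also_mosaic)
})

test_that("colonies without an evaluable pair are rejected or excluded", {
  bad <- data.frame(N_L = 0L, N_A = NA_integer_, D = NA_real_,
                    evaluable = FALSE)
  expect_error(classifyColony(bad, thr), "no evaluable pair")
  g <- matrix(5L, 2, 12)
  x <- genoDataset(list(g, g, g, g), colony = c("C1", "C1", "C2", "C2"))
  x <- setMissing(x, "n1", 1:6)
  x <- setMissing(x, "n2", 7:12)
  cls <- suppressMessages(classifyDataset(x, thr))
  expect_equal(attr(cls, "excluded"), "C1")
  expect_equal(cls$colony_id, "C2")
})

test_that("single-locus variability raises the QC re-amplification flag", {
  g <- matrix(c(10L, 14L), 2, 12)
  g2 <- g; g2[1, 5] <- g2[1, 5] + 1L; g2[2, 5] <- g2[2, 5] + 1L
  x <- genoDataset(list(g, g, g2))
  cls <- classifyDataset(x, thr)
  expect_equal(as.character(cls$category), "mosaic")
  expect_true(cls$qc_single_locus_flag)
  # two mutated loci: no flag
  g3 <- g; g3[1, 5] <- g3[1, 5] + 1L; g3[1, 9] <- g3[1, 9] + 1L
  y <- genoDataset(list(g, g, g3))
  expect_false(classifyDataset(y, thr)$qc_single_locus_flag)
})

test_that("distinct genotypes within a colony are counted as equivalence classes", {
  g <- matrix(c(10L, 14L), 2, 12)
  gm <- g; gm[1, 2] <- gm[1, 2] + 1L
  gm2 <- g; gm2[1, 7] <- gm2[1, 7] + 2L
  expect_equal(countDistinctMLGs(genoDataset(list(g, g, g)), "C1"), 1L)
  expect_equal(countDistinctMLGs(genoDataset(list(g, g, gm)), "C1"), 2L)
  expect_equal(countDistinctMLGs(genoDataset(list(g, gm, gm2)), "C1"), 3L)
})

test_that("classification is invariant to nubbin order within a colony", {
  set.seed(61)
  sim <- generateDataset(simulationConfig(nSites = 1, coloniesPerSite = 30,
                                          mosaicRate = 0.4,
                                          chimeraRate = 0.2,
                                          dropout = c(0.1, 0.3),
                                          seed = 61))
  x <- sim$data
  perm <- sample(nNubbins(x))
  cls1 <- suppressMessages(classifyDataset(x, thr))
  cls2 <- suppressMessages(classifyDataset(x[perm, ], thr))
  cls2 <- cls2[match(cls1$colony_id, cls2$colony_id), ]
  expect_equal(as.character(cls1$category), as.character(cls2$category))
  expect_equal(cls1$also_mosaic, cls2$also_mosaic)
  expect_equal(cls1$n_distinct_mlgs, cls2$n_distinct_mlgs)
})

test_that("the five categories partition the retained colonies", {
  sim <- generateDataset(simulationConfig(nSites = 2, coloniesPerSite = 40,
                                          dropout = c(0.1, 0.4), seed = 77))
  cls <- suppressMessages(classifyDataset(sim$data, thr))
  expect_equal(sum(table(cls$category)), nrow(cls))
  expect_equal(nrow(cls) + length(attr(cls, "excluded")),
               length(colonyIds(sim$data)))
  expect_false(any(is.na(cls$category)))
})

test_that("the chimera count is monotone non-increasing in each threshold", {
  sim <- generateDataset(simulationConfig(nSites = 1, coloniesPerSite = 60,
                                          mosaicRate = 0.4,
                                          chimeraRate = 0.3,
                                          dropout = c(0, 0.2), seed = 83))
  x <- sim$data
  sens <- suppressMessages(
    sensitivityAnalysis(x, thr, deltaNA = -2:2,
                        dValues = c(0.083, 0.146, 0.3)))
  byNA <- sens[sens$d_chi_mos == thr@dChiMos, ]
  expect_true(all(diff(byNA$n_chimeric[order(byNA$n_a_chi_mos)]) <= 0))
  byD <- sens[sens$n_a_chi_mos == thr@nAChiMos, ]
  expect_true(all(diff(byD$n_chimeric[order(byD$d_chi_mos)]) <= 0))
  # identity perturbation reproduces the baseline count
  base <- sum(suppressMessages(
    classifyDataset(x, thr))$category == "chimeric")
  expect_equal(byNA$n_chimeric[byNA$n_a_chi_mos == thr@nAChiMos], base)
})

test_that("raising the allele cutoff to the planted fusion level removes chimeras", {
  cfg <- simulationConfig(nSites = 1, coloniesPerSite = 40,
                          mosaicRate = 0, chimeraRate = 1,
                          chimeraMinNA = 6, dropout = c(0, 0), seed = 97)
  sim <- generateDataset(cfg)
  fusNA <- sim$truth$fusions$N_A
  hi <- max(fusNA)
  sens <- suppressMessages(sensitivityAnalysis(
    sim$data, thresholdSet(9, 6, 0.12), deltaNA = c(0, hi - 6)))
  expect_equal(sens$n_chimeric[1], 40L)
  expect_equal(sens$n_chimeric[2], 0L)
})

test_that("a permissive recruit-style rule inflates the chimera fraction in adults", {
  # adult colonies accumulate >= 2 somatic changes; calling any pair with
  # N_A >= 2 chimeric then absorbs most mosaics into the chimera class
  cfg <- simulationConfig(nSites = 1, coloniesPerSite = 80,
                          mosaicRate = 0.5, mosaicAlleles = 2L,
                          chimeraRate = 0.1, dropout = c(0, 0), seed = 29)
  sim <- generateDataset(cfg)
  strictRule <- suppressMessages(classifyDataset(sim$data, thr))
  recruitRule <- suppressMessages(classifyDataset(
    sim$data, thresholdSet(9, 1, 1e-6)))
  fracStrict <- mean(strictRule$category == "chimeric")
  fracRecruit <- mean(recruitRule$category == "chimeric")
  expect_gt(fracRecruit, fracStrict + 0.3)
})

test_that("genotypes shared among variable colonies are tabulated", {
  g <- matrix(c(10L, 14L), 2, 12)
  gm <- g; gm[1, 2] <- gm[1, 2] + 1L
  far <- matrix(c(30L, 34L), 2, 12)
  # C1 and C2 are chimeras sharing founder g; C3 is invariable elsewhere
  x <- genoDataset(list(g, far, g, far, gm, gm),
                   colony = c("C1", "C1", "C2", "C2", "C3", "C3"),
                   ids = paste0("n", 1:6))
  cls <- classifyDataset(x, thr)
  sh <- sharedMLGsAcrossColonies(x, cls)
  expect_equal(nrow(sh), 2L)   # founder g and partner far both shared
  expect_true(all(sh$n_colonies == 2L))
  expect_true(any(grepl("C1", sh$colony_ids) & grepl("C2", sh$colony_ids)))
  # invariable colonies never appear
  expect_false(any(grepl("C3", sh$colony_ids)))
})
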