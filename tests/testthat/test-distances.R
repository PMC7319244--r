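test_that("comparable-locus counting handles missingness, including disjoint support", {
  g1 <- matrix(10L, 2, 12); g2 <- matrix(10L, 2, 12)
  x <- genoDataset(list(g1, g2))
  expect_equal(comparableLoci(x, "n1", "n2"), 12L)
  x2 <- setMissing(x, "n1", 1:3)
  expect_equal(comparableLoci(x2, "n1", "n2"), 9L)
  x3 <- setMissing(setMissing(x, "n1", 1:6), "n2", 7:12)
  expect_equal(comparableLoci(x3, "n1", "n2"), 0L)
  expect_warning(nDifferentAlleles(x3, "n1", "n2"), "non-evaluable")
  expect_warning(expect_true(is.na(bruvoDistance(x3, "n1", "n2"))))
})

test_that("N_A counts different alleles by per-locus multiset intersection", {
  # one locus {100,104} vs {100,108} shares one allele
  x <- genoDataset(list(rbind(100L, 104L), rbind(100L, 108L)))
  expect_equal(nDifferentAlleles(x, "n1", "n2"), 1L)
  # fully disjoint diploid locus contributes 2; 12 such loci reach 2*N_L
  g1 <- matrix(c(100L, 104L), 2, 12); g2 <- matrix(c(108L, 112L), 2, 12)
  y <- genoDataset(list(g1, g2))
  expect_equal(nDifferentAlleles(y, "n1", "n2"), 24L)
  # identical genotypes give zero
  z <- genoDataset(list(g1, g1))
  expect_equal(nDifferentAlleles(z, "n1", "n2"), 0L)
  # shared homozygote vs heterozygote counted through the multiset
  w <- genoDataset(list(rbind(7L, 7L), rbind(7L, 9L)))
  expect_equal(nDifferentAlleles(w, "n1", "n2"), 1L)
})

test_that("N_A matches a brute-force multiset oracle on random genotypes", {
  set.seed(101)
  for (rep in 1:40) {
    g1 <- randomGeno(5, missingP = 0.2)
    g2 <- randomGeno(5, missingP = 0.2)
    if (all(is.na(g1[1, ]) | is.na(g2[1, ]))) next
    x <- genoDataset(list(g1, g2))
    expect_equal(nDifferentAlleles(x, "n1", "n2"), oracleNA(g1, g2))
  }
})

test_that("Bruvo distance uses the minimum-cost diploid allele pairing", {
  # (100,104) vs (102,104), motif 2 -> repeats (50,52) vs (51,52):
  # pairing costs {0.5, 1.25}; the minimum gives D = 0.5/2 = 0.25
  x <- genoDataset(list(rbind(50L, 52L), rbind(51L, 52L)))
  expect_equal(bruvoDistance(x, "n1", "n2"), 0.25)
})

test_that("Bruvo distance reproduces the published worked configurations", {
  # four alleles differing by two steps each over 12 loci
  d1 <- offsetPair(list(c(1, 1, 2), c(2, 1, 2), c(3, 1, 2), c(4, 1, 2)))
  expect_equal(bruvoDistance(d1, "a", "b"), 0.125)
  # two alleles by one step plus two by four steps
  d2 <- offsetPair(list(c(1, 1, 1), c(2, 1, 1), c(3, 1, 4), c(4, 1, 4)))
  expect_equal(round(bruvoDistance(d2, "a", "b"), 3), 0.120)
  # the alternative configuration printed for the same value:
  # two alleles by five steps plus one by four steps
  d2b <- offsetPair(list(c(1, 1, 5), c(2, 1, 5), c(3, 1, 4)))
  expect_equal(bruvoDistance(d2b, "a", "b"), bruvoDistance(d2, "a", "b"))
})

test_that("minimum-pairing Bruvo equals brute-force bijection search (<= 3 loci)", {
  set.seed(202)
  for (nL in 1:3) for (rep in 1:25) {
    g1 <- randomGeno(nL); g2 <- randomGeno(nL)
    x <- genoDataset(list(g1, g2))
    expect_equal(bruvoDistance(x, "n1", "n2"), oracleBruvo(g1, g2))
  }
})

test_that("distance indices are symmetric, zero-equivalent and bounded", {
  set.seed(303)
  for (rep in 1:25) {
    g1 <- randomGeno(8, missingP = 0.15)
    g2 <- randomGeno(8, missingP = 0.15)
    if (all(is.na(g1[1, ]) | is.na(g2[1, ]))) next
    x <- genoDataset(list(g1, g2))
    nA <- nDifferentAlleles(x, "n1", "n2")
    nAr <- nDifferentAlleles(x, "n2", "n1")
    D <- bruvoDistance(x, "n1", "n2")
    expect_identical(nA, nAr)
    expect_equal(D, bruvoDistance(x, "n2", "n1"))
    expect_true(D >= 0 && D <= 1)
    expect_true(nA >= 0 && nA <= 2 * comparableLoci(x, "n1", "n2"))
    expect_equal(nA == 0, D == 0)
  }
})

test_that("D increases strictly with the step count of a differing allele", {
  ds <- vapply(1:8, function(k) {
    bruvoDistance(offsetPair(list(c(1, 1, k))), "a", "b")
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  # adding a differing allele increases both indices
  one <- offsetPair(list(c(1, 1, 2)))
  two <- offsetPair(list(c(1, 1, 2), c(2, 1, 2)))
  expect_true(nDifferentAlleles(two, "a", "b") >
              nDifferentAlleles(one, "a", "b"))
  expect_true(bruvoDistance(two, "a", "b") > bruvoDistance(one, "a", "b"))
})

test_that("D approaches 1 as every allele diverges by many steps", {
  g1 <- matrix(c(10L, 12L), 2, 12)
  g2 <- matrix(c(500L, 600L), 2, 12)
  x <- genoDataset(list(g1, g2))
  expect_equal(nDifferentAlleles(x, "n1", "n2"), 24L)
  expect_gt(bruvoDistance(x, "n1", "n2"), 1 - 1e-9)
  expect_lte(bruvoDistance(x, "n1", "n2"), 1)
})

test_that("restricting the panel never increases N_A", {
  set.seed(404)
  for (rep in 1:20) {
    g1 <- randomGeno(10); g2 <- randomGeno(10)
    x <- genoDataset(list(g1, g2))
    full <- nDifferentAlleles(x, "n1", "n2")
    sub <- sample(10, 6)
    xs <- x[, sort(sub)]
    expect_lte(nDifferentAlleles(xs, "n1", "n2"), full)
  }
})

test_that("stratified pair counts match the two-cluster and two-SSH designs", {
  set.seed(7)
  x <- strataDataset(c(rep("SSH05c-1", 99), rep("SSH05c-2", 17)))
  ap <- allPairwise(x)
  counts <- attr(ap, "counts")
  expect_equal(nrow(ap), 6670L)
  expect_equal(as.integer(counts["intracluster"]), 4987L)
  expect_equal(as.integer(counts["intercluster"]), 1683L)
  expect_equal(as.integer(counts["inter_SSH"]), 0L)

  y <- strataDataset(c(rep("SSH05c-1", 99), rep("SSH05c-2", 17),
                       rep("SSH13a", 4)), nL = 11)
  apy <- allPairwise(y)
  expect_equal(as.integer(attr(apy, "counts")["inter_SSH"]), 464L)

  z <- strataDataset(rep("G1", 2))
  expect_equal(nrow(allPairwise(z)), 1L)
})

test_that("only complete genotypes enter all-pairwise comparisons", {
  x <- strataDataset(rep("G1", 5))
  x <- setMissing(x, "N001", 1)
  ap <- allPairwise(x, requireComplete = TRUE)
  expect_equal(nrow(ap), choose(4, 2))
  expect_false("N001" %in% c(ap$id_a, ap$id_b))
  expect_warning(allPairwise(x[1, ]), "fewer than 2")
})

test_that("intracolonial pairs enumerate within-colony comparisons", {
  g <- matrix(c(10L, 12L), 2, 12)
  x <- genoDataset(list(g, g, g))
  ip <- intracolonialPairs(x)
  expect_equal(nrow(ip), 3L)
  expect_equal(ip$N_L, rep(12L, 3))
  expect_equal(ip$N_A, rep(0L, 3))
  expect_equal(ip$D, rep(0, 3))
  expect_true(all(ip$stratum == "intracolony"))
})

test_that("colonies whose nubbins share no locus are flagged for exclusion", {
  g <- matrix(5L, 2, 12)
  x <- genoDataset(list(g, g, g, g),
                   colony = c("C1", "C1", "C2", "C2"))
  x <- setMissing(x, "n1", 1:6)
  x <- setMissing(x, "n2", 7:12)
  expect_message(ip <- intracolonialPairs(x), "C1")
  expect_equal(attr(ip, "excluded"), "C1")
  expect_false(ip$evaluable[ip$colony_id == "C1"])
})

test_that("clone matching groups identical complete genotypes", {
  g <- matrix(c(10L, 14L), 2, 12)
  g2 <- g; g2[1, 3] <- g2[1, 3] + 1L   # one allele, one step away
  x <- genoDataset(list(g, g, g2), colony = c("C1", "C2", "C3"))
  cm <- cloneMatch(x)
  expect_equal(cm$clone_id[1], cm$clone_id[2])
  expect_false(cm$clone_id[3] == cm$clone_id[1])
  expect_equal(as.integer(attr(cm, "sizes")[1]), 2L)
})

test_that("a planted dominant clone is recovered at its planted frequency", {
  cfg <- simulationConfig(nSites = 1, coloniesPerSite = 120,
                          clusterWeights = c("SSH05c-1" = 1),
                          cloneFreq = 0.81, mosaicRate = 0,
                          chimeraRate = 0, dropout = c(0, 0), seed = 31)
  sim <- generateDataset(cfg)
  cm <- cloneMatch(sim$data)
  planted <- sum(sim$truth$colonies$clonal_founder) * 3L
  expect_equal(as.integer(attr(cm, "sizes")[1]), planted)
  # and the planted fraction sits near the configured 81%
  expect_lt(abs(planted / nNubbins(sim$data) - 0.81), 0.12)
})

test_that("pairwise TSV output prints D at six decimals", {
  x <- offsetPair(list(c(1, 1, 1)))
  ap <- allPairwise(x)
  f <- file.path(tempdir(), "pairs.tsv")
  writePairwiseTSV(ap, f)
  tab <- read.delim(f, colClasses = "character")
  expect_match(tab$D[1], "^0\\.0208(33)?[0-9]*$")
  expect_equal(nchar(sub(".*\\.", "", tab$D[1])), 6L)
})
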