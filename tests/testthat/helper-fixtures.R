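# Fixture builders and independent oracles used across the suite.

# Two-nubbin dataset over nL loci. Both nubbins start as the same
# heterozygote (10, 20) at every locus; `offsets` is a list of
# c(locus, alleleIndex, steps) perturbations applied to nubbin "b".
offsetPair <- function(offsets = list(), nL = 12L) {
  A1 <- matrix(10L, 2, nL)
  A2 <- matrix(20L, 2, nL)
  for (o in offsets) {
    if (o[2] == 1) A1[2, o[1]] <- A1[2, o[1]] + o[3]
    else A2[2, o[1]] <- A2[2, o[1]] + o[3]
  }
  microsatDataset(A1, A2, sprintf("L%02d", seq_len(nL)),
                  data.frame(nubbin_id = c("a", "b"), colony_id = "C1",
                             site = "S1", group = "G1"))
}

# Dataset from explicit per-nubbin genotype lists: `genos` is a list of
# 2 x nL matrices (rows = the two alleles), NA = missing.
genoDataset <- function(genos, colony = rep("C1", length(genos)),
                        group = rep("G1", length(genos)),
                        site = rep("S1", length(genos)),
                        ids = paste0("n", seq_along(genos))) {
  A <- do.call(rbind, lapply(genos, function(g) g[1, ]))
  B <- do.call(rbind, lapply(genos, function(g) g[2, ]))
  microsatDataset(A, B, sprintf("L%02d", seq_len(ncol(A))),
                  data.frame(nubbin_id = ids, colony_id = colony,
                             site = site, group = group))
}

# Independent N_A oracle: per-locus multiset intersection via table().
oracleNA <- function(g1, g2) {
  total <- 0L
  for (l in seq_len(ncol(g1))) {
    a <- g1[, l]; b <- g2[, l]
    if (anyNA(a) || anyNA(b)) next
    ta <- table(a); tb <- table(b)
    shared <- sum(pmin(ta[names(ta)], ifelse(is.na(tb[names(ta)]), 0,
                                             tb[names(ta)])))
    total <- total + (2L - shared)
  }
  total
}

# Independent Bruvo oracle: global minimization over every combination of
# per-locus allele bijections (2 per diploid locus), enumerated explicitly.
oracleBruvo <- function(g1, g2) {
  f <- function(x) 1 - 2^(-x)
  comp <- which(!is.na(g1[1, ]) & !is.na(g2[1, ]))
  if (!length(comp)) return(NA_real_)
  perLocus <- lapply(comp, function(l) {
    a <- g1[, l]; b <- g2[, l]
    c(f(abs(a[1] - b[1])) + f(abs(a[2] - b[2])),
      f(abs(a[1] - b[2])) + f(abs(a[2] - b[1])))
  })
  choices <- expand.grid(rep(list(1:2), length(comp)))
  best <- Inf
  for (r in seq_len(nrow(choices))) {
    tot <- sum(vapply(seq_along(comp),
                      function(k) perLocus[[k]][choices[r, k]], numeric(1)))
    best <- min(best, tot)
  }
  best / (2 * length(comp))
}

# Random diploid genotype matrix (2 x nL) on a modest repeat ladder.
randomGeno <- function(nL, missingP = 0) {
  g <- matrix(sample(10:20, 2 * nL, replace = TRUE), 2, nL)
  if (missingP > 0) {
    drop <- runif(nL) < missingP
    g[, drop] <- NA_integer_
  }
  g
}

# One-nubbin-per-colony dataset of complete random genotypes, for
# stratified pair counting.
strataDataset <- function(groups, nL = 12L) {
  n <- length(groups)
  genos <- replicate(n, randomGeno(nL), simplify = FALSE)
  genoDataset(genos, colony = sprintf("C%03d", seq_len(n)),
              group = groups, site = rep("S1", n),
              ids = sprintf("N%03d", seq_len(n)))
}
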