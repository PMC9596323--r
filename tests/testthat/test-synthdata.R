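# Synthetic cohort generators: pedigree structure, Mendelian gene
# dropping, amplicon read pools, dyadic count tables.

test_that("pedigree generator handles degenerate and structured cases", {
  ped0 <- simulatePedigree(simConfig(n_founders = 2, n_generations = 0),
                           seed = 1)
  expect_equal(nrow(ped0), 2L)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))

  # determinism under seed
  cfg <- simConfig(n_founders = 4, n_generations = 2)
  expect_identical(simulatePedigree(cfg, seed = 1),
                   simulatePedigree(cfg, seed = 1))

  # every non-founder has two parents from strictly earlier generations
  ped <- simulatePedigree(simConfig(n_founders = 10, n_generations = 3),
                          seed = 7)
  expect_silent(validatePedigree(ped))
  kids <- ped[ped$generation > 0, ]
  for (i in seq_len(nrow(kids))) {
    for (par in c(kids$sire[i], kids$dam[i])) {
      expect_false(is.na(par))
      expect_lt(ped$generation[ped$id == par], kids$generation[i])
    }
  }
  sires <- ped$sex[match(kids$sire, ped$id)]
  dams <- ped$sex[match(kids$dam, ped$id)]
  expect_true(all(sires == "M") && all(dams == "F"))
})

test_that("gene dropping is Mendelian-consistent at zero error rate", {
  cfg <- simConfig(n_founders = 8, n_generations = 2, n_sites = 300,
                   genotyping_error = 0)
  ped <- simulatePedigree(cfg, seed = 3)
  g <- genotypes(simulateSnpGenotypes(ped, cfg, seed = 4))
  kids <- which(!is.na(ped$sire))
  for (i in kids) {
    s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
    ok <- vapply(seq_len(ncol(g)), function(j)
      mendelian_ok(g[i, j], g[s, j], g[d, j]), logical(1))
    expect_true(all(ok))
  }
})

test_that("founder genotypes follow the configured MAF law", {
  # point mass at 0.5: expected heterozygosity 2pq = 0.5
  cfg <- simConfig(n_founders = 60, n_generations = 0, n_sites = 10000,
                   maf_min = 0.5, maf_max = 0.5)
  g <- simulateSnpGenotypes(simulatePedigree(cfg, seed = 5), cfg, seed = 6)
  expect_equal(mean(heterozygosity(g)), 0.5, tolerance = 0.01)

  # chi-square goodness of fit of founder genotype counts to HWE at p=0.3
  cfg2 <- simConfig(n_founders = 50, n_generations = 0, n_sites = 10000,
                    maf_min = 0.3, maf_max = 0.3)
  calls <- genotypes(simulateSnpGenotypes(simulatePedigree(cfg2, seed = 7),
                                          cfg2, seed = 8))
  obs <- table(factor(calls, levels = 0:2))
  p <- 0.3
  expected <- length(calls) * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_gt(pchisq(chi2, df = 2, lower.tail = FALSE), 0.001)
})

test_that("LD blocks duplicate one variant and errors break them", {
  cfg <- simConfig(n_founders = 40, n_generations = 0, n_sites = 50,
                   ld_block_size = 5, genotyping_error = 0)
  g <- simulateSnpGenotypes(simulatePedigree(cfg, seed = 9), cfg, seed = 10)
  calls <- genotypes(g)
  blocks <- siteInfo(g)$block
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    expect_true(all(calls[, cols] == calls[, cols[1]]))
  }
  # determinism of the full genotype stage
  g2 <- simulateSnpGenotypes(simulatePedigree(cfg, seed = 9), cfg, seed = 10)
  expect_identical(genotypes(g), genotypes(g2))
})

test_that("noise-free amplicon pools reproduce the truth exactly", {
  truth <- c(rand_dna(60), rand_dna(60), rand_dna(60))
  spec <- mhcSimSpec(depth_mean = 1000, depth_sd = 0, error_rate = 0,
                     chimera_rate = 0)
  pool <- simulateAmpliconReads(truth, "i1", "A", spec, seed = 11)
  expect_setequal(pool@sequences, truth)
  expect_true(all(pool@copies == 1000L))
  expect_error(simulateAmpliconReads(character(0), "i1", "A", spec),
               "empty truth")
})

test_that("per-base errors and chimeras appear at their expected rates", {
  L <- 195L
  truth <- c(rand_dna(L), rand_dna(L))
  spec <- mhcSimSpec(depth_mean = 5000, depth_sd = 0, error_rate = 0.001,
                     chimera_rate = 0)
  pool <- simulateAmpliconReads(truth, "i1", "A", spec, seed = 12)
  clean <- sum(pool@copies[pool@sequences %in% truth])
  # fraction of error-free reads ~ 0.999^195 ~ 0.823
  expect_equal(clean / sum(pool@copies), 0.999^L, tolerance = 0.02)

  # chimeras at 2%: each unique artifact stays far below the 5% threshold
  spec2 <- mhcSimSpec(depth_mean = 5000, depth_sd = 0, error_rate = 0,
                      chimera_rate = 0.02)
  for (s in 1:5) {
    p2 <- simulateAmpliconReads(truth, "i1", "A", spec2, seed = 100 + s)
    art <- !p2@sequences %in% truth
    expect_true(all(p2@copies[art] / sum(p2@copies) < 0.05))
  }
})

test_that("dyadic count simulator matches its Poisson law", {
  phi <- matrix(0, 40, 40)
  K <- KinshipMatrix(phi)
  # intercept-only: mean count = exp(intercept)
  d0 <- simulateDyadicCounts(K, beta_kinship = 0, beta_total = 0,
                             intercept = log(2), totals = 0, seed = 13)
  expect_equal(mean(d0$count), 2, tolerance = 0.1)

  # beta_kinship = 0: fitted kinship effect is null
  phi2 <- matrix(rnorm(40 * 40, 0, 0.1), 40, 40)
  phi2 <- (phi2 + t(phi2)) / 2
  K2 <- KinshipMatrix(phi2)
  d1 <- simulateDyadicCounts(K2, beta_kinship = 0, beta_total = 0,
                             intercept = 1, totals = 0, seed = 14)
  fit <- glm(count ~ kinship, data = d1, family = poisson())
  expect_gt(summary(fit)$coefficients["kinship", "Pr(>|z|)"], 0.01)
})
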