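# Statistical layer: power solver, BH, VIF, kinship LMM, robust Poisson.

test_that("power solver inverts the noncentral-F power function", {
  for (pw in c(0.8, 0.5, 0.1)) {
    f2 <- powerMinEffect(1, 20, 0.05, pw)
    expect_equal(powerF2(f2, 1, 20, 0.05), pw, tolerance = 1e-8)
  }
  # strictly increasing in target power
  f2s <- vapply(seq(0.1, 0.9, by = 0.1),
                function(p) powerMinEffect(1, 20, 0.05, p), numeric(1))
  expect_true(all(diff(f2s) > 0))
  # boundary: power at (or below) alpha needs no effect
  expect_equal(powerMinEffect(1, 20, 0.05, 0.05), 0)
  expect_lt(powerMinEffect(1, 20, 0.05, 0.0501), 1e-3)
})

test_that("BH adjustment follows the step-up formula", {
  # hand-applied step-up on (0.01, 0.02, 0.03, 0.04): p_(i) * 4 / i,
  # cummin from the largest -> all 0.04
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  # flat already-adjusted sequences are fixed points
  expect_equal(bhAdjust(rep(0.04, 4)), rep(0.04, 4))
})

test_that("VIF reflects predictor collinearity exactly", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)   # orthogonal to x1
  expect_equal(unname(vif(cbind(x1, x2))), c(1, 1))
  expect_true(is.infinite(vif(cbind(x1, x1))[1]))
  # empirical correlation exactly 0.6 -> VIF = 1/(1-0.36) = 1.5625
  x3 <- 0.6 * x1 + sqrt(1 - 0.36) * x2
  expect_equal(unname(vif(cbind(x1, x3))), rep(1.5625, 2), tolerance = 1e-9)
})

test_that("kinship LMM collapses to OLS for degenerate covariance", {
  set.seed(61)
  n <- 24
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  ols <- unname(coef(lm(y ~ X[, 2])))
  for (K in list(KinshipMatrix(matrix(0, n, n)),
                 KinshipMatrix(diag(0.5, n)))) {
    fit <- lmmKinshipFit(y, X, K)
    expect_equal(unname(coef(fit)), ols, tolerance = 1e-6)
  }
})

test_that("kinship LMM is permutation-invariant and recovers coefficients", {
  set.seed(62)
  cfg <- simConfig(n_founders = 16, n_generations = 2, n_sites = 3000)
  ped <- simulatePedigree(cfg, seed = 63)
  g <- simulateSnpGenotypes(ped, cfg, seed = 64)
  K <- kingKinship(g)
  n <- nrow(kinship(K))
  A <- 2 * kinship(K); diag(A) <- 1
  eg <- eigen(A, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + drop(L %*% rnorm(n)) + rnorm(n)

  fit <- lmmKinshipFit(y, X, K)
  perm <- sample(n)
  fit_p <- lmmKinshipFit(y[perm], X[perm, ],
                         KinshipMatrix(kinship(K)[perm, perm]))
  expect_equal(coef(fit), coef(fit_p), tolerance = 1e-10)
  expect_equal(fit@logLik, fit_p@logLik, tolerance = 1e-10)

  # likelihood at the optimum beats both variance-ratio boundaries
  # (checked via the degenerate OLS fit inside the optimiser) and the
  # average estimate over replicates recovers the simulated betas
  reps <- 200
  bhat <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    yr <- drop(X %*% c(1, 2)) + drop(L %*% rnorm(n)) + rnorm(n)
    bhat[r, ] <- coef(lmmKinshipFit(yr, X, K))
  }
  expect_equal(colMeans(bhat), c(1, 2), tolerance = 0.1)
})

test_that("Huber-Poisson moment formulas match brute-force summation", {
  cc <- 1.345
  for (mu in c(0.4, 1.7, 6, 25, 180)) {
    y <- 0:max(50, ceiling(mu + 15 * sqrt(mu)))
    r <- (y - mu) / sqrt(mu)
    psi <- pmin(pmax(r, -cc), cc)
    w <- dpois(y, mu)
    mom <- mhcdiv:::.huberPoisMoments(mu, cc)
    expect_equal(mom$e1, sum(psi * w), tolerance = 1e-10)
    expect_equal(mom$e2, sum(psi^2 * w), tolerance = 1e-10)
  }
})

test_that("robust Poisson matches ML on clean data and resists outliers", {
  set.seed(65)
  n <- 300
  x <- rnorm(n)
  X <- cbind(1, x)
  y <- rpois(n, exp(1 + 0.5 * x))
  ml <- unname(coef(glm(y ~ x, family = poisson())))
  # infinite tuning constant reduces the estimating equation to the score
  fit_inf <- robustPoissonFit(y, X, tuning = Inf)
  expect_equal(unname(coef(fit_inf)), ml, tolerance = 1e-6)
  # a large but finite constant changes nothing on clean moderate counts
  fit_10 <- robustPoissonFit(y, X, tuning = 10)
  expect_equal(unname(coef(fit_10)), ml, tolerance = 1e-3)
  # default constant stays close
  fit_def <- robustPoissonFit(y, X)
  expect_true(fit_def@converged)
  expect_equal(unname(coef(fit_def)), ml, tolerance = 0.08)

  # intercept-only with constant response: the score equation gives
  # log(c) exactly; the bounded-influence fit stays within the small
  # Fisher-consistency correction of it
  yc <- rep(7L, 40)
  expect_equal(unname(coef(robustPoissonFit(yc, matrix(1, 40, 1),
                                            tuning = Inf))),
               log(7), tolerance = 1e-8)
  expect_equal(unname(coef(robustPoissonFit(yc, matrix(1, 40, 1)))),
               log(7), tolerance = 0.02)

  # gross outlier: robust shift strictly smaller than classical shift
  y_out <- c(y, 5000L)
  X_out <- rbind(X, c(1, 0))
  ml_out <- unname(coef(glm(y_out ~ X_out[, 2], family = poisson())))
  rob_out <- unname(coef(robustPoissonFit(y_out, X_out)))
  rob_clean <- unname(coef(fit_def))
  expect_lt(sum(abs(rob_out - rob_clean)), sum(abs(ml_out - ml)))
})

test_that("robust Wald test behaves at its null and trivial cases", {
  # a coefficient of exactly zero gives statistic 0, p = 1
  cf <- data.frame(term = c("(Intercept)", "b"), estimate = c(1, 0),
                   se = c(0.1, 0.2), z = c(10, 0), p = c(0, 1))
  V <- diag(c(0.01, 0.04)); dimnames(V) <- list(cf$term, cf$term)
  fit <- new("FitResult", coefficients = cf, vcov = V,
             varcomp = numeric(0), logLik = 0, converged = TRUE,
             method = "manual")
  w <- robustWaldTest(fit, "b")
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)
  expect_error(robustWaldTest(fit, "missing_term"), "not in the model")
})

test_that("the association battery has the documented structure", {
  set.seed(66)
  cfg <- pipelineConfig(
    sim = simConfig(n_founders = 8, n_generations = 2, n_sites = 1500,
                    ld_block_size = 2),
    mhc = mhcSimSpec(depth_mean = 400, depth_sd = 0))
  dir <- file.path(tempdir(), "battery_run")
  unlink(dir, recursive = TRUE)
  res <- suppressMessages(runPipeline(dir, cfg, seed = 67))
  models <- res$models
  expect_equal(nrow(models), 2 + 7 + 4)
  expect_equal(sum(grepl("^stMLH->", models$model)), 7L)
  expect_equal(sum(grepl("^shared_", models$model)), 4L)
  # BH adjustment applied within the stMLH and dyadic families
  a4 <- models[grepl("^stMLH->", models$model), ]
  ok <- !is.na(a4$p)
  expect_equal(a4$p_adj[ok], bhAdjust(a4$p)[ok])
  unlink(dir, recursive = TRUE)
})
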