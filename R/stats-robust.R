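# Bounded-influence Poisson regression (Huber-psi M-estimation on
# Pearson residuals with a Fisher-consistency correction), robust
# Wald-type nested tests, BH correction and collinearity diagnostics.

# E[psi_c(r)] and E[psi_c(r)^2] for r = (Y - mu)/sqrt(mu), Y ~ Poisson(mu),
# in closed form via Poisson cdf/pmf identities. c = Inf gives (0, 1).
.huberPoisMoments <- function(mu, cc) {
  if (!is.finite(cc)) return(list(e1 = rep(0, length(mu)),
                                  e2 = rep(1, length(mu))))
  s <- sqrt(mu)
  j1 <- floor(mu - cc * s)   # psi = -c for Y <= j1
  j2 <- floor(mu + cc * s)   # psi = +c for Y > j2
  F <- function(k) ppois(pmax(k, -1), mu) * (k >= 0)
  D <- function(k) dpois(pmax(k, 0), mu) * (k >= 0)
  e1 <- -cc * F(j1) + cc * (1 - F(j2)) + s * (D(j1) - D(j2))
  m2 <- mu^2 * (F(j2 - 2) - F(j1 - 2)) +
    mu * (1 - 2 * mu) * (F(j2 - 1) - F(j1 - 1)) +
    mu^2 * (F(j2) - F(j1))
  e2 <- cc^2 * (F(j1) + 1 - F(j2)) + m2 / mu
  list(e1 = e1, e2 = e2)
}

.huberPsi <- function(r, cc) pmin(pmax(r, -cc), cc)

.designNames <- function(X) {
  nm <- colnames(X)
  if (is.null(nm)) nm <- rep("", ncol(X))
  fallback <- c("(Intercept)", paste0("x", seq_len(max(ncol(X) - 1L, 0L))))
  nm[!nzchar(nm)] <- fallback[seq_len(ncol(X))][!nzchar(nm)]
  nm
}

# estimating function U(beta) = X' s, s_i = (psi(r_i) - E psi) sqrt(mu_i)
.rpoisU <- function(beta, y, X, cc) {
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  r <- (y - mu) / sqrt(mu)
  mom <- .huberPoisMoments(mu, cc)
  s <- (.huberPsi(r, cc) - mom$e1) * sqrt(mu)
  drop(crossprod(X, s))
}

#' Bounded-influence robust Poisson regression
#'
#' Mallows/Huber-type M-estimation for the Poisson log-linear model:
#' the maximum-likelihood score is replaced by Huber-psi-winsorised
#' Pearson residuals with an analytic Fisher-consistency correction, so
#' gross outliers have bounded influence while clean data give
#' near-ML estimates. `tuning = Inf` recovers the classical ML fit
#' exactly. Standard errors come from the M-estimation sandwich
#' (model-based middle matrix, numerically differentiated outer
#' matrix).
#'
#' @param y non-negative integer response counts.
#' @param X design matrix including the intercept column.
#' @param tuning Huber tuning constant on the Pearson-residual scale;
#'   the classical robustness default 1.345.
#' @param maxit,tol Newton iteration controls.
#' @return a [FitResult-class]; `converged` is `FALSE` when the Newton
#'   iteration fails to drive the estimating equations to zero.
#' @export
robustPoissonFit <- function(y, X, tuning = 1.345, maxit = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y >= 0), all(y == round(y)))
  colnames(X) <- .designNames(X)
  p <- ncol(X)
  n <- length(y)
  beta <- suppressWarnings(
    glm.fit(X, y, family = poisson())$coefficients)
  beta[!is.finite(beta)] <- 0
  jac <- function(b) {
    J <- matrix(0, p, p)
    h <- 1e-6 * pmax(abs(b), 1)
    for (k in seq_len(p)) {
      bp <- b; bm <- b
      bp[k] <- bp[k] + h[k]; bm[k] <- bm[k] - h[k]
      J[, k] <- (.rpoisU(bp, y, X, tuning) - .rpoisU(bm, y, X, tuning)) /
        (2 * h[k])
    }
    J
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    U <- .rpoisU(beta, y, X, tuning)
    if (sqrt(sum(U^2)) < tol * n) { converged <- TRUE; break }
    J <- jac(beta)
    step <- tryCatch(solve(J, U), error = function(e) NULL)
    if (is.null(step)) break
    # damped Newton: halve until the estimating equations shrink
    lam <- 1
    repeat {
      cand <- beta - lam * step
      Uc <- .rpoisU(cand, y, X, tuning)
      if (sqrt(sum(Uc^2)) < sqrt(sum(U^2)) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (sqrt(sum((lam * step)^2)) < 1e-12) { converged <- TRUE; beta <- cand; break }
    beta <- cand
  }
  U <- .rpoisU(beta, y, X, tuning)
  if (sqrt(sum(U^2)) < 1e-4 * n) converged <- TRUE
  mu <- exp(drop(X %*% beta))
  mom <- .huberPoisMoments(mu, tuning)
  qv <- (mom$e2 - mom$e1^2) * mu
  Q <- crossprod(X * qv, X)
  M <- -jac(beta)
  Minv <- solve(M)
  V <- Minv %*% Q %*% t(Minv)
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  z <- beta / se
  cf <- data.frame(term = colnames(X), estimate = unname(beta),
                   se = unname(se), z = unname(z),
                   p = unname(2 * pnorm(-abs(z))), stringsAsFactors = FALSE)
  ll <- sum(dpois(y, mu, log = TRUE))
  new("FitResult", coefficients = cf, vcov = V, varcomp = numeric(0),
      logLik = ll, converged = converged,
      method = sprintf("robust_poisson_huber%.3g", tuning))
}

#' Robust Wald-type test of dropped terms
#'
#' Tests a full model against the reduction that excludes the named
#' terms with the Wald quadratic form on the dropped coefficients and
#' their robust covariance block, referred to chi-square with as many
#' degrees of freedom as dropped terms. This is the robust analogue of
#' a nested model comparison (e.g. full dyadic model versus the model
#' without kinship).
#'
#' @param fit a [FitResult-class] from [robustPoissonFit()] (any fit
#'   exposing a coefficient covariance works).
#' @param terms character vector of coefficient names to drop.
#' @return list: `statistic`, `df`, `p`.
#' @export
robustWaldTest <- function(fit, terms) {
  stopifnot(is(fit, "FitResult"))
  cf <- fit@coefficients
  miss <- setdiff(terms, cf$term)
  if (length(miss)) stop("terms not in the model: ", paste(miss, collapse = ", "))
  b <- cf$estimate[match(terms, cf$term)]
  V <- fit@vcov[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  df <- length(terms)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]): monotone in rank order and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Variance inflation factors
#'
#' `1 / (1 - R^2)` of each predictor regressed on the others; an exact
#' linear dependency yields `Inf`.
#'
#' @param X numeric matrix or data.frame of predictors (no intercept
#'   column; one is added internally), at least two columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    # summary.lm warns on exact fits; R^2 = 1 is an expected branch here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Run the full association battery on a cohort
#'
#' Reproduces the three-tier analysis structure: (a) class I diversity
#' predicting class II diversity (alleles, then supertypes) in
#' kinship-random-effect linear mixed models; (b) genome-wide stMLH
#' predicting each of the seven MHC heterozygosity indices in the same
#' mixed model, BH-corrected across the seven; (c) four dyadic robust
#' Poisson models (shared alleles/supertypes at class I/II on kinship
#' plus the dyad's total unique count), each tested for the kinship
#' term with the robust Wald-type test and BH-corrected across the
#' four.
#'
#' @param indices per-individual data.frame from
#'   [heterozygosityIndices()] with an `stMLH` column appended.
#' @param K a [KinshipMatrix-class] aligned with `indices$individual`.
#' @param dyads per-dyad data.frame from [dyadComplementarity()] with a
#'   `kinship` column appended.
#' @param tuning Huber constant for the dyadic fits.
#' @return tidy data.frame: `model`, `term`, `estimate`, `se`, `z`,
#'   `p`, `p_adj` (`p` for dyadic kinship rows is the robust Wald
#'   p-value).
#' @export
runAssociationModels <- function(indices, K, dyads, tuning = 1.345) {
  phi <- kinship(K)[indices$individual, indices$individual]
  Ksub <- KinshipMatrix(phi)
  rows <- list()
  scale01 <- function(x) (x - mean(x)) / sd(x)
  lmm_row <- function(model, yv, xv) {
    ok <- is.finite(yv) & is.finite(xv)
    # a constant index carries no signal; report an empty row rather
    # than fit a degenerate regression
    if (sum(ok) < 3L || sd(yv[ok]) == 0 || sd(xv[ok]) == 0)
      return(data.frame(model = model, term = "predictor",
                        estimate = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    fit <- lmmKinshipFit(scale01(yv[ok]),
                         cbind(`(Intercept)` = 1, predictor = scale01(xv[ok])),
                         KinshipMatrix(phi[ok, ok]))
    cf <- fitTable(fit)
    cbind(model = model, cf[cf$term == "predictor", ])
  }
  rows$aim3 <- rbind(
    lmm_row("classI_alleles->classII_alleles",
            indices$n_alleles_classII, indices$n_alleles_classI),
    lmm_row("classI_supertypes->classII_supertypes",
            indices$n_supertypes_classII, indices$n_supertypes_classI))
  aim4_targets <- c("n_alleles_classI", "n_alleles_classII",
                    "mean_aa_diff_classI", "mean_aa_diff_DQA",
                    "mean_aa_diff_DRB", "n_supertypes_classI",
                    "n_supertypes_classII")
  a4 <- do.call(rbind, lapply(aim4_targets, function(tg)
    lmm_row(paste0("stMLH->", tg), indices[[tg]], indices$stMLH)))
  a4$p_adj <- bhAdjust(a4$p)
  aim5_specs <- list(
    c("shared_alleles_classI", "total_alleles_classI"),
    c("shared_alleles_classII", "total_alleles_classII"),
    c("shared_supertypes_classI", "total_supertypes_classI"),
    c("shared_supertypes_classII", "total_supertypes_classII"))
  a5 <- do.call(rbind, lapply(aim5_specs, function(sp) {
    Xd <- cbind(`(Intercept)` = 1, kinship = dyads$kinship,
                total = dyads[[sp[2]]])
    # a constant total is collinear with the intercept; drop it
    if (sd(Xd[, "total"]) == 0) Xd <- Xd[, c("(Intercept)", "kinship")]
    out <- tryCatch({
      fit <- robustPoissonFit(dyads[[sp[1]]], Xd, tuning = tuning)
      wald <- robustWaldTest(fit, "kinship")
      cf <- fitTable(fit)
      o <- cbind(model = sp[1], cf[cf$term == "kinship", ])
      o$p <- wald$p
      o
    }, error = function(e)
      data.frame(model = sp[1], term = "kinship", estimate = NA_real_,
                 se = NA_real_, z = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE))
    out
  }))
  a5$p_adj <- bhAdjust(a5$p)
  rows$aim3$p_adj <- NA_real_
  out <- rbind(rows$aim3, a4, a5)
  rownames(out) <- NULL
  out
}
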