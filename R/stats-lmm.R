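# Linear mixed model with a kinship random effect, fitted by profiling
# the variance ratio on the eigendecomposition of the relatedness
# matrix (the standard trick for a single genetic variance component).

#' Linear mixed model with a kinship random effect
#'
#' Fits `y = X beta + g + e` with `cov(g) = sg2 * A` and
#' `cov(e) = se2 * I`, where `A = 2 * phi` off-diagonal with unit
#' diagonal (outbred relatedness scaling). The likelihood is profiled
#' over the variance ratio `lambda = sg2 / se2` on the
#' eigendecomposition of `A`, so each candidate ratio costs one
#' generalized least squares solve; maximum likelihood by default,
#' REML optionally. Coefficient p-values are Wald z against the normal
#' reference.
#'
#' @param y numeric response vector.
#' @param X design matrix including the intercept column.
#' @param K a [KinshipMatrix-class] or symmetric matrix of kinship phi
#'   aligned with `y`.
#' @param method `"ML"` (default) or `"REML"`.
#' @return a [FitResult-class] with coefficient table, variance
#'   components (`genetic`, `residual`) and log-likelihood.
#' @export
lmmKinshipFit <- function(y, X, K, method = c("ML", "REML")) {
  method <- match.arg(method)
  phi <- if (is(K, "KinshipMatrix")) kinship(K) else as.matrix(K)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(phi) == n, ncol(phi) == n)
  colnames(X) <- .designNames(X)
  A <- 2 * phi
  diag(A) <- 1
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    warning("kinship-derived covariance not PSD; shifting by smallest eigenvalue")
    eg$values <- eg$values - min(eg$values)
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)
  profile <- function(loglambda) {
    lambda <- exp(loglambda)
    w <- 1 / (lambda * d + 1)
    XtW <- Xt * w
    XX <- crossprod(Xt, XtW)
    beta <- solve(XX, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(lambda * d + 1)) + n)
    } else {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(lambda * d + 1)) +
                      determinant(XX, logarithm = TRUE)$modulus + (n - p))
    }
    list(ll = as.numeric(ll), beta = drop(beta), s2 = s2, lambda = lambda,
         XXinv = solve(XX))
  }
  # profile over log variance ratio; include the OLS boundary
  grid <- seq(-12, 12, length.out = 25)
  lls <- vapply(grid, function(t) profile(t)$ll, numeric(1))
  best <- grid[which.max(lls)]
  opt <- optimize(function(t) profile(t)$ll,
                  interval = c(best - 2, best + 2), maximum = TRUE)
  fit <- profile(opt$maximum)
  ols <- profile(-50)  # lambda ~ 0: genetic variance off
  if (ols$ll >= fit$ll - 1e-8) { fit <- ols; fit$lambda <- 0 }
  se <- sqrt(fit$s2 * diag(fit$XXinv))
  z <- fit$beta / se
  cf <- data.frame(term = colnames(X), estimate = unname(fit$beta),
                   se = unname(se), z = unname(z),
                   p = unname(2 * pnorm(-abs(z))), stringsAsFactors = FALSE)
  vc <- c(genetic = fit$lambda * fit$s2, residual = fit$s2)
  V <- fit$s2 * fit$XXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  new("FitResult", coefficients = cf, vcov = V,
      varcomp = vc, logLik = fit$ll, converged = TRUE,
      method = paste0("lmm_kinship_", method))
}
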