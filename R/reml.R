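# Single-kinship linear mixed model fitted by REML through a one-time
# eigendecomposition of K (EMMA-style): with V = sigma_a^2 (K + lambda I),
# lambda = sigma_e^2 / sigma_a^2, the restricted likelihood is profiled over
# lambda on a log grid and refined by Brent search.

# restricted / maximum log-likelihood at a given lambda, on rotated data.
# Returns the profile value and the ingredients at the optimum scale.
.profile_at <- function(lambda, d, ytil, Xtil, logdetXX, reml = TRUE) {
  n <- length(ytil)
  p <- ncol(Xtil)
  w <- d + lambda
  sw <- sqrt(w)
  xw <- Xtil / sw
  yw <- ytil / sw
  qrx <- qr(xw)
  beta <- qr.coef(qrx, yw)
  res <- yw - xw %*% beta
  S <- sum(res^2)
  logdetXWX <- 2 * sum(log(abs(diag(qr.R(qrx)))))
  if (reml) {
    df <- n - p
    ll <- -0.5 * (df * log(2 * pi) + df * log(S / df) + df +
                    sum(log(w)) + logdetXWX)
    sigma_a2 <- S / df
  } else {
    ll <- -0.5 * (n * log(2 * pi) + n * log(S / n) + n + sum(log(w)))
    sigma_a2 <- S / n
  }
  list(ll = ll, sigma_a2 = sigma_a2, beta = drop(beta), S = S, w = w)
}

# restricted log-likelihood at explicit variance components (for the
# observed-information standard error of h2)
.reml_ll_at <- function(sigma_a2, sigma_e2, d, ytil, Xtil, logdetXX) {
  n <- length(ytil)
  p <- ncol(Xtil)
  w <- sigma_a2 * d + sigma_e2
  if (any(w <= 0)) return(-Inf)
  sw <- sqrt(w)
  xw <- Xtil / sw
  yw <- ytil / sw
  qrx <- qr(xw)
  beta <- qr.coef(qrx, yw)
  S <- sum((yw - xw %*% beta)^2)
  logdetXWX <- 2 * sum(log(abs(diag(qr.R(qrx)))))
  -0.5 * ((n - p) * log(2 * pi) + sum(log(w)) + logdetXWX + S)
}

.optimize_lambda <- function(d, ytil, Xtil, logdetXX, reml = TRUE,
                             grid_n = 100, grid_range = c(1e-5, 1e5),
                             tol = 1e-8) {
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]), length.out = grid_n))
  ll <- vapply(grid, function(l)
    .profile_at(l, d, ytil, Xtil, logdetXX, reml)$ll, 1)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(grid_n, i + 1)]
  opt <- optimize(function(loglam)
    .profile_at(exp(loglam), d, ytil, Xtil, logdetXX, reml)$ll,
    interval = c(log(lo), log(hi)), maximum = TRUE, tol = tol)
  lambda <- exp(opt$maximum)
  # keep the grid end point when the optimum sits on the boundary
  if (ll[i] > opt$objective) lambda <- grid[i]
  lambda
}

#' Fit the single-random-effect mixed model by REML
#'
#' Fits \eqn{y = X\beta + a + \epsilon} with \eqn{a \sim N(0, K\sigma_a^2)}
#' and \eqn{\epsilon \sim N(0, I\sigma_e^2)} by restricted maximum
#' likelihood. K is eigendecomposed once; the restricted likelihood is
#' profiled over \eqn{\lambda = \sigma_e^2/\sigma_a^2} on a 100-point log
#' grid spanning \[1e-5, 1e5\] and refined by Brent search (tolerance 1e-8 in
#' log \eqn{\lambda}). The maximized ordinary (ML) likelihood is profiled the
#' same way and reported alongside, as are the intercept-only null
#' log-likelihoods, so likelihood-ratio variance-explained statistics
#' ([r2_lr()]) can be formed. Individuals with missing phenotype are dropped
#' from y, X and K consistently.
#'
#' @param y Named numeric phenotype vector (names = individual ids, matched
#'   against `rownames(K)`; an unnamed vector must already align with K).
#' @param K A `kinship_matrix` (or plain symmetric matrix). Must be positive
#'   semi-definite: blend a directly-inverted G first if needed.
#' @param X Fixed-covariate matrix (an intercept column is added when
#'   absent). Default intercept only.
#' @param se Compute an approximate standard error for h2 from the observed
#'   information at the optimum (delta method for the ratio)?
#' @param eigen_K Optional pre-computed `eigen(K, symmetric = TRUE)` of the
#'   (already subsetted, id-aligned) kinship matrix - a performance hook for
#'   fitting many traits against one kinship; ignored when phenotypes are
#'   missing (the subset changes K).
#' @return A `reml_fit` object: variance components `sigma_a2`, `sigma_e2`,
#'   `h2` (\eqn{\sigma_a^2/(\sigma_a^2+\sigma_e^2)}, per unit of K), `h2_se`,
#'   `h2_realized` (the same ratio after converting \eqn{\sigma_a^2} to the
#'   realized genetic variance of this sample via the mean diagonal and
#'   off-diagonal of K - the two coincide when K's diagonal averages 1),
#'   restricted and ML maximized log-likelihoods (`logl_reml`,
#'   `logl_ml`), the matching intercept-only null values (`logl0_reml`,
#'   `logl0_ml`), BLUP breeding values `blup`, fixed effects `beta`, and the
#'   rotated data reused by [emmax_scan()].
#' @export
reml_fit <- function(y, K, X = NULL, se = TRUE, eigen_K = NULL) {
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    assert_that(all(names(y) %in% rownames(K)),
                "phenotype ids missing from kinship matrix")
    K <- unclass(K)[names(y), names(y)]
  }
  keep <- is.finite(y)
  assert_that(any(keep), "no finite phenotype values")
  y <- y[keep]
  K <- unclass(K)[keep, keep]
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    X <- X[keep, , drop = FALSE]
    if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
      X <- cbind(`(Intercept)` = 1, X)
    }
  }
  assert_that(qr(X)$rank == ncol(X), "X must have full column rank")
  p <- ncol(X)

  identifiable <- TRUE
  if (max(abs(K - diag(n))) < 1e-10) {
    warn(paste("K is the identity: sigma_a2 and sigma_e2 are only",
               "identified through their sum; h2 is arbitrary"))
    identifiable <- FALSE
  }

  eg <- if (!is.null(eigen_K) && all(keep)) eigen_K else
    eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  assert_that(min(eg$values) > -1e-6 * max(abs(eg$values)) - 1e-10,
              "K is not positive semi-definite; blend it first")
  U <- eg$vectors
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, X)
  logdetXX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))

  lambda <- .optimize_lambda(d, ytil, Xtil, logdetXX, reml = TRUE)
  at <- .profile_at(lambda, d, ytil, Xtil, logdetXX, reml = TRUE)
  sigma_a2 <- at$sigma_a2
  sigma_e2 <- lambda * sigma_a2
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)

  lambda_ml <- .optimize_lambda(d, ytil, Xtil, logdetXX, reml = FALSE)
  logl_ml <- .profile_at(lambda_ml, d, ytil, Xtil, logdetXX, reml = FALSE)$ll

  # sample-variance scale of K: the sample variance of a ~ N(0, sigma_a2 K)
  # is sigma_a2 (mean diag - mean offdiag); when K's diagonal is not 1 on
  # average (family samples, marker-based G) this converts the per-unit-of-K
  # variance to the realized genetic variance in this sample
  k_scale <- mean(diag(K)) -
    (sum(K) - sum(diag(K))) / (n * (n - 1))
  h2_realized <- sigma_a2 * k_scale / (sigma_a2 * k_scale + sigma_e2)

  # BLUP of additive values: a_hat = sigma_a2 K V^-1 (y - X beta) =
  # U diag(d / (d + lambda)) U' (y - X beta) on the rotated scale
  rtil <- ytil - Xtil %*% at$beta
  blup <- drop(U %*% ((d / (d + lambda)) * rtil))
  names(blup) <- names(y)

  nul <- loglik_null(y, X)

  h2_se <- NA_real_
  if (se && identifiable) {
    h2_se <- tryCatch({
      H <- pracma::hessian(function(par)
        .reml_ll_at(par[1], par[2], d, ytil, Xtil, logdetXX),
        c(sigma_a2, sigma_e2))
      Vpar <- solve(-H)
      s <- sigma_a2 + sigma_e2
      grad <- c(sigma_e2, -sigma_a2) / s^2
      sqrt(max(drop(t(grad) %*% Vpar %*% grad), 0))
    }, error = function(e) NA_real_)
  }

  structure(list(
    sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, lambda = lambda,
    h2 = h2, h2_se = h2_se, h2_realized = h2_realized, k_scale = k_scale,
    logl_reml = at$ll, logl_ml = logl_ml,
    logl0_reml = nul$logl_reml, logl0_ml = nul$logl_ml,
    beta = setNames(drop(at$beta), colnames(X)),
    blup = blup, n = n, p = p,
    identifiable = identifiable,
    eigen = list(U = U, d = d), X = X, y = y
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> n = %d  sigma_a2 = %.4g  sigma_e2 = %.4g  h2 = %.3f%s\n",
    x$n, x$sigma_a2, x$sigma_e2, x$h2,
    if (is.na(x$h2_se)) "" else sprintf(" (SE %.3f)", x$h2_se)))
  cat(sprintf("  logL (REML) = %.3f  null = %.3f  R2_LR = %.3f\n",
              x$logl_reml, x$logl0_reml,
              r2_lr(x$logl_reml, x$logl0_reml, x$n)))
  invisible(x)
}

#' Maximized log-likelihood of the intercept-only model
#'
#' Fits \eqn{y = X\beta + \epsilon} (default intercept only) and returns both
#' the restricted and the ordinary maximized log-likelihoods, using the same
#' conventions as [reml_fit()] so the two are directly comparable.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effect matrix (default intercept).
#' @return List with `logl_reml` and `logl_ml`.
#' @export
loglik_null <- function(y, X = NULL) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  assert_that(nrow(X) == n, "X and y dimensions differ")
  p <- ncol(X)
  qrx <- qr(X)
  res <- qr.resid(qrx, y)
  rss <- sum(res^2)
  assert_that(rss > 1e-12 * (sum(y^2) + 1),
              "phenotype is constant after adjusting for X")
  logdetXX <- 2 * sum(log(abs(diag(qr.R(qrx)))))
  list(
    logl_reml = -0.5 * ((n - p) * (log(2 * pi) + 1 + log(rss / (n - p))) +
                          logdetXX),
    logl_ml = -0.5 * n * (log(2 * pi) + 1 + log(rss / n))
  )
}

#' Likelihood-ratio proportion of phenotypic variance explained
#'
#' \eqn{R^2_{LR} = 1 - \exp(-\frac{2}{n}(logL_M - logL_0))}. For ordinary
#' fixed-effects regressions fitted by maximum likelihood this equals the
#' classical coefficient of determination. A model log-likelihood below the
#' null is clamped to zero with a warning.
#'
#' @param logl_m Maximized log-likelihood of the model.
#' @param logl_0 Maximized log-likelihood of the intercept-only model (same
#'   likelihood flavor as `logl_m`).
#' @param n Number of individuals with observed phenotype.
#' @return Scalar in \[0, 1).
#' @export
r2_lr <- function(logl_m, logl_0, n) {
  assert_that(n > 0, "n must be positive")
  if (logl_m < logl_0 - 1e-8) {
    warn("model log-likelihood below null; clamping R2_LR to 0")
    return(0)
  }
  max(1 - exp(-2 / n * (logl_m - logl_0)), 0)
}

#' @export
tidy.reml_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = names(x$beta), type = "fixed", estimate = unname(x$beta)),
    tibble(term = c("sigma_a2", "sigma_e2"), type = "variance",
           estimate = c(x$sigma_a2, x$sigma_e2))
  )
}

#' @export
glance.reml_fit <- function(x, ...) {
  tibble(
    n = x$n, sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
    h2 = x$h2, h2_se = x$h2_se, h2_realized = x$h2_realized,
    logl_reml = x$logl_reml, logl0_reml = x$logl0_reml,
    logl_ml = x$logl_ml, logl0_ml = x$logl0_ml,
    r2_lr = r2_lr(x$logl_reml, x$logl0_reml, x$n)
  )
}

#' Breeding values of a mixed-model fit
#'
#' @param fit A `reml_fit`.
#' @return Tibble with `id` and `blup` (predicted additive genetic value).
#' @export
blup_values <- function(fit) {
  tibble(id = names(fit$blup) %||% as.character(seq_along(fit$blup)),
         blup = unname(fit$blup))
}
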