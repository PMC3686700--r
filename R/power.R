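# Analytic power of the single-marker regression t test, with a
# non-centrality correction for genetically related samples, and a
# Monte-Carlo validator.

#' Design parameters for marker-trait association power
#'
#' @param n Sample size.
#' @param ld_r2 Marker-QTL linkage disequilibrium r2 in (0, 1\].
#' @param qtl_var QTL variance as a fraction of phenotypic variance.
#' @param p_marker,q_qtl Allele frequencies of the counted marker and QTL
#'   alleles.
#' @param rel_r Coefficient of relationship between family members of the
#'   sampled individuals (0 = unrelated sample).
#' @param h2 Narrow-sense heritability of the trait.
#' @param alpha Significance level.
#' @param sided `"two"` (the default, testing both directions) or `"one"`.
#' @return A validated `power_spec` list.
#' @export
power_spec <- function(n, ld_r2, qtl_var, p_marker = 0.5, q_qtl = 0.5,
                       rel_r = 0, h2 = 0.4, alpha = 0.05,
                       sided = c("two", "one")) {
  sided <- match.arg(sided)
  assert_that(n > 2, "n must exceed 2")
  assert_that(ld_r2 > 0 && ld_r2 <= 1, "ld_r2 must lie in (0, 1]")
  assert_that(qtl_var >= 0 && qtl_var < 1, "qtl_var must lie in [0, 1)")
  assert_that(p_marker > 0 && p_marker < 1 && q_qtl > 0 && q_qtl < 1,
              "allele frequencies must lie in (0, 1)")
  assert_that(rel_r >= 0 && rel_r <= 1, "rel_r must lie in [0, 1]")
  assert_that(h2 >= 0 && h2 <= 1, "h2 must lie in [0, 1]")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(n = n, ld_r2 = ld_r2, qtl_var = qtl_var,
                 p_marker = p_marker, q_qtl = q_qtl, rel_r = rel_r,
                 h2 = h2, alpha = alpha, sided = sided),
            class = "power_spec")
}

# small-sample correction Gamma(v/2) sqrt(2/v) / Gamma((v-1)/2); -> 1 as v
# grows
.gamma_correction <- function(v) {
  exp(lgamma(v / 2) - lgamma((v - 1) / 2)) * sqrt(2 / v)
}

#' Non-centrality of the marker regression t statistic (unrelated sample)
#'
#' Assembled from the marker regression coefficient \eqn{b = D\alpha/(p_m
#' q_m)} and its sampling standard deviation \eqn{\sigma_b =
#' \sqrt{\sigma_{res}^2 / (2 n p_m q_m)}}, where D is the marker-QTL
#' haplotype covariance and \eqn{\alpha} the QTL allele substitution effect.
#' Writing \eqn{v_m = r^2 \cdot qtl\_var} for the phenotypic variance
#' fraction the marker captures, the frequencies cancel and
#' \eqn{\delta_t = \sqrt{n v_m / (1 - v_m)}} times a small-sample
#' gamma-function correction \eqn{\Gamma(v/2)\sqrt{2/v}/\Gamma((v-1)/2)}
#' (v = n - 2). In particular, at fixed `ld_r2` and `qtl_var` the analytic
#' power does not depend on the allele frequencies; they matter only for
#' feasibility (the implied |D| must respect its frequency bounds).
#'
#' @param spec A [power_spec()].
#' @return The non-centrality parameter \eqn{\delta_t}.
#' @export
ncp_unrelated <- function(spec) {
  v_m <- spec$ld_r2 * spec$qtl_var
  assert_that(v_m < 1, "marker variance fraction must be below 1")
  .check_ld_feasible(spec)
  if (v_m == 0) return(0)
  sqrt(spec$n * v_m / (1 - v_m)) * .gamma_correction(spec$n - 2)
}

# |D| = r sqrt(p q (1-p)(1-q)) must satisfy the haplotype-frequency bounds
.check_ld_feasible <- function(spec) {
  p <- spec$p_marker
  q <- spec$q_qtl
  D <- sqrt(spec$ld_r2 * p * (1 - p) * q * (1 - q))
  dmax <- min(p * (1 - q), (1 - p) * q)
  assert_that(D <= dmax + 1e-12,
              sprintf("LD r2 = %.3g infeasible for frequencies (%.2f, %.2f)",
                      spec$ld_r2, p, q))
  invisible(D)
}

#' Non-centrality ratio for related versus unrelated samples
#'
#' \eqn{R = 1 - r^2 h^2 (1 - h^2)}: the approximate ratio of the association
#' test's non-centrality parameter in a sample of individuals related by
#' coefficient r, relative to an unrelated sample, when resemblance is due
#' to additive genetic effects. Equals 1 when r = 0 or when \eqn{h^2} is 0
#' or 1.
#'
#' @param rel_r Coefficient of relationship in \[0, 1\].
#' @param h2 Narrow-sense heritability in \[0, 1\].
#' @return The ratio R.
#' @export
relatedness_ratio <- function(rel_r, h2) {
  assert_that(rel_r >= 0 && rel_r <= 1, "rel_r must lie in [0, 1]")
  assert_that(h2 >= 0 && h2 <= 1, "h2 must lie in [0, 1]")
  1 - rel_r^2 * h2 * (1 - h2)
}

#' Analytic power of the single-marker association t test
#'
#' Power is the tail probability of the non-central t distribution with
#' v = n - 2 degrees of freedom and non-centrality \eqn{\delta_t^* =
#' \delta_t R} beyond the central-t critical value at `alpha` (for a
#' two-sided test the minor-tail contribution is included). `ncp_scale =
#' "sqrt"` applies \eqn{\sqrt{R}} instead, for the reading of the
#' relatedness ratio as a ratio of squared non-centralities.
#'
#' @param spec A [power_spec()].
#' @param ncp_scale `"linear"` (\eqn{\delta_t R}, default) or `"sqrt"`.
#' @return Power \eqn{\beta_t} in (0, 1).
#' @export
power_t <- function(spec, ncp_scale = c("linear", "sqrt")) {
  ncp_scale <- match.arg(ncp_scale)
  v <- spec$n - 2
  R <- relatedness_ratio(spec$rel_r, spec$h2)
  if (ncp_scale == "sqrt") R <- sqrt(R)
  ncp <- ncp_unrelated(spec) * R
  if (spec$sided == "one") {
    crit <- qt(1 - spec$alpha, v)
    pt(crit, v, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - spec$alpha / 2, v)
    pt(crit, v, ncp = ncp, lower.tail = FALSE) + pt(-crit, v, ncp = ncp)
  }
}

#' Monte-Carlo validation of the analytic power
#'
#' Simulates marker and QTL genotypes with the specified allele frequencies
#' and LD (joint haplotype frequencies with \eqn{D = r\sqrt{p q (1-p)(1-q)}})
#' and phenotypes with the specified QTL variance fraction. For `rel_r > 0`
#' the sample is built from full-sib-like families of `family_size` members:
#' each member copies each of a family reference pair of haplotypes with
#' probability \eqn{\sqrt{rel\_r}} (giving exchangeable genotype correlation
#' `rel_r` within families) and shares a family polygenic effect, so the
#' within-family phenotype correlation is `rel_r * h2`. Each replicate is
#' tested by the regression t test of phenotype on marker dosage, computed
#' by generalized least squares under the true (block equicorrelated)
#' phenotypic covariance - the structure-corrected association test whose
#' information loss the non-centrality ratio R describes; at `rel_r = 0`
#' this is the plain regression t test. The rejection rate at `spec$alpha`
#' (per `spec$sided`) is returned with its binomial standard error.
#'
#' @param spec A [power_spec()].
#' @param n_reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param family_size Members per family for related samples (default 3).
#' @return Tibble: `power`, `se`, `n_reps`.
#' @export
mc_power_validate <- function(spec, n_reps = 1000, seed = 1,
                              family_size = 3) {
  assert_that(n_reps >= 100, "use at least 100 replicates")
  set.seed(seed)
  p <- spec$p_marker
  q <- spec$q_qtl
  D <- .check_ld_feasible(spec)
  # haplotype frequencies for (marker allele, qtl allele) in {1,0}^2
  fr <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D,
          (1 - p) * (1 - q) + D)
  assert_that(min(fr) >= -1e-12, "infeasible LD")
  fr <- pmax(fr, 0)
  hap_m <- c(1, 1, 0, 0)
  hap_q <- c(1, 0, 1, 0)

  related <- spec$rel_r > 0
  m <- if (related) family_size else 1L
  n_fam <- floor(spec$n / m)
  n <- n_fam * m
  fam <- rep(seq_len(n_fam), each = m)
  qtl_var <- spec$qtl_var
  h2 <- max(spec$h2, qtl_var)
  poly_var <- h2 - qtl_var
  res_var <- 1 - h2
  a <- if (qtl_var > 0) sqrt(qtl_var / (2 * q * (1 - q))) else 0
  v <- n - 2
  crit <- if (spec$sided == "one") qt(1 - spec$alpha, v) else
    qt(1 - spec$alpha / 2, v)
  cpy <- sqrt(spec$rel_r)

  # block-equicorrelated whitening of [1, x, y]: within-family deviations
  # scale by 1/sqrt(1-rho), family means by 1/sqrt(1+(m-1)rho)
  rho <- spec$rel_r * h2
  s_dev <- 1 / sqrt(1 - rho)
  s_mean <- 1 / sqrt(1 + (m - 1) * rho)

  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    h1 <- sample.int(4, n, replace = TRUE, prob = fr)
    h2i <- sample.int(4, n, replace = TRUE, prob = fr)
    if (related) {
      ref1 <- rep(sample.int(4, n_fam, replace = TRUE, prob = fr), each = m)
      ref2 <- rep(sample.int(4, n_fam, replace = TRUE, prob = fr), each = m)
      take1 <- runif(n) < cpy
      take2 <- runif(n) < cpy
      h1[take1] <- ref1[take1]
      h2i[take2] <- ref2[take2]
    }
    x <- hap_m[h1] + hap_m[h2i]
    gq <- hap_q[h1] + hap_q[h2i]
    u <- rnorm(n, sd = sqrt(max(poly_var, 0)))
    if (related && poly_var > 0) {
      shared <- rep(rnorm(n_fam, sd = sqrt(poly_var)), each = m)
      u <- sqrt(spec$rel_r) * shared + sqrt(1 - spec$rel_r) * u
    }
    y <- a * gq + u + rnorm(n, sd = sqrt(res_var))
    if (related && rho > 0) {
      whiten <- function(z) {
        zm <- ave(z, fam)
        s_dev * (z - zm) + s_mean * zm
      }
      xw <- whiten(x)
      yw <- whiten(y)
      ow <- whiten(rep(1, n))
    } else {
      xw <- x; yw <- y; ow <- rep(1, n)
    }
    # regression of yw on [ow, xw]
    oo <- sum(ow^2)
    xr <- xw - ow * sum(ow * xw) / oo
    yr <- yw - ow * sum(ow * yw) / oo
    sxx <- sum(xr^2)
    if (sxx <= 0) next
    b <- sum(xr * yr) / sxx
    rss <- sum((yr - b * xr)^2)
    tstat <- b / sqrt(rss / v / sxx)
    hits[r] <- if (spec$sided == "one") tstat > crit else abs(tstat) > crit
  }
  phat <- mean(hits)
  tibble(power = phat, se = sqrt(phat * (1 - phat) / n_reps),
         n_reps = n_reps)
}

#' Power over a grid of designs
#'
#' Convenience wrapper evaluating [power_t()] over the cross product of the
#' supplied parameter values (one row per combination).
#'
#' @param n,ld_r2,qtl_var,p_marker,q_qtl,rel_r,h2,alpha Vectors of design
#'   values, crossed.
#' @param sided Test sidedness passed to [power_spec()].
#' @return Tibble with the design columns and `power`.
#' @export
power_grid <- function(n = 1120, ld_r2 = 0.25, qtl_var = 0.02,
                       p_marker = 0.5, q_qtl = 0.5, rel_r = c(0, 0.25, 0.5),
                       h2 = c(0.15, 0.4), alpha = 0.05, sided = "two") {
  grid <- tidyr::expand_grid(n = n, ld_r2 = ld_r2, qtl_var = qtl_var,
                             p_marker = p_marker, q_qtl = q_qtl,
                             rel_r = rel_r, h2 = h2, alpha = alpha)
  grid$power <- purrr::pmap_dbl(grid, function(n, ld_r2, qtl_var, p_marker,
                                               q_qtl, rel_r, h2, alpha) {
    power_t(power_spec(n, ld_r2, qtl_var, p_marker, q_qtl, rel_r, h2,
                       alpha, sided))
  })
  grid
}
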