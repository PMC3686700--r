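# EMMAX-style single-SNP association scan under the unified mixed linear
# model: variance components are estimated once from the null model (no SNP)
# and reused for every SNP test, which reduces each test to generalized least
# squares in the eigenspace of K.

#' Choose the number of principal-component covariates by BIC
#'
#' Forward model selection: the mixed model is fitted with 0..`max_pcs`
#' leading PC covariates (no SNP), and the count minimizing
#' \eqn{BIC = -2 logL + k \log(n)} (k = number of fixed-effect parameters,
#' ML likelihood) is returned. Ties go to fewer PCs.
#'
#' @param y Named phenotype vector.
#' @param K Kinship matrix.
#' @param pcs A [pca_genotypes()] result or a score matrix whose rows align
#'   with `y`.
#' @param max_pcs Maximum number of PCs to consider (must be < n).
#' @return The chosen count (integer) with the candidate table in attribute
#'   `"table"`.
#' @export
select_pcs_bic <- function(y, K, pcs, max_pcs = 5) {
  scores <- if (inherits(pcs, "genotype_pca")) {
    as.matrix(pcs$scores[, -1])
  } else {
    as.matrix(pcs)
  }
  if (inherits(pcs, "genotype_pca")) rownames(scores) <- pcs$scores$id
  keep <- is.finite(y)
  assert_that(max_pcs < sum(keep), "max_pcs must be below n")
  assert_that(max_pcs <= ncol(scores), "not enough PC columns supplied")
  if (!is.null(names(y)) && !is.null(rownames(scores))) {
    scores <- scores[names(y), , drop = FALSE]
  }
  cand <- purrr::map_dfr(0:max_pcs, function(k) {
    X <- if (k == 0) NULL else scores[, seq_len(k), drop = FALSE]
    fit <- reml_fit(y, K, X, se = FALSE)
    tibble(n_pcs = k, logl_ml = fit$logl_ml,
           k_fixed = k + 1,
           bic = -2 * fit$logl_ml + (k + 1) * log(fit$n))
  })
  best <- cand$n_pcs[which.min(cand$bic)]  # which.min takes the first tie
  structure(as.integer(best), table = cand)
}

#' EMMAX single-SNP association scan
#'
#' Tests each SNP in turn by generalized least squares regression of the
#' phenotype on \[intercept, PCs, SNP dosage\] with covariance
#' \eqn{\hat V = \hat\sigma_a^2 K + \hat\sigma_e^2 I} fixed at the null-model
#' REML estimates (the EMMAX approximation). The SNP coefficient is tested
#' two-sided against \eqn{t_{n - p}} with p = number of fixed-effect
#' parameters. Per-SNP likelihood-ratio variance-explained contributions
#' (R2_LR with minus without the SNP, both against the intercept-only null)
#' use profile maximum likelihood at the fixed variance ratio, so they are
#' monotone in |t|.
#'
#' @param y Named phenotype vector.
#' @param K Kinship matrix (usually the VanRaden G).
#' @param g A [genotype_matrix()] with imputed (complete) dosages.
#' @param n_pcs Number of leading genotype PCs included as fixed covariates.
#' @param pcs Optional pre-computed [pca_genotypes()] result (computed from
#'   `g` when needed).
#' @param threshold Per-test significance level declaring genome-wide
#'   significance (default 5e-7).
#' @param null_fit Optional pre-computed null [reml_fit()] (same y, K, PCs).
#' @return A `gwas_scan` tibble: `snp_id`, `lg`, `bp`, `freq`, `effect`,
#'   `se`, `t`, `p`, `log10p`, `r2_lr`, `significant`; scan metadata in
#'   attributes (`n`, `n_pcs`, `lambda`, `threshold`, and the reusable
#'   whitened model pieces for [joint_r2()]).
#' @export
emmax_scan <- function(y, K, g, n_pcs = 0, pcs = NULL, threshold = 5e-7,
                       null_fit = NULL) {
  assert_that(!anyNA(g$dosages), "impute missing dosages before scanning")
  keep <- is.finite(y)
  y <- y[keep]
  ids <- names(y) %||% rownames(g$dosages)[keep]
  M <- g$dosages[ids, , drop = FALSE]

  Xpc <- NULL
  if (n_pcs > 0) {
    if (is.null(pcs)) pcs <- pca_genotypes(subset_genotypes(g, ids), k = n_pcs)
    sc <- as.matrix(pcs$scores[, -1, drop = FALSE])
    rownames(sc) <- pcs$scores$id
    Xpc <- sc[ids, seq_len(n_pcs), drop = FALSE]
  }
  if (is.null(null_fit)) null_fit <- reml_fit(y, K, Xpc, se = FALSE)
  n <- null_fit$n
  U <- null_fit$eigen$U
  w <- null_fit$sigma_a2 * null_fit$eigen$d + null_fit$sigma_e2
  sw <- sqrt(w)

  Xs <- crossprod(U, null_fit$X) / sw
  ys <- drop(crossprod(U, y)) / sw
  Ms <- crossprod(U, M) / sw
  qrx <- qr(Xs)
  ey <- qr.resid(qrx, ys)
  EM <- qr.resid(qrx, Ms)

  a <- unname(drop(crossprod(EM, ey)))
  b <- unname(colSums(EM^2))
  rss0 <- sum(ey^2)
  p_fixed <- ncol(Xs) + 1
  df <- n - p_fixed
  ok <- b > 1e-10 * max(b, 1)
  beta <- ifelse(ok, a / b, NA_real_)
  rssj <- ifelse(ok, pmax(rss0 - a^2 / b, 1e-300), NA_real_)
  tstat <- ifelse(ok, a / sqrt(b * rssj / df), NA_real_)
  se <- ifelse(ok, abs(beta / tstat), NA_real_)
  pval <- ifelse(ok, 2 * pt(-abs(tstat), df), NA_real_)

  # fixed-structure profile-ML likelihoods for R2_LR contributions
  logw <- sum(log(w))
  const <- -0.5 * n * (log(2 * pi) + 1)
  l_wo <- const - 0.5 * (n * log(rss0 / n) + logw)
  l_w <- const - 0.5 * (n * log(rssj / n) + logw)
  l0 <- loglik_null(y)$logl_ml
  r2_with <- 1 - exp(-2 / n * pmax(l_w - l0, 0))
  r2_without <- 1 - exp(-2 / n * max(l_wo - l0, 0))
  r2 <- ifelse(ok, r2_with - r2_without, NA_real_)

  out <- tibble(
    snp_id = g$map$snp_id, lg = g$map$lg, bp = g$map$bp,
    freq = unname(colMeans(M)) / 2,
    effect = beta, se = se, t = tstat, p = pval,
    log10p = -log10(pval), r2_lr = r2,
    significant = !is.na(pval) & pval < threshold
  )
  class(out) <- c("gwas_scan", class(out))
  attr(out, "scan_meta") <- list(
    n = n, n_pcs = n_pcs, df = df,
    lambda = null_fit$lambda, sigma_a2 = null_fit$sigma_a2,
    sigma_e2 = null_fit$sigma_e2, threshold = threshold,
    r2_base = r2_without, logl0_ml = l0, logw = logw,
    U = U, w = w, Xs = Xs, ys = ys, ids = ids
  )
  out
}

#' Per-SNP likelihood-ratio variance-explained contributions
#'
#' Accessor for the `r2_lr` column of a [emmax_scan()] result (the R2_LR of
#' the model with the SNP minus without it, both against the intercept-only
#' null).
#'
#' @param scan A `gwas_scan`.
#' @param snp_ids Optional subset of SNP ids.
#' @return Tibble `snp_id`, `r2_lr`.
#' @export
snp_r2lr <- function(scan, snp_ids = NULL) {
  out <- tibble(snp_id = scan$snp_id, r2_lr = scan$r2_lr)
  if (!is.null(snp_ids)) out <- out[match(snp_ids, out$snp_id), ]
  out
}

#' Genome-wide significance threshold arithmetic
#'
#' Bonferroni-style translation between a per-test p-value threshold and the
#' implied genome-wide level: `per_test_alpha * n_snps`. A product above 1 is
#' flagged with a warning.
#'
#' @param per_test_alpha Per-test significance level in (0, 1).
#' @param n_snps Number of SNPs tested.
#' @return Implied genome-wide alpha.
#' @export
genomewide_threshold <- function(per_test_alpha, n_snps) {
  assert_that(per_test_alpha > 0 && per_test_alpha < 1,
              "per_test_alpha must lie in (0, 1)")
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  out <- per_test_alpha * n_snps
  if (out > 1) warn("implied genome-wide level exceeds 1")
  out
}

#' @rdname genomewide_threshold
#' @param genomewide_alpha Genome-wide level to convert back to a per-test
#'   threshold.
#' @export
per_test_threshold <- function(genomewide_alpha, n_snps) {
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  genomewide_alpha / n_snps
}

#' Joint variance explained by pruned genome-wide significant SNPs
#'
#' Among genome-wide significant SNPs, greedily keeps the largest-|t| SNP per
#' 5-Mb window within each linkage group (windows anchored at the most
#' significant SNP; ties broken towards the smaller bp), then fits all kept
#' SNPs simultaneously as fixed effects in the mixed model (variance
#' structure fixed from the null fit, as in the per-SNP tests) and returns
#' the likelihood-ratio variance explained of the joint fit.
#'
#' @param scan A [emmax_scan()] result.
#' @param g The same [genotype_matrix()] the scan used.
#' @param window_bp Pruning window (default 5e6).
#' @return A one-row tibble: `r2_lr_joint`, `n_significant`, `n_kept`,
#'   `kept_snps` (list column). With no significant SNPs, `r2_lr_joint` is 0
#'   and a note is attached.
#' @export
joint_r2 <- function(scan, g, window_bp = 5e6) {
  meta <- attr(scan, "scan_meta")
  assert_that(!is.null(meta), "scan must come from emmax_scan()")
  sig <- scan[scan$significant & !is.na(scan$t), ]
  if (!nrow(sig)) {
    out <- tibble(r2_lr_joint = 0, n_significant = 0L, n_kept = 0L,
                  kept_snps = list(character(0)))
    attr(out, "note") <- "no genome-wide significant SNPs"
    return(out)
  }
  kept <- character(0)
  for (lg in unique(sig$lg)) {
    cand <- sig[sig$lg == lg, ]
    cand <- cand[order(-abs(cand$t), cand$bp), ]
    while (nrow(cand)) {
      top <- cand[1, ]
      kept <- c(kept, top$snp_id)
      cand <- cand[abs(cand$bp - top$bp) > window_bp, , drop = FALSE]
    }
  }
  Mk <- g$dosages[meta$ids, kept, drop = FALSE]
  Ms <- crossprod(meta$U, Mk) / sqrt(meta$w)
  qrx <- qr(cbind(meta$Xs, Ms))
  rss <- sum(qr.resid(qrx, meta$ys)^2)
  n <- meta$n
  l_joint <- -0.5 * n * (log(2 * pi) + 1) -
    0.5 * (n * log(rss / n) + meta$logw)
  r2_joint <- (1 - exp(-2 / n * max(l_joint - meta$logl0_ml, 0))) -
    meta$r2_base
  tibble(r2_lr_joint = r2_joint, n_significant = nrow(sig),
         n_kept = length(kept), kept_snps = list(kept))
}

#' Quantile-quantile data and genomic inflation factor
#'
#' Observed sorted \eqn{-\log_{10} p} against the null expectation
#' \eqn{-\log_{10}((i - 0.5)/m)}, plus the genomic inflation factor
#' \eqn{\lambda_{GC} = median(\chi^2_1)/0.456}.
#'
#' @param scan A `gwas_scan` (or any data frame with a `p` column).
#' @return Tibble `expected`, `observed` (ascending) with the inflation
#'   factor in attribute `lambda_gc`.
#' @export
qq_data <- function(scan) {
  p <- scan$p[!is.na(scan$p)]
  m <- length(p)
  obs <- sort(-log10(p))
  expd <- -log10((m:1 - 0.5) / m)
  lambda_gc <- median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
  out <- tibble(expected = sort(expd), observed = obs)
  attr(out, "lambda_gc") <- lambda_gc
  out
}

#' @importFrom stats qchisq
NULL
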