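# Pairwise linkage disequilibrium (r2) and distance-binned genome-wide decay
# profiles, comparable across populations or generations.

#' Pairwise LD between two SNPs
#'
#' The composite estimator is the squared product-moment correlation of the
#' two dosage vectors (usable on unphased data). The haplotype estimator,
#' for phased input, is \eqn{r^2 = D^2 / (p_A q_A p_B q_B)} with D the
#' haplotype-frequency covariance.
#'
#' @param g A [genotype_matrix()] (composite method), or a phased haplotype
#'   matrix (haplotypes x sites, 0/1) for `method = "haplotype"`.
#' @param snp_i,snp_j SNP ids or column indices.
#' @param method `"composite"` or `"haplotype"`.
#' @return r2 in \[0, 1\].
#' @export
pairwise_r2 <- function(g, snp_i, snp_j, method = c("composite", "haplotype")) {
  method <- match.arg(method)
  if (method == "composite") {
    assert_that(inherits(g, "genotype_matrix"),
                "composite method needs a genotype_matrix")
    if (is.character(snp_i)) snp_i <- match(snp_i, g$map$snp_id)
    if (is.character(snp_j)) snp_j <- match(snp_j, g$map$snp_id)
    x <- g$dosages[, snp_i]
    y <- g$dosages[, snp_j]
    ok <- !is.na(x) & !is.na(y)
    assert_that(sd(x[ok]) > 0 && sd(y[ok]) > 0,
                "monomorphic SNP: r2 undefined")
    return(cor(x[ok], y[ok])^2)
  }
  assert_that(is.matrix(g) && all(g %in% c(0L, 1L)),
              "haplotype method needs a phased 0/1 haplotype matrix")
  if (is.character(snp_i)) snp_i <- match(snp_i, colnames(g))
  if (is.character(snp_j)) snp_j <- match(snp_j, colnames(g))
  a <- g[, snp_i]
  b <- g[, snp_j]
  pa <- mean(a)
  pb <- mean(b)
  assert_that(pa > 0 && pa < 1 && pb > 0 && pb < 1,
              "monomorphic SNP: r2 undefined")
  D <- mean(a * b) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Genome-wide LD decay profile
#'
#' Mean pairwise r2 (composite estimator) of all within-linkage-group SNP
#' pairs separated by less than `max_dist_bp`, binned by physical distance
#' into half-open bins \[lo, hi). Empty bins are reported with a missing
#' mean, never dropped.
#'
#' @param g A [genotype_matrix()] (missing dosages allowed; pairwise complete
#'   observations are used via the dosage correlation).
#' @param bins Number of equal-width bins, or an explicit vector of bin
#'   edges in bp.
#' @param max_dist_bp Maximum pair distance considered.
#' @param population Label stored with the profile.
#' @return An `ld_profile` tibble: `bin_lo`, `bin_hi`, `mean_r2`, `n_pairs`,
#'   `population`.
#' @export
decay_profile <- function(g, bins = 20, max_dist_bp = 1e6,
                          population = "population") {
  edges <- if (length(bins) == 1) {
    seq(0, max_dist_bp, length.out = bins + 1)
  } else {
    sort(bins)
  }
  nb <- length(edges) - 1
  sum_r2 <- numeric(nb)
  n_pair <- integer(nb)
  for (lg in unique(g$map$lg)) {
    idx <- which(g$map$lg == lg)
    if (length(idx) < 2) next
    bp <- g$map$bp[idx]
    cc <- suppressWarnings(
      cor(g$dosages[, idx, drop = FALSE], use = "pairwise.complete.obs"))
    dist <- abs(outer(bp, bp, "-"))
    ut <- upper.tri(dist)
    dd <- dist[ut]
    rr <- cc[ut]^2
    sel <- dd < max_dist_bp & !is.na(rr)
    bin <- findInterval(dd[sel], edges, rightmost.closed = FALSE)
    bin[bin > nb] <- NA  # pairs at exactly max_dist when edges end there
    keep <- !is.na(bin)
    sum_r2 <- sum_r2 + vapply(seq_len(nb), function(b)
      sum(rr[sel][keep & bin == b]), 1)
    n_pair <- n_pair + vapply(seq_len(nb), function(b)
      sum(keep & bin == b), 1L)
  }
  out <- tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    mean_r2 = ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_),
    n_pairs = n_pair, population = population
  )
  class(out) <- c("ld_profile", class(out))
  out
}

#' Compare two LD decay profiles
#'
#' Per-bin differences in mean r2 and the Spearman rank correlation between
#' the two bin-mean sequences (a shape similarity measure). Bins missing in
#' either profile propagate as missing differences.
#'
#' @param p1,p2 [decay_profile()] results with identical bin definitions.
#' @return List: `bins` (tibble `bin_lo`, `bin_hi`, `mean_r2_1`, `mean_r2_2`,
#'   `delta`), `rank_correlation`.
#' @export
compare_profiles <- function(p1, p2) {
  assert_that(identical(p1$bin_lo, p2$bin_lo) &&
                identical(p1$bin_hi, p2$bin_hi),
              "profiles must share bin definitions")
  bins <- tibble(bin_lo = p1$bin_lo, bin_hi = p1$bin_hi,
                 mean_r2_1 = p1$mean_r2, mean_r2_2 = p2$mean_r2,
                 delta = p2$mean_r2 - p1$mean_r2)
  ok <- !is.na(bins$mean_r2_1) & !is.na(bins$mean_r2_2)
  rc <- if (sum(ok) >= 2) {
    cor(bins$mean_r2_1[ok], bins$mean_r2_2[ok], method = "spearman")
  } else {
    NA_real_
  }
  list(bins = bins, rank_correlation = rc)
}
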