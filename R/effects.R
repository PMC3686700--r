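# Back-solving per-SNP allele substitution effects from GBLUP breeding
# values, the exact dual of ridge regression on all SNPs (RR-BLUP), and the
# linkage-group decomposition of breeding values used for LG-level genetic
# correlations.

#' Back-solve SNP allele substitution effects from breeding values
#'
#' \eqn{\hat\alpha = (2\sum_i p_i q_i)^{-1} M' G^{-1} \hat a} where M is the
#' dosage matrix centered by \eqn{2p_i} and \eqn{\hat a} the GBLUP breeding
#' values fitted with the VanRaden G built from the same M. With the exact
#' (unblended) G, \eqn{M\hat\alpha} reproduces \eqn{\hat a}, and the result
#' equals ridge-regression (RR-BLUP) SNP effects with matched shrinkage.
#' Because a G built from sample allele frequencies is singular by centering
#' (its null space equals that of M'), the inverse is taken as the
#' eigendecomposition pseudo-inverse, under which \eqn{\hat\alpha} is unique;
#' for a blended G the same route gives the ordinary inverse. The
#' aggregation error \eqn{\lVert M\hat\alpha - \hat a\rVert / \lVert \hat
#' a\rVert} is reported in attribute `aggregation_error`.
#'
#' @param blup_a Named breeding-value vector (e.g. [blup_values()] of a G
#'   fit).
#' @param g The [genotype_matrix()] the G matrix was built from.
#' @param G The `kinship_matrix` (VanRaden, possibly blended).
#' @return An `ase` tibble: `snp_id`, `lg`, `bp`, `freq`, `effect`, with
#'   attribute `aggregation_error`.
#' @export
backsolve_ase <- function(blup_a, g, G) {
  if (is.data.frame(blup_a)) blup_a <- setNames(blup_a$blup, blup_a$id)
  ids <- names(blup_a) %||% rownames(G)
  assert_that(all(ids %in% rownames(G)) && all(ids %in% rownames(g$dosages)),
              "breeding-value ids must appear in G and the genotype matrix")
  Gm <- unclass(G)[ids, ids]
  p <- attr(G, "freqs") %||% (colMeans(g$dosages[ids, , drop = FALSE]) / 2)
  c2 <- attr(G, "sumpq2") %||% (2 * sum(p * (1 - p)))
  M <- sweep(g$dosages[ids, , drop = FALSE], 2, 2 * p)
  # G built from sample frequencies is singular by centering (G 1 = 0), but
  # null(G) = null(M'), so the pseudo-inverse solution gives the unique alpha
  eg <- eigen(Gm, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  assert_that(any(pos), "G has no positive eigenvalues")
  Ginv_a <- eg$vectors[, pos, drop = FALSE] %*%
    (crossprod(eg$vectors[, pos, drop = FALSE], blup_a) / eg$values[pos])
  alpha <- drop(crossprod(M, Ginv_a)) / c2
  agg <- drop(M %*% alpha)
  err <- if (sum(blup_a^2) > 0) {
    sqrt(sum((agg - blup_a)^2) / sum(blup_a^2))
  } else 0
  out <- tibble(snp_id = g$map$snp_id, lg = g$map$lg, bp = g$map$bp,
                freq = unname(p), effect = unname(alpha))
  class(out) <- c("ase", class(out))
  attr(out, "aggregation_error") <- err
  attr(out, "ids") <- ids
  out
}

#' Decompose breeding values to linkage-group level
#'
#' Per individual and linkage group, the partial breeding value is the sum
#' over that LG's SNPs of centered dosage times the allele substitution
#' effect. Centered dosages make partial values mean-zero per LG, and the sum
#' over LGs equals the marker-based total breeding value \eqn{M\hat\alpha}.
#'
#' @param ase An [backsolve_ase()] result (or tibble with `snp_id`, `lg`,
#'   `effect`).
#' @param g The matching [genotype_matrix()].
#' @param ids Individuals to decompose (default: the ids the ASEs were
#'   back-solved for).
#' @return An `lg_breakdown` tibble: `id`, one `LG<k>` column per linkage
#'   group, and `total` (the row sum).
#' @export
lg_decompose <- function(ase, g, ids = NULL) {
  ids <- ids %||% attr(ase, "ids") %||% rownames(g$dosages)
  assert_that(all(ase$snp_id %in% g$map$snp_id), "ASE SNPs missing from map")
  j <- match(ase$snp_id, g$map$snp_id)
  p <- ase$freq %||% (colMeans(g$dosages[ids, j, drop = FALSE]) / 2)
  M <- sweep(g$dosages[ids, j, drop = FALSE], 2, 2 * p)
  lgs <- sort(unique(ase$lg))
  parts <- vapply(lgs, function(lg) {
    sel <- which(ase$lg == lg)
    drop(M[, sel, drop = FALSE] %*% ase$effect[sel])
  }, numeric(length(ids)))
  if (is.null(dim(parts))) parts <- matrix(parts, nrow = length(ids))
  colnames(parts) <- sprintf("LG%d", lgs)
  out <- dplyr::bind_cols(tibble(id = ids), as_tibble(parts),
                          tibble(total = unname(rowSums(parts))))
  class(out) <- c("lg_breakdown", class(out))
  out
}

#' Linkage-group-level and genome-level genetic correlations
#'
#' Product-moment correlations, across individuals, of the LG-level partial
#' breeding values of two traits (one value per linkage group) plus the
#' genome-level correlation of the total breeding values. An LG whose partial
#' values have zero variance for either trait yields `NA`.
#'
#' @param bk_a,bk_b [lg_decompose()] results for the two traits (same
#'   individuals).
#' @param total_a,total_b Optional total breeding-value vectors to use for
#'   the genome-level correlation instead of the marker-based totals (e.g.
#'   BLUP-BVs straight from the mixed model).
#' @return Tibble `lg` (linkage group label, `"genome"` for the last row)
#'   and `r_g`.
#' @export
lg_genetic_correlations <- function(bk_a, bk_b,
                                    total_a = NULL, total_b = NULL) {
  assert_that(identical(bk_a$id, bk_b$id),
              "breakdowns must cover the same individuals in the same order")
  lg_cols <- setdiff(names(bk_a), c("id", "total"))
  assert_that(identical(lg_cols, setdiff(names(bk_b), c("id", "total"))),
              "breakdowns must cover the same linkage groups")
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  per_lg <- vapply(lg_cols, function(cl) safe_cor(bk_a[[cl]], bk_b[[cl]]), 1)
  ta <- total_a %||% bk_a$total
  tb <- total_b %||% bk_b$total
  tibble(lg = c(lg_cols, "genome"),
         r_g = unname(c(per_lg, safe_cor(ta, tb))))
}

#' Correlation between single-SNP and all-SNP effect estimates
#'
#' Product-moment correlation across SNPs between allele substitution
#' effects from the single-SNP scan and from the all-SNP back-solving, plus
#' the per-SNP scatter for plotting.
#'
#' @param single_snp A [emmax_scan()] result (uses its `effect` column), or
#'   a numeric vector.
#' @param all_snp An [backsolve_ase()] result (uses `effect`), or a numeric
#'   vector. Same SNP set and allele coding as `single_snp`.
#' @return List: `correlation` (scalar) and `scatter` (tibble `snp_id`,
#'   `effect_single`, `effect_all`).
#' @export
compare_ase <- function(single_snp, all_snp) {
  es <- if (is.data.frame(single_snp)) single_snp$effect else single_snp
  ea <- if (is.data.frame(all_snp)) all_snp$effect else all_snp
  assert_that(length(es) == length(ea), "effect vectors differ in length")
  ids <- if (is.data.frame(single_snp)) single_snp$snp_id else
    if (is.data.frame(all_snp)) all_snp$snp_id else
      as.character(seq_along(es))
  ok <- is.finite(es) & is.finite(ea)
  list(correlation = cor(es[ok], ea[ok]),
       scatter = tibble(snp_id = ids[ok], effect_single = es[ok],
                        effect_all = ea[ok]))
}
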