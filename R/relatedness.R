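#' Kinship matrix container
#'
#' A symmetric matrix of coefficients of relationship with an id header and a
#' `kind` flag (`"pedigree_A"`, `"genomic_G"` or `"blended"`).
#'
#' @param mat Symmetric numeric matrix with matching row/col names.
#' @param kind Flavor flag.
#' @return A `kinship_matrix`.
#' @export
kinship_matrix <- function(mat, kind = c("pedigree_A", "genomic_G", "blended")) {
  kind <- match.arg(kind)
  assert_that(is.matrix(mat) && nrow(mat) == ncol(mat), "matrix must be square")
  assert_that(max(abs(mat - t(mat))) < 1e-8, "matrix must be symmetric")
  assert_that(!is.null(rownames(mat)), "kinship needs individual ids")
  structure(mat, kind = kind, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix: %s> %d individuals, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Pedigree-expected numerator relationship matrix (A)
#'
#' Builds the numerator relationship matrix by the tabular (recursive)
#' method: individuals are sorted so parents precede offspring, then
#' \eqn{A_{ij} = (A_{j,sire(i)} + A_{j,dam(i)})/2} and
#' \eqn{A_{ii} = 1 + A_{sire(i),dam(i)}/2}. Unknown parents ("0") contribute
#' zero relationship.
#'
#' @param ped Tibble with character columns `id`, `sire`, `dam` ("0" =
#'   unknown). Every named parent must itself appear as an `id`.
#' @return A `kinship_matrix` of kind `"pedigree_A"`.
#' @export
pedigree_A <- function(ped) {
  ped <- as_tibble(ped)
  ids <- ped$id
  assert_that(!anyDuplicated(ids), "duplicated ids in pedigree")
  for (side in c("sire", "dam")) {
    known <- ped[[side]][ped[[side]] != "0"]
    assert_that(all(known %in% ids),
                sprintf("unknown-id %s in pedigree", side))
  }
  # topological order (Kahn); failure to place everyone means a cycle
  placed <- character(0)
  remaining <- ped
  order_ids <- character(0)
  while (nrow(remaining)) {
    ready <- (remaining$sire == "0" | remaining$sire %in% placed) &
      (remaining$dam == "0" | remaining$dam %in% placed)
    assert_that(any(ready), "pedigree contains a cycle")
    order_ids <- c(order_ids, remaining$id[ready])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  ped <- ped[match(order_ids, ped$id), ]
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)  # NA = unknown
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    f <- 0
    if (!is.na(si[i]) && !is.na(di[i])) f <- A[si[i], di[i]] / 2
    A[i, i] <- 1 + f
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- numeric(i - 1)
      if (!is.na(si[i])) aij <- aij + A[j, si[i]]
      if (!is.na(di[i])) aij <- aij + A[j, di[i]]
      aij <- aij / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  # restore input order
  A <- A[ped$id, ped$id][match(ids, ped$id), match(ids, ped$id)]
  A <- A[ids, ids]
  kinship_matrix(A, "pedigree_A")
}

#' Marker-realized relationship matrix (VanRaden method 1)
#'
#' \eqn{G = M M' / (2 \sum_i p_i q_i)} where M is the dosage matrix with
#' column i centered by \eqn{2 p_i} (entries \eqn{2q_i}, \eqn{q_i - p_i},
#' \eqn{-2p_i} for AA/AB/BB) and \eqn{p_i} the observed sample frequency of
#' the counted allele.
#'
#' @param g A [genotype_matrix()] without missing dosages (impute first).
#' @param freqs Optional allele frequencies to center with (defaults to the
#'   observed sample frequencies).
#' @return A `kinship_matrix` of kind `"genomic_G"`, with the centered matrix
#'   scale \eqn{2\sum p_i q_i} in attribute `sumpq2`.
#' @export
vanraden_G <- function(g, freqs = NULL) {
  dos <- g$dosages
  assert_that(!anyNA(dos), "missing dosages present; run impute_missing() first")
  p <- freqs %||% (colMeans(dos) / 2)
  assert_that(all(p > 0 & p < 1),
              "monomorphic SNPs present; filter them before building G")
  M <- sweep(dos, 2, 2 * p)
  c2 <- 2 * sum(p * (1 - p))
  G <- tcrossprod(M) / c2
  G <- kinship_matrix((G + t(G)) / 2, "genomic_G")
  attr(G, "sumpq2") <- c2
  attr(G, "freqs") <- p
  G
}

#' Blend a kinship matrix towards the identity
#'
#' \eqn{(1-\epsilon) K + \epsilon I}: guarantees positive definiteness of a
#' positive semi-definite G so it can be inverted (e.g. for back-solving SNP
#' effects).
#'
#' @param gmat A `kinship_matrix`.
#' @param epsilon Blending weight in \[0, 1).
#' @return A `kinship_matrix`; kind becomes `"blended"` when `epsilon > 0`.
#' @export
blend_kinship <- function(gmat, epsilon = 0.01) {
  assert_that(epsilon >= 0 && epsilon < 1, "epsilon must lie in [0, 1)")
  if (epsilon == 0) return(gmat)
  out <- (1 - epsilon) * unclass(gmat) + epsilon * diag(nrow(gmat))
  dimnames(out) <- dimnames(gmat)
  out <- kinship_matrix(out, "blended")
  attr(out, "sumpq2") <- attr(gmat, "sumpq2")
  attr(out, "freqs") <- attr(gmat, "freqs")
  attr(out, "epsilon") <- epsilon
  out
}

#' Principal components of the genotype matrix
#'
#' Singular value decomposition of the column-centered dosage matrix (no
#' per-SNP variance standardization unless `standardize = TRUE`). Component
#' signs follow a deterministic convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param g A [genotype_matrix()] without missing dosages.
#' @param k Number of leading components.
#' @param standardize Scale each SNP column to unit variance first.
#' @return A `genotype_pca` list: `scores` (tibble `id`, `PC1`..), `loadings`,
#'   `var_explained` (fraction per component).
#' @export
pca_genotypes <- function(g, k = 10, standardize = FALSE) {
  dos <- g$dosages
  assert_that(!anyNA(dos), "missing dosages present; impute first")
  assert_that(k <= min(dim(dos)), "k cannot exceed min(n, m)")
  X <- scale(dos, center = TRUE, scale = standardize)
  if (standardize) X[, attr(X, "scaled:scale") == 0] <- 0
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, 1)
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(loadings) <- colnames(dos)
  ve <- sv$d^2 / sum(svd(X, nu = 0, nv = 0)$d^2)
  structure(list(
    scores = dplyr::bind_cols(tibble(id = rownames(dos)), as_tibble(scores)),
    loadings = loadings,
    var_explained = ve[seq_len(k)]
  ), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d individuals, %d components (PC1 %.1f%%)\n",
              nrow(x$scores), length(x$var_explained),
              100 * x$var_explained[1]))
  invisible(x)
}

#' Compare pedigree-expected and marker-realized relationships
#'
#' Product-moment correlation and means over the off-diagonal upper-triangle
#' elements of two kinship matrices on the same individuals (diagonals are
#' excluded; the comparison is about pairwise coefficients of relationship).
#'
#' @param a,g `kinship_matrix` objects with identical ids in the same order.
#' @return One-row tibble: `element_correlation`, `mean_pairwise_A`,
#'   `mean_pairwise_G`, `n_pairs`.
#' @export
compare_A_G <- function(a, g) {
  assert_that(all(dim(a) == dim(g)), "dimension mismatch")
  assert_that(identical(rownames(a), rownames(g)),
              "individual ids must match and be in the same order")
  ut <- upper.tri(a)
  tibble(
    element_correlation = cor(a[ut], g[ut]),
    mean_pairwise_A = mean(a[ut]),
    mean_pairwise_G = mean(g[ut]),
    n_pairs = sum(ut)
  )
}
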