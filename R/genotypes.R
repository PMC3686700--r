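#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs allele dosage matrix (counts of the "A"
#' allele, values 0/1/2 or `NA`) with its marker map. The map is a tibble with
#' one row per SNP column, sorted by linkage group then position.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames = ids), SNPs in
#'   columns (colnames = snp ids). Entries 0, 1, 2 or `NA`.
#' @param map Tibble/data frame with columns `snp_id`, `lg` (integer linkage
#'   group) and `bp` (1-based physical position).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map) {
  assert_that(is.matrix(dosages), "`dosages` must be a matrix")
  map <- as_tibble(map)
  assert_that(all(c("snp_id", "lg", "bp") %in% names(map)),
              "`map` needs columns snp_id, lg, bp")
  assert_that(nrow(map) == ncol(dosages),
              "one map row per dosage column is required")
  assert_that(!is.null(rownames(dosages)), "`dosages` needs individual ids as rownames")
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp_id
  assert_that(identical(colnames(dosages), map$snp_id),
              "dosage column names must match map$snp_id in order")
  assert_that(!anyDuplicated(map$snp_id), "duplicated snp_ids in map")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2) |
    (dosages >= 0 & dosages <= 2)  # imputed dosages may be fractional
  assert_that(all(ok), "dosages must lie in [0, 2] or be NA")
  o <- order(map$lg, map$bp)
  map <- map[o, ]
  dosages <- dosages[, o, drop = FALSE]
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d SNPs on %d linkage groups (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages), dplyr::n_distinct(x$map$lg),
    100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Individual ids of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of individual ids.
#' @export
individual_ids <- function(g) rownames(g$dosages)

#' Allele frequencies from observed calls
#'
#' Frequency of the counted "A" allele per SNP, computed from non-missing
#' calls of the full sample.
#'
#' @param g A `genotype_matrix`.
#' @return Named numeric vector of frequencies \eqn{p_i}.
#' @export
allele_freqs <- function(g) {
  colMeans(g$dosages, na.rm = TRUE) / 2
}

#' Drop monomorphic SNPs
#'
#' Removes SNPs whose observed calls are all identical (sample allele
#' frequency 0 or 1), which carry no relationship or association
#' information and are rejected by [vanraden_G()].
#'
#' @param g A `genotype_matrix`.
#' @return A `genotype_matrix` with only segregating SNPs.
#' @export
filter_monomorphic <- function(g) {
  p <- allele_freqs(g)
  subset_genotypes(g, snps = which(p > 0 & p < 1))
}

#' Subset a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @param individuals Optional character/integer/logical index of rows.
#' @param snps Optional character/integer/logical index of SNP columns.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, snps = NULL) {
  d <- g$dosages
  map <- g$map
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp_id)
    d <- d[, snps, drop = FALSE]
    map <- map[snps, ]
  }
  genotype_matrix(d, map)
}
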