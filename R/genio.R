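#' Read a genotype matrix from VCF or tabular dosage format
#'
#' For VCF input the dosage is the count of the ALT allele in the `GT` field;
#' the linkage group is parsed from `CHROM` (a leading "LG"/"chr" prefix is
#' accepted). Multi-allelic records are rejected. The tabular dialect is a TSV
#' with individuals in rows (first column `id`) and SNPs in columns, values
#' 0/1/2 or `NA`; its marker map is supplied separately via `map` or
#' `map_path`.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` or `"tabular"`.
#' @param map,map_path For tabular input: the marker map as a data frame or
#'   a TSV path with columns `snp_id`, `lg`, `bp`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tabular"),
                           map = NULL, map_path = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    assert_that(!any(grepl(",", fix$ALT, fixed = TRUE)),
                "multi-allelic VCF records are not supported")
    assert_that(!anyDuplicated(fix$ID), "duplicated snp_ids in VCF")
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), 0))
    }
    dos <- apply(gt, 2, count_alt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                         dimnames = list(fix$ID, colnames(gt)))
    dos <- t(dos)
    colnames(dos) <- fix$ID
    mp <- tibble(snp_id = fix$ID,
                 lg = as.integer(sub("^(LG|lg|chr|Chr)0*", "", fix$CHROM)),
                 bp = as.numeric(fix$POS))
    assert_that(!anyNA(mp$lg), "could not parse linkage group from CHROM")
    return(genotype_matrix(dos, mp))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(names(tab)[1] == "id", "tabular dosage file must start with an `id` column")
  dos <- as.matrix(tab[, -1])
  rownames(dos) <- tab$id
  if (is.null(map)) {
    assert_that(!is.null(map_path), "tabular input needs `map` or `map_path`")
    map <- readr::read_tsv(map_path, show_col_types = FALSE, progress = FALSE)
  }
  genotype_matrix(dos, map)
}

#' Write a genotype matrix
#'
#' VCF output is a minimal plain-text VCF 4.2 with only the `GT` field
#' (unphased; fractional imputed dosages are rounded to the nearest count).
#' Tabular output writes the dosage TSV and, alongside it, the marker map.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param format `"vcf"` or `"tabular"`.
#' @param map_path Map TSV path for tabular output (default: `path` with a
#'   `.map.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "tabular"),
                            map_path = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    dos <- round(g$dosages)
    gt_of <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
    body <- vapply(seq_len(ncol(dos)), function(j) {
      gt <- ifelse(is.na(dos[, j]), "./.", gt_of[dos[, j] + 1])
      paste(c(sprintf("LG%d", g$map$lg[j]), g$map$bp[j], g$map$snp_id[j],
              "A", "B", ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, "")
    writeLines(c(lines, body), path)
    return(invisible(path))
  }
  tab <- dplyr::bind_cols(tibble(id = rownames(g$dosages)),
                          as_tibble(g$dosages))
  readr::write_tsv(tab, path, progress = FALSE)
  map_path <- map_path %||% sub("(\\.tsv)?$", ".map.tsv", path)
  readr::write_tsv(g$map, map_path, progress = FALSE)
  invisible(path)
}

#' Read / write a pedigree table
#'
#' Three-column TSV (`id`, `sire`, `dam`), `"0"` marking unknown parents.
#' Founders are rows whose parents are both unknown.
#'
#' @param path File path.
#' @return A tibble with character columns `id`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  assert_that(all(c("id", "sire", "dam") %in% names(ped)),
              "pedigree needs columns id, sire, dam")
  ped
}

#' @rdname read_pedigree
#' @param ped Pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_tsv(ped[, c("id", "sire", "dam")], path, progress = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' TSV with an `id` column and one column per trait (analysis form), or the
#' raw long form with `id`, `trait`, `year`, optional `replicate`, `value`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_phenotypes
#' @param phen Phenotype tibble.
#' @export
write_phenotypes <- function(phen, path) {
  readr::write_tsv(phen, path, progress = FALSE)
  invisible(path)
}

#' Post-genotyping quality control
#'
#' Applies, in order: (1) drop SNPs with a missing-call fraction above
#' `max_missing`; (2) drop SNPs whose opposite-homozygote parent-offspring
#' conflict rate exceeds `max_mendel_rate` (checked against each genotyped
#' recorded parent; SNPs with no genotyped parent comparisons skip the
#' check). The per-filter counts, in application order, are attached as the
#' `qc_report` attribute (also returned by [qc_report()]).
#'
#' @param g A [genotype_matrix()].
#' @param ped Pedigree tibble (`id`, `sire`, `dam`); ids must be a subset of
#'   the genotyped ids for the Mendel check to apply to them.
#' @param max_missing Maximum tolerated missing fraction per SNP.
#' @param max_mendel_rate Maximum tolerated conflict rate per SNP.
#' @return The filtered `genotype_matrix` with a `qc_report` attribute.
#' @export
qc_filter <- function(g, ped = NULL, max_missing = 0.05,
                      max_mendel_rate = 0.05) {
  dos <- g$dosages
  n0 <- ncol(dos)
  miss <- colMeans(is.na(dos))
  keep1 <- miss <= max_missing
  n_missing_dropped <- sum(!keep1)
  dos <- dos[, keep1, drop = FALSE]

  n_mendel_dropped <- 0L
  keep2 <- rep(TRUE, ncol(dos))
  if (!is.null(ped)) {
    ped <- ped[ped$id %in% rownames(dos), ]
    conflicts <- rep(0, ncol(dos))
    informative <- rep(0, ncol(dos))
    for (side in c("sire", "dam")) {
      par <- ped[[side]]
      has <- par != "0" & par %in% rownames(dos)
      if (!any(has)) next
      o <- dos[ped$id[has], , drop = FALSE]
      p <- dos[par[has], , drop = FALSE]
      both <- !is.na(o) & !is.na(p)
      conf <- both & ((o == 0 & p == 2) | (o == 2 & p == 0))
      conflicts <- conflicts + colSums(conf)
      informative <- informative + colSums(both)
    }
    rate <- ifelse(informative > 0, conflicts / informative, 0)
    keep2 <- rate <= max_mendel_rate
    n_mendel_dropped <- sum(!keep2)
    dos <- dos[, keep2, drop = FALSE]
  }

  report <- tibble(
    filter = c("missingness", "mendel"),
    threshold = c(max_missing, max_mendel_rate),
    n_before = c(n0, n0 - n_missing_dropped),
    n_removed = c(n_missing_dropped, n_mendel_dropped),
    n_after = c(n0 - n_missing_dropped,
                n0 - n_missing_dropped - n_mendel_dropped)
  )
  if (ncol(dos) == 0) {
    warn("qc_filter removed every SNP")
    out <- structure(list(dosages = dos, map = g$map[0, ]),
                     class = "genotype_matrix")
  } else {
    out <- genotype_matrix(dos, g$map[match(colnames(dos), g$map$snp_id), ])
  }
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_filter
#' @export
qc_report <- function(g) attr(g, "qc_report")

#' Impute missing dosages by the observed mean
#'
#' Missing entries are replaced by the SNP's observed mean dosage (a
#' continuous value, kept as-is downstream); observed entries are unchanged,
#' so allele-frequency estimates from observed calls are preserved.
#'
#' @param g A [genotype_matrix()].
#' @param method Only `"mean_dosage"` is implemented.
#' @return A complete `genotype_matrix`.
#' @export
impute_missing <- function(g, method = "mean_dosage") {
  method <- match.arg(method, "mean_dosage")
  dos <- g$dosages
  nobs <- colSums(!is.na(dos))
  assert_that(all(nobs >= 1), "every SNP needs at least one observed call")
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx)) dos[idx] <- mu[idx[, 2]]
  genotype_matrix(dos, g$map)
}

#' Average raw phenotype records to one analysis value per individual
#'
#' Two-stage mean as used for multi-year fruit evaluation: fruit replicate
#' measurements are first averaged within individual and year, then the
#' per-year means are averaged over years. Individuals with no records for a
#' trait get `NA`.
#'
#' @param raw Long tibble with columns `id`, `trait`, `year`, `value`
#'   (replicate records are simply additional rows).
#' @return A wide tibble, one row per individual, one column per trait.
#' @export
average_phenotypes <- function(raw) {
  assert_that(all(c("id", "trait", "year", "value") %in% names(raw)),
              "raw phenotypes need columns id, trait, year, value")
  raw |>
    dplyr::group_by(.data$id, .data$trait, .data$year) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop_last") |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
}
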