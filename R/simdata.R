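#' Design of a synthetic factorial full-sib mating population
#'
#' Describes the mating design and genome used by the simulator: a set of
#' female and male founders crossed in a factorial design (with optionally
#' failed crosses), full-sib family sizes, a genome of equally long linkage
#' groups carrying SNPs at random positions, a physical-to-genetic map scaling,
#' and a pollen contamination rate.
#'
#' Defaults emulate a 4 x 2 factorial apple seedling trial: one failed cross
#' leaves seven full-sib families with sizes between 40 and 350 summing to
#' 1,200 seedlings, genotyped at 147 SNPs on each of 17 linkage groups
#' (2,499 SNPs), with 500,000 bp per cM.
#'
#' @param n_founders_female,n_founders_male Counts of design parents.
#' @param family_sizes Integer vector, one size per realized cross (row-major
#'   over the female x male grid after removing `failed_crosses`).
#' @param n_lg Number of linkage groups.
#' @param snps_per_lg SNPs simulated per linkage group.
#' @param lg_length_bp Length of each linkage group in bp.
#' @param bp_per_cm Map scaling (bp per centimorgan).
#' @param contamination_rate Fraction of offspring whose paternal gamete comes
#'   from a non-design pollen donor (the recorded pedigree keeps the design
#'   father).
#' @param n_contaminants Number of non-design pollen donors available.
#' @param failed_crosses Integer indices into the female x male cross grid
#'   (row-major, female fastest) that produced no offspring.
#' @param ld_decay_bp Correlation length (bp) of the latent autoregressive
#'   process generating founder linkage disequilibrium; 0 gives independent
#'   sites.
#' @param freq_range Range from which target allele frequencies are drawn.
#' @param seed Optional default seed used by [sim_population()].
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_founders_female = 4,
                       n_founders_male = 2,
                       family_sizes = c(350, 300, 180, 120, 90, 120, 40),
                       n_lg = 17,
                       snps_per_lg = 147,
                       lg_length_bp = 4e7,
                       bp_per_cm = 5e5,
                       contamination_rate = 0.05,
                       n_contaminants = 2,
                       failed_crosses = 8,
                       ld_decay_bp = 1e6,
                       freq_range = c(0.15, 0.85),
                       seed = NULL) {
  counts <- c(n_founders_female, n_founders_male, n_lg, snps_per_lg,
              lg_length_bp, bp_per_cm, family_sizes)
  assert_that(all(counts > 0), "all design counts and lengths must be > 0")
  assert_that(contamination_rate >= 0 && contamination_rate <= 1,
              "contamination_rate must lie in [0, 1]")
  n_cross <- n_founders_female * n_founders_male
  if (length(failed_crosses)) {
    assert_that(all(failed_crosses %in% seq_len(n_cross)),
                "failed_crosses must index the cross grid")
  }
  n_realized <- n_cross - length(failed_crosses)
  assert_that(length(family_sizes) == n_realized,
              sprintf("family_sizes must have one entry per realized cross (%d)",
                      n_realized))
  assert_that(ld_decay_bp >= 0, "ld_decay_bp must be >= 0")
  structure(list(
    n_founders_female = n_founders_female,
    n_founders_male = n_founders_male,
    family_sizes = as.integer(family_sizes),
    n_lg = as.integer(n_lg),
    snps_per_lg = as.integer(snps_per_lg),
    lg_length_bp = lg_length_bp,
    bp_per_cm = bp_per_cm,
    contamination_rate = contamination_rate,
    n_contaminants = as.integer(n_contaminants),
    failed_crosses = as.integer(failed_crosses),
    ld_decay_bp = ld_decay_bp,
    freq_range = freq_range,
    seed = seed
  ), class = "sim_design")
}

#' Multi-trait architecture for phenotype simulation
#'
#' Defines, per trait, the narrow-sense heritability, whether the trait is a
#' binary disorder score (simulated on a liability scale and thresholded), and
#' the large-effect QTL (position, phenotypic variance share, effect sign).
#' QTL are pleiotropic when two traits list the same position. QTL not placed
#' on a genotyped SNP (`snp_id = NA`) are simulated as hidden causal loci
#' inserted between markers, so marker-QTL LD is below 1. The residual genetic
#' variance (h2 minus the summed QTL shares) is polygenic, spread over linkage
#' groups proportionally to `lg_weights`, with between-trait background
#' correlations from `background_cor`.
#'
#' The default architecture echoes a six-trait apple fruit-quality panel:
#' firmness (FF), weighted cortical intensity (WCI), internal browning (IB),
#' titratable acidity (TA) and the binary disorders splitting (CR) and bitter
#' pit (BP); WCI and IB share a major QTL, as do CR and BP.
#'
#' @param traits Tibble with columns `trait`, `h2`, `binary`, `prevalence`.
#' @param qtl Tibble with columns `trait`, `lg`, `bp`, `share` (fraction of
#'   phenotypic variance), `sign` and optional `snp_id`.
#' @param background_cor Between-trait correlation matrix of polygenic
#'   backgrounds (default identity).
#' @param lg_weights Per-LG polygenic variance weights (default uniform);
#'   normalized internally.
#' @return A `trait_architecture` list.
#' @export
trait_architecture <- function(traits = NULL, qtl = NULL,
                               background_cor = NULL, lg_weights = NULL) {
  if (is.null(traits)) {
    traits <- tibble(
      trait = c("FF", "WCI", "IB", "TA", "CR", "BP"),
      h2 = c(0.43, 0.50, 0.16, 0.31, 0.23, 0.25),
      binary = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      prevalence = c(NA, NA, NA, NA, 0.30, 0.25)
    )
  }
  traits <- as_tibble(traits)
  if (!"binary" %in% names(traits)) traits$binary <- FALSE
  if (!"prevalence" %in% names(traits)) traits$prevalence <- NA_real_
  if (is.null(qtl)) {
    qtl <- tibble(
      trait = c("FF", "FF", "WCI", "WCI", "IB", "IB", "TA", "CR", "BP"),
      lg    = c(10L, 3L, 9L, 16L, 9L, 16L, 8L, 16L, 16L),
      bp    = c(20833228, 15000000, 32840325, 1496083, 32840325, 1496083,
                19658610, 1496083, 1496083),
      share = c(0.02, 0.01, 0.17, 0.03, 0.07, 0.02, 0.06, 0.09, 0.11),
      sign  = c(1, 1, 1, 1, 1, 1, 1, 1, 1)
    )
  }
  qtl <- as_tibble(qtl)
  if (!"sign" %in% names(qtl)) qtl$sign <- 1
  if (!"snp_id" %in% names(qtl)) qtl$snp_id <- NA_character_
  assert_that(all(traits$h2 > 0 & traits$h2 < 1), "h2 must lie in (0, 1)")
  assert_that(all(qtl$trait %in% traits$trait), "QTL listed for unknown trait")
  shares <- tapply(qtl$share, qtl$trait, sum)
  h2_of <- setNames(traits$h2, traits$trait)
  assert_that(all(shares <= h2_of[names(shares)] + 1e-12),
              "per-trait QTL shares cannot exceed h2")
  if (!is.null(background_cor)) {
    assert_that(is.matrix(background_cor) &&
                  nrow(background_cor) == nrow(traits),
                "background_cor must be n_traits x n_traits")
  }
  structure(list(traits = traits, qtl = qtl,
                 background_cor = background_cor, lg_weights = lg_weights),
            class = "trait_architecture")
}

#' Simulate phased founder haplotypes with distance-decaying LD
#'
#' Generates phased haplotypes for the design founders (and, when the design
#' has a positive contamination rate, a separate pool of non-design pollen
#' donors) by thresholding a latent first-order autoregressive Gaussian
#' process along each linkage group. The latent correlation between adjacent
#' sites is `exp(-d / ld_decay_bp)` for distance `d` bp, so pairwise LD (r2)
#' declines with physical distance; `ld_decay_bp = 0` gives independent
#' sites. Markers at identical positions are exact copies. Columns that come
#' out monomorphic across all founder haplotypes are made polymorphic by
#' flipping one random haplotype (a rare-variant injection), so every marker
#' segregates somewhere.
#'
#' @param design A [sim_design()].
#' @param map Optional marker map (tibble `snp_id`, `lg`, `bp`); by default
#'   SNP positions are drawn uniformly along each linkage group.
#' @param extra_positions Optional tibble (`snp_id`, `lg`, `bp`) of hidden
#'   causal loci to carry along (flagged `hidden = TRUE` in the result map).
#' @return A `founder_haplotypes` list: `haps` (haplotypes x sites 0/1
#'   matrix), `map` (with `hidden` flag), `founder_ids`, `role` (female,
#'   male or contaminant per founder).
#' @export
simulate_founder_haplotypes <- function(design, map = NULL,
                                        extra_positions = NULL) {
  assert_that(inherits(design, "sim_design"), "`design` must be a sim_design")
  if (is.null(map)) {
    map <- purrr::map_dfr(seq_len(design$n_lg), function(lg) {
      bp <- sort(ceiling(runif(design$snps_per_lg, 1, design$lg_length_bp)))
      tibble(snp_id = sprintf("LG%02d_%06d", lg, seq_along(bp)),
             lg = lg, bp = bp)
    })
  }
  map <- as_tibble(map)
  map$hidden <- FALSE
  if (!is.null(extra_positions) && nrow(extra_positions)) {
    extra <- as_tibble(extra_positions)
    extra$hidden <- TRUE
    map <- dplyr::bind_rows(map, extra[, c("snp_id", "lg", "bp", "hidden")])
  }
  map <- dplyr::arrange(map, .data$lg, .data$bp)
  assert_that(all(map$bp >= 1 & map$bp <= design$lg_length_bp),
              "map positions must lie within the linkage group length")

  n_cont <- if (design$contamination_rate > 0) design$n_contaminants else 0L
  roles <- c(rep("female", design$n_founders_female),
             rep("male", design$n_founders_male),
             rep("contaminant", n_cont))
  founder_ids <- c(sprintf("D%d", seq_len(design$n_founders_female)),
                   sprintf("S%d", seq_len(design$n_founders_male)),
                   if (n_cont) sprintf("X%d", seq_len(n_cont)))
  n_haps <- 2L * length(founder_ids)
  m <- nrow(map)

  # target frequencies; duplicated positions share the frequency of the first
  p <- runif(m, design$freq_range[1], design$freq_range[2])
  for (j in seq_len(m)[-1]) {
    if (map$lg[j] == map$lg[j - 1] && map$bp[j] == map$bp[j - 1]) {
      p[j] <- p[j - 1]
    }
  }

  haps <- matrix(0L, n_haps, m)
  for (lg in unique(map$lg)) {
    idx <- which(map$lg == lg)
    d <- diff(map$bp[idx])
    rho <- if (design$ld_decay_bp > 0) exp(-d / design$ld_decay_bp) else
      rep(0, length(d))
    rho[d == 0] <- 1
    z <- matrix(rnorm(n_haps * length(idx)), n_haps, length(idx))
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        z[, j] <- rho[j - 1] * z[, j - 1] +
          sqrt(1 - rho[j - 1]^2) * z[, j]
      }
    }
    thr <- qnorm(p[idx])
    haps[, idx] <- ifelse(sweep(z, 2, thr, "<"), 1L, 0L)
  }

  # design founders must segregate: flip one haplotype at monomorphic columns
  mono <- which(apply(haps, 2, function(x) all(x == x[1])))
  if (length(mono)) {
    flip <- sample.int(n_haps, length(mono), replace = TRUE)
    haps[cbind(flip, mono)] <- 1L - haps[cbind(flip, mono)]
  }
  colnames(haps) <- map$snp_id
  rownames(haps) <- paste0(rep(founder_ids, each = 2), c("_h1", "_h2"))
  structure(list(haps = haps, map = map, founder_ids = founder_ids,
                 role = setNames(roles, founder_ids)),
            class = "founder_haplotypes")
}

# one meiosis per row of `parents`: returns gametes x sites matrix.
# hap_a, hap_b: matrices of the two parental haplotypes per gamete (rows
# aligned with gametes). Crossovers are Poisson per LG from map length
# (Haldane, no interference), placed uniformly.
.meiose <- function(hap_a, hap_b, map, design) {
  n_gam <- nrow(hap_a)
  out <- matrix(0L, n_gam, ncol(hap_a))
  for (lg in unique(map$lg)) {
    idx <- which(map$lg == lg)
    len_morgan <- design$lg_length_bp / design$bp_per_cm / 100
    n_xo <- rpois(n_gam, len_morgan)
    start <- sample(c(0L, 1L), n_gam, replace = TRUE)
    plain <- n_xo == 0L
    if (any(plain)) {
      pi <- which(plain)
      use_b <- start[pi] == 1L
      out[pi[!use_b], idx] <- hap_a[pi[!use_b], idx]
      out[pi[use_b], idx] <- hap_b[pi[use_b], idx]
    }
    for (g in which(!plain)) {
      xo <- sort(runif(n_xo[g], 0, design$lg_length_bp))
      seg <- (start[g] + findInterval(map$bp[idx], xo)) %% 2L
      out[g, idx] <- ifelse(seg == 0L, hap_a[g, idx], hap_b[g, idx])
    }
  }
  out
}

#' Mate founders in a factorial design
#'
#' Produces full-sib families by meiosis from the design parents, with
#' crossovers drawn per linkage group from the map length (Poisson counts,
#' uniform placement, no interference). A fraction `contamination_rate` of
#' offspring receive their paternal gamete from a random non-design pollen
#' donor, while the recorded pedigree still lists the design father.
#'
#' @param founders A [simulate_founder_haplotypes()] result.
#' @param design The matching [sim_design()].
#' @return A list: `dosages_full` (offspring+founder dosages at all sites,
#'   hidden loci included), `map` (with `hidden` flag), `pedigree` (tibble
#'   `id`, `sire`, `dam`; founders have "0"), `true_parents` (tibble with the
#'   actual gamete donors), `family` (recorded family label per offspring).
#' @export
mate_factorial <- function(founders, design) {
  assert_that(inherits(founders, "founder_haplotypes"),
              "`founders` must come from simulate_founder_haplotypes()")
  map <- founders$map
  females <- founders$founder_ids[founders$role == "female"]
  males <- founders$founder_ids[founders$role == "male"]
  conts <- founders$founder_ids[founders$role == "contaminant"]

  grid <- expand.grid(dam = females, sire = males,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (length(design$failed_crosses)) grid <- grid[-design$failed_crosses, ]
  assert_that(nrow(grid) == length(design$family_sizes),
              "family count inconsistent with design")

  n_off <- sum(design$family_sizes)
  dam_of <- rep(grid$dam, design$family_sizes)
  sire_rec <- rep(grid$sire, design$family_sizes)
  fam_of <- rep(sprintf("A%03d", 400 + seq_len(nrow(grid))),
                design$family_sizes)

  sire_true <- sire_rec
  if (design$contamination_rate > 0 && length(conts)) {
    contam <- runif(n_off) < design$contamination_rate
    sire_true[contam] <- sample(conts, sum(contam), replace = TRUE)
  }

  hap_row <- function(id, which_hap) match(paste0(id, "_h", which_hap),
                                           rownames(founders$haps))
  mat_gam <- .meiose(founders$haps[hap_row(dam_of, 1), , drop = FALSE],
                     founders$haps[hap_row(dam_of, 2), , drop = FALSE],
                     map, design)
  pat_gam <- .meiose(founders$haps[hap_row(sire_true, 1), , drop = FALSE],
                     founders$haps[hap_row(sire_true, 2), , drop = FALSE],
                     map, design)
  off <- mat_gam + pat_gam
  rownames(off) <- sprintf("O%04d", seq_len(n_off))

  design_parents <- c(females, males)
  fdos <- founders$haps[paste0(rep(design_parents, each = 2), c("_h1", "_h2")), ,
                        drop = FALSE]
  fdos <- fdos[seq(1, nrow(fdos), 2), , drop = FALSE] +
    fdos[seq(2, nrow(fdos), 2), , drop = FALSE]
  rownames(fdos) <- design_parents

  dosages <- rbind(fdos, off)
  colnames(dosages) <- map$snp_id
  pedigree <- dplyr::bind_rows(
    tibble(id = design_parents, sire = "0", dam = "0"),
    tibble(id = rownames(off), sire = sire_rec, dam = dam_of)
  )
  list(dosages_full = dosages, map = map, pedigree = pedigree,
       true_parents = tibble(id = rownames(off), sire = sire_true,
                             dam = dam_of),
       family = setNames(fam_of, rownames(off)))
}

#' Simulate correlated quantitative traits over a genotyped population
#'
#' Trait values are built as QTL dosage effects plus a per-LG polygenic term
#' plus a Gaussian residual. QTL effects are scaled against the realized
#' dosage variance so each QTL contributes its stated share of phenotypic
#' variance; the residual is rescaled exactly so the realized heritability
#' (var(genetic) / var(genetic + residual)) equals the target h2. Binary
#' disorder traits are thresholded on the liability scale at their prevalence
#' and returned as 0/1 scores (downstream analysis treats them as
#' quantitative).
#'
#' @param dosages Individuals x sites dosage matrix including any hidden
#'   causal loci (e.g. `dosages_full` from [mate_factorial()]).
#' @param map Site map with `snp_id`, `lg`, `bp` (and optionally `hidden`).
#' @param arch A [trait_architecture()].
#' @param seed Optional integer seed.
#' @return A list: `phenotypes` (tibble `id` + one column per trait),
#'   `genetic_values` (matrix of true genetic values), `qtl_sites` (tibble
#'   mapping each QTL to the site used).
#' @export
simulate_phenotypes <- function(dosages, map, arch, seed = NULL) {
  assert_that(inherits(arch, "trait_architecture"),
              "`arch` must be a trait_architecture")
  if (!is.null(seed)) set.seed(seed)
  map <- as_tibble(map)
  n <- nrow(dosages)
  traits <- arch$traits
  lgs <- sort(unique(map$lg))
  lg_w <- arch$lg_weights %||% rep(1, length(lgs))
  lg_w <- lg_w / sum(lg_w)

  # resolve each QTL to a site column
  qtl <- arch$qtl
  site_of <- function(k) {
    if (!is.na(qtl$snp_id[k])) {
      j <- match(qtl$snp_id[k], map$snp_id)
      assert_that(!is.na(j), sprintf("QTL snp_id %s not on map", qtl$snp_id[k]))
      return(j)
    }
    cand <- which(map$lg == qtl$lg[k] & map$bp == qtl$bp[k])
    assert_that(length(cand) >= 1,
                sprintf("QTL at LG%d:%d has no simulated site; pass it via extra_positions",
                        qtl$lg[k], qtl$bp[k]))
    cand[1]
  }
  qtl$site <- if (nrow(qtl)) vapply(seq_len(nrow(qtl)), site_of, 1L) else integer()

  # shared polygenic effect basis across traits (for background correlations)
  bg_cor <- arch$background_cor
  nt <- nrow(traits)
  poly_sites <- which(!(map$hidden %||% rep(FALSE, nrow(map))))
  Z <- matrix(rnorm(length(poly_sites) * nt), length(poly_sites), nt)
  if (!is.null(bg_cor)) Z <- Z %*% chol(bg_cor)

  geno_c <- scale(dosages, center = TRUE, scale = FALSE)
  pheno <- matrix(NA_real_, n, nt, dimnames = list(rownames(dosages),
                                                   traits$trait))
  gvals <- pheno
  for (t in seq_len(nt)) {
    tr <- traits$trait[t]
    h2 <- traits$h2[t]
    qk <- qtl[qtl$trait == tr, ]
    qtl_part <- rep(0, n)
    for (k in seq_len(nrow(qk))) {
      x <- geno_c[, qk$site[k]]
      sdx <- sd(x)
      if (sdx > 0) qtl_part <- qtl_part + qk$sign[k] * sqrt(qk$share[k]) * x / sdx
    }
    poly_share <- h2 - sum(qk$share)
    poly_part <- rep(0, n)
    if (poly_share > 1e-12) {
      # iid small effects, variance scaled per LG to the stated shares; one
      # global amplitude calibration keeps the effect covariance consistent
      # with the marker relationship model (no per-direction reweighting)
      cvec <- Z[, t]
      for (li in seq_along(lgs)) {
        sel <- which(map$lg[poly_sites] == lgs[li])
        if (!length(sel)) next
        vsum <- sum(apply(geno_c[, poly_sites[sel], drop = FALSE], 2, var))
        if (vsum > 0) cvec[sel] <- cvec[sel] * sqrt(lg_w[li] / vsum)
        else cvec[sel] <- 0
      }
      u <- drop(geno_c[, poly_sites, drop = FALSE] %*% cvec)
      sdu <- sd(u)
      if (sdu > 0) poly_part <- sqrt(poly_share) * u / sdu
    }
    g <- drop(qtl_part + poly_part)
    vg <- var(g)
    e <- rnorm(n)
    if (vg > 0) {
      # orthogonalize against g so the realized variance ratio is exact
      e <- e - g * cov(e, g) / vg
      e <- e / sd(e) * sqrt(vg * (1 - h2) / h2)
    }
    y <- g + e
    gvals[, t] <- g
    if (isTRUE(traits$binary[t])) {
      thr <- quantile(y, 1 - traits$prevalence[t])
      y <- as.numeric(y >= thr)
    }
    pheno[, t] <- y
  }
  list(phenotypes = dplyr::bind_cols(tibble(id = rownames(dosages)),
                                     as_tibble(pheno)),
       genetic_values = gvals,
       qtl_sites = qtl)
}

#' Weighted cortical intensity score
#'
#' The red-flesh coverage score used for pigmentation phenotyping: the
#' proportion of cortex area that is red (PRA, in \[0, 1\]) times the red
#' intensity score (RI, 0-9).
#'
#' @param pra Proportion of red cortex area, in \[0, 1\].
#' @param ri Red intensity score, in \[0, 9\].
#' @return `pra * ri`, vectorized.
#' @export
derive_wci <- function(pra, ri) {
  assert_that(all(pra >= 0, na.rm = TRUE), "pra must be non-negative")
  assert_that(all(ri >= 0 & ri <= 9, na.rm = TRUE), "ri must lie in [0, 9]")
  pra * ri
}

#' Simulate a complete study population
#'
#' Orchestrates [simulate_founder_haplotypes()], [mate_factorial()] and
#' [simulate_phenotypes()] under one seed: founder haplotypes with
#' distance-decaying LD, factorial full-sib families with optional pollen
#' contamination, and a correlated multi-trait phenotype panel. Hidden causal
#' loci named by the architecture are carried through meiosis but excluded
#' from the exposed genotype matrix.
#'
#' @param design A [sim_design()].
#' @param arch A [trait_architecture()], or `NULL` to skip phenotypes.
#' @param seed Integer seed (falls back to `design$seed`).
#' @param missing_rate Fraction of genotype calls masked to `NA` (default 0).
#' @return A `sim_population` list: `genotypes` (a [genotype_matrix()] of
#'   founders + offspring at visible SNPs), `pedigree`, `phenotypes`
#'   (offspring only), `true_parents`, `family`, `founders`,
#'   `dosages_full`, `map_full`, `genetic_values`, `qtl_sites`.
#' @export
sim_population <- function(design = sim_design(), arch = trait_architecture(),
                           seed = NULL, missing_rate = 0) {
  seed <- seed %||% design$seed
  if (!is.null(seed)) set.seed(seed)
  extra <- NULL
  if (!is.null(arch) && nrow(arch$qtl)) {
    hid <- arch$qtl[is.na(arch$qtl$snp_id), ]
    if (nrow(hid)) {
      extra <- dplyr::distinct(tibble(
        snp_id = sprintf("QTL_LG%02d_%d", hid$lg, hid$bp),
        lg = hid$lg, bp = hid$bp))
    }
  }
  founders <- simulate_founder_haplotypes(design, extra_positions = extra)
  fam <- mate_factorial(founders, design)

  vis <- !fam$map$hidden
  dos <- fam$dosages_full[, vis, drop = FALSE]
  if (missing_rate > 0) {
    mask <- matrix(runif(length(dos)) < missing_rate, nrow(dos))
    dos[mask] <- NA
  }
  g <- genotype_matrix(dos, fam$map[vis, c("snp_id", "lg", "bp")])

  phen <- NULL; gv <- NULL; qtl_sites <- NULL
  if (!is.null(arch)) {
    off_ids <- fam$true_parents$id
    sim <- simulate_phenotypes(fam$dosages_full[off_ids, , drop = FALSE],
                               fam$map, arch)
    phen <- sim$phenotypes
    gv <- sim$genetic_values
    qtl_sites <- sim$qtl_sites
  }
  structure(list(genotypes = g, pedigree = fam$pedigree, phenotypes = phen,
                 true_parents = fam$true_parents, family = fam$family,
                 founders = founders, dosages_full = fam$dosages_full,
                 map_full = fam$map, genetic_values = gv,
                 qtl_sites = qtl_sites, design = design, arch = arch),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d offspring in %d families, %d SNPs, %s traits\n",
              nrow(x$true_parents), length(unique(x$family)),
              ncol(x$genotypes$dosages),
              if (is.null(x$phenotypes)) "no" else ncol(x$phenotypes) - 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
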