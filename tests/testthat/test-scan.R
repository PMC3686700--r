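# shared scan fixture: family population with one strong genotyped QTL
scan_fixture <- function(seed = 201, share = 0.25, h2 = 0.5,
                         snps_per_lg = 40, n_lg = 4,
                         family_sizes = c(60, 50, 45, 40, 40, 35, 30)) {
  key <- paste0("scanfix", seed, share, h2)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  design <- sim_design(family_sizes = family_sizes, n_lg = n_lg,
                       snps_per_lg = snps_per_lg, contamination_rate = 0)
  pop0 <- sim_population(design, arch = NULL, seed = seed)
  go <- offspring_genotypes(pop0)
  # pick a segregating mid-frequency marker as the causal SNP
  p <- allele_freqs(go)
  sds <- apply(go$dosages, 2, sd)
  cand <- which(sds > 0.5)
  qtl <- go$map$snp_id[cand[which.min(abs(p[cand] - 0.5))]]
  arch <- trait_architecture(
    traits = tibble::tibble(trait = "T1", h2 = h2, binary = FALSE,
                            prevalence = NA),
    qtl = tibble::tibble(trait = "T1", lg = NA_integer_, bp = NA_real_,
                         share = share, sign = 1, snp_id = qtl)
  )
  sim <- simulate_phenotypes(pop0$dosages_full[pop0$true_parents$id, ],
                             pop0$map_full, arch, seed = seed + 1)
  y <- setNames(sim$phenotypes$T1, sim$phenotypes$id)
  G <- blend_kinship(vanraden_G(go), 0.01)
  out <- list(go = go, y = y, G = G, qtl = qtl, pop = pop0)
  .fixture_env[[key]] <- out
  out
}

test_that("the scan ranks the causal SNP first with a genome-wide significant signal", {
  fx <- scan_fixture()
  sc <- emmax_scan(fx$y, fx$G, fx$go)
  top <- sc$snp_id[which.max(abs(sc$t))]
  expect_equal(top, fx$qtl)
  expect_true(sc$significant[sc$snp_id == fx$qtl])
  expect_equal(sc$r2_lr[which.max(abs(sc$t))], max(sc$r2_lr, na.rm = TRUE))
  # internal consistency of the result table
  ok <- !is.na(sc$p)
  expect_true(all(sc$p[ok] > 0 & sc$p[ok] <= 1))
  expect_equal(sc$log10p[ok], -log10(sc$p[ok]))
  expect_equal(sc$significant[ok], sc$p[ok] < 5e-7)
})

test_that("duplicated SNPs give identical test results", {
  fx <- scan_fixture()
  go <- fx$go
  dos <- go$dosages
  dos[, 2] <- dos[, 1]   # exact copy
  g2 <- genotype_matrix(dos, go$map)
  sc <- emmax_scan(fx$y, fx$G, g2)
  expect_equal(sc$t[2], sc$t[1])
  expect_equal(sc$p[2], sc$p[1])
  expect_equal(sc$r2_lr[2], sc$r2_lr[1])
})

test_that("allele-label swaps flip the effect sign but not p or r2_lr", {
  fx <- scan_fixture()
  go <- fx$go
  dos <- go$dosages
  dos[, 5] <- 2 - dos[, 5]
  sc1 <- emmax_scan(fx$y, fx$G, fx$go)
  sc2 <- emmax_scan(fx$y, fx$G, genotype_matrix(dos, go$map))
  expect_equal(sc2$effect[5], -sc1$effect[5])
  expect_equal(sc2$p[5], sc1$p[5])
  expect_equal(sc2$r2_lr[5], sc1$r2_lr[5])
})

test_that("monomorphic SNPs yield missing results, not failures", {
  fx <- scan_fixture()
  dos <- fx$go$dosages
  dos[, 3] <- 2
  sc <- emmax_scan(fx$y, fx$G, genotype_matrix(dos, fx$go$map))
  expect_true(is.na(sc$p[3]))
  expect_true(is.na(sc$effect[3]))
  expect_false(is.na(sc$p[4]))
})

test_that("genome-wide threshold arithmetic and its inverse round trip", {
  expect_equal(genomewide_threshold(5e-7, 2500), 0.00125)
  expect_equal(genomewide_threshold(0.05, 1), 0.05)
  expect_equal(per_test_threshold(0.00125, 2500), 5e-7)
  expect_warning(genomewide_threshold(0.9, 100), "exceeds 1")
})

test_that("BIC selection picks no PCs for unstructured traits and PCs for PC-driven traits", {
  fx <- scan_fixture()
  pca <- pca_genotypes(fx$go, k = 5)
  # max_pcs = 0 returns 0 trivially
  expect_equal(as.integer(select_pcs_bic(fx$y, fx$G, pca, max_pcs = 0)), 0L)
  # traits that are pure noise rarely earn a PC covariate
  set.seed(205)
  null_picks <- sapply(1:10, function(i) {
    y <- rnorm(length(fx$y))
    names(y) <- names(fx$y)
    as.integer(select_pcs_bic(y, fx$G, pca, max_pcs = 3))
  })
  expect_gte(mean(null_picks == 0), 0.8)
  # a trait that is PC1 plus small noise earns at least one PC
  sc1 <- pca$scores$PC1
  y_pc <- sc1 / sd(sc1) + rnorm(length(sc1), sd = 0.3)
  names(y_pc) <- pca$scores$id
  expect_gte(as.integer(select_pcs_bic(y_pc, fx$G, pca, max_pcs = 3)), 1L)
})

test_that("scans with and without PC covariates agree on admixed family data (Q+K vs K)", {
  # A QTL segregating within families (not a family-discriminating marker,
  # like the fruit-quality QTLs this models): kinship alone then captures
  # the structure and PC covariates barely move the SNP effects.
  design <- sim_design(family_sizes = c(120, 100, 90, 80, 80, 70, 60),
                       n_lg = 4, snps_per_lg = 40,
                       contamination_rate = 0.1)
  pop <- sim_population(design, arch = NULL, seed = 230)
  go <- offspring_genotypes(pop)
  pca <- pca_genotypes(go, k = 2)
  p <- allele_freqs(go)
  sds <- apply(go$dosages, 2, sd)
  pc_cor <- abs(cor(go$dosages, pca$scores$PC1))
  cand <- which(sds > 0.5 & pc_cor < 0.15)
  qtl <- go$map$snp_id[cand[which.min(abs(p[cand] - 0.5))]]
  arch <- trait_architecture(
    traits = tibble::tibble(trait = "T1", h2 = 0.5, binary = FALSE,
                            prevalence = NA),
    qtl = tibble::tibble(trait = "T1", lg = NA_integer_, bp = NA_real_,
                         share = 0.2, sign = 1, snp_id = qtl))
  sim <- simulate_phenotypes(pop$dosages_full[pop$true_parents$id, ],
                             pop$map_full, arch, seed = 231)
  y <- setNames(sim$phenotypes$T1, sim$phenotypes$id)
  G <- blend_kinship(vanraden_G(go), 0.01)
  sc0 <- emmax_scan(y, G, go, n_pcs = 0)
  sc2 <- emmax_scan(y, G, go, n_pcs = 2)
  ok <- !is.na(sc0$effect) & !is.na(sc2$effect)
  expect_gt(cor(sc0$effect[ok], sc2$effect[ok]), 0.95)
})

test_that("signal strength grows with the QTL variance share", {
  tq <- sapply(c(0.005, 0.02, 0.1), function(sh) {
    mean(sapply(1:3, function(r) {
      fx <- scan_fixture(seed = 210 + r, share = sh, h2 = 0.4)
      sc <- emmax_scan(fx$y, fx$G, fx$go)
      abs(sc$t[sc$snp_id == fx$qtl])
    }))
  })
  expect_true(all(diff(tq) > 0))
})

test_that("permuting the phenotype destroys genome-wide hits", {
  fx <- scan_fixture()
  set.seed(207)
  clean <- sapply(1:8, function(i) {
    yp <- sample(fx$y)
    names(yp) <- names(fx$y)
    sum(emmax_scan(yp, fx$G, fx$go)$significant, na.rm = TRUE) == 0
  })
  expect_gte(mean(clean), 7 / 8)
})

test_that("joint_r2 prunes 5-Mb windows and is consistent and monotone", {
  fx <- scan_fixture(seed = 208, share = 0.3)
  # plant a second 'significant' SNP: a near-copy of the causal one 1 Mb away
  go <- fx$go
  dos <- go$dosages
  j_qtl <- match(fx$qtl, go$map$snp_id)
  lg_qtl <- go$map$lg[j_qtl]
  near <- which(go$map$lg == lg_qtl &
                  abs(go$map$bp - go$map$bp[j_qtl]) < 1e6 &
                  seq_along(go$map$lg) != j_qtl)[1]
  set.seed(209)
  flip <- sample(nrow(dos), 8)
  dos[, near] <- dos[, j_qtl]
  dos[flip, near] <- pmin(pmax(dos[flip, near] + 1, 0), 2)
  g2 <- genotype_matrix(dos, go$map)
  sc <- emmax_scan(fx$y, fx$G, g2)
  sig <- sc[sc$significant & !is.na(sc$t), ]
  expect_gte(nrow(sig), 2)
  jr <- joint_r2(sc, g2)
  # both hits sit within one window: only one kept per 5 Mb
  kept <- jr$kept_snps[[1]]
  same_window <- sig[sig$lg == lg_qtl, ]
  expect_equal(sum(kept %in% same_window$snp_id), 1)
  # joint value at least the best single-SNP contribution
  expect_gte(jr$r2_lr_joint, max(sig$r2_lr) - 1e-10)
  # with a single significant SNP the joint value equals the single value
  sc1 <- emmax_scan(fx$y, fx$G, fx$go)
  sig1 <- sc1[sc1$significant & !is.na(sc1$t), ]
  if (nrow(sig1) == 1) {
    expect_equal(joint_r2(sc1, fx$go)$r2_lr_joint, sig1$r2_lr,
                 tolerance = 1e-10)
  }
  # no significant SNPs: zero with a note
  yp <- sample(fx$y); names(yp) <- names(fx$y)
  scn <- emmax_scan(yp, fx$G, fx$go)
  if (!any(scn$significant, na.rm = TRUE)) {
    jn <- joint_r2(scn, fx$go)
    expect_equal(jn$r2_lr_joint, 0)
    expect_match(attr(jn, "note"), "no genome-wide")
  }
})

test_that("qq_data is sorted, calibrated on uniform p, and degenerate on p = 1", {
  set.seed(212)
  fake <- tibble::tibble(p = runif(5000))
  qq <- qq_data(fake)
  expect_true(all(diff(qq$observed) >= 0))
  expect_true(all(diff(qq$expected) >= 0))
  expect_lt(abs(attr(qq, "lambda_gc") - 1), 0.1)
  qq1 <- qq_data(tibble::tibble(p = rep(1, 100)))
  expect_true(all(qq1$observed == 0))
})

test_that("a structured null trait is calibrated once kinship is modeled", {
  fx <- scan_fixture(seed = 213)
  # polygenic-only trait: family structure but no causal SNP
  arch <- trait_architecture(
    traits = tibble::tibble(trait = "T1", h2 = 0.4, binary = FALSE,
                            prevalence = NA),
    qtl = tibble::tibble(trait = character(), lg = integer(),
                         bp = numeric(), share = numeric(), sign = numeric())
  )
  sim <- simulate_phenotypes(
    fx$pop$dosages_full[fx$pop$true_parents$id, ], fx$pop$map_full, arch,
    seed = 214)
  y <- setNames(sim$phenotypes$T1, sim$phenotypes$id)
  sc <- emmax_scan(y, fx$G, fx$go)
  lam <- attr(qq_data(sc), "lambda_gc")
  expect_gt(lam, 0.7)
  expect_lt(lam, 1.4)
})
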