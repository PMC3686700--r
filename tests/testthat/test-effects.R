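effects_fixture <- function(seed = 301, n = 300, m = 500, h2 = 0.4,
                            n_qtl = 20) {
  key <- paste0("efffix", seed, n, m)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  set.seed(seed)
  p <- runif(m, 0.15, 0.85)
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(dos) <- list(sprintf("i%03d", 1:n), sprintf("s%03d", 1:m))
  keep <- which(apply(dos, 2, function(x) length(unique(x)) > 1))
  dos <- dos[, keep]
  m2 <- ncol(dos)
  lg <- rep(1:5, length.out = m2)[order(rep(1:5, length.out = m2))]
  map <- tibble::tibble(snp_id = colnames(dos), lg = sort(rep(1:5, length.out = m2)),
                        bp = unlist(lapply(table(sort(rep(1:5, length.out = m2))),
                                           function(k) sort(sample(1e7, k)))))
  g <- genotype_matrix(dos[, order(map$lg, map$bp)], map)
  qtl <- sample(ncol(g$dosages), n_qtl)
  b <- rnorm(n_qtl)
  gv <- drop(scale(g$dosages[, qtl], scale = FALSE) %*% b)
  gv <- gv / sd(gv) * sqrt(h2)
  y <- gv + rnorm(n, sd = sqrt(1 - h2))
  names(y) <- rownames(g$dosages)
  G <- vanraden_G(g)   # exact, unblended
  fit <- reml_fit(y, G, se = FALSE)
  out <- list(g = g, G = G, y = y, fit = fit, qtl = qtl)
  .fixture_env[[key]] <- out
  out
}

test_that("back-solved ASEs equal direct ridge-regression SNP effects (RR-BLUP identity)", {
  fx <- effects_fixture()
  ase <- backsolve_ase(blup_values(fx$fit), fx$g, fx$G)
  # independent ridge oracle with matched shrinkage:
  # alpha = (M'M + lambda_r I)^-1 M'(y - X beta), lambda_r = sigma_e2 * c / sigma_a2
  c2 <- attr(fx$G, "sumpq2")
  p <- attr(fx$G, "freqs")
  M <- sweep(fx$g$dosages, 2, 2 * p)
  lam_r <- fx$fit$sigma_e2 * c2 / fx$fit$sigma_a2
  r <- fx$y - fx$fit$beta[1]
  alpha_ridge <- solve(crossprod(M) + lam_r * diag(ncol(M)),
                       crossprod(M, r))
  expect_equal(ase$effect, unname(drop(alpha_ridge)), tolerance = 1e-8)
  # exact aggregation: M alpha reproduces the BLUP breeding values
  expect_lt(attr(ase, "aggregation_error"), 1e-8)
  expect_equal(unname(drop(M %*% ase$effect)), unname(fx$fit$blup),
               tolerance = 1e-8)
})

test_that("zero breeding values back-solve to zero effects", {
  fx <- effects_fixture()
  zero <- setNames(rep(0, length(fx$y)), names(fx$y))
  ase <- backsolve_ase(zero, fx$g, fx$G)
  expect_true(all(ase$effect == 0))
})

test_that("swapping allele labels at one SNP flips only that effect's sign", {
  fx <- effects_fixture()
  ase1 <- backsolve_ase(blup_values(fx$fit), fx$g, fx$G)
  dos <- fx$g$dosages
  dos[, 7] <- 2 - dos[, 7]
  g2 <- genotype_matrix(dos, fx$g$map)
  G2 <- vanraden_G(g2)  # same G (coding invariance)
  ase2 <- backsolve_ase(blup_values(fx$fit), g2, G2)
  expect_equal(ase2$effect[7], -ase1$effect[7], tolerance = 1e-10)
  expect_equal(ase2$effect[-7], ase1$effect[-7], tolerance = 1e-10)
})

test_that("blended G reports its aggregation error", {
  fx <- effects_fixture()
  Gb <- blend_kinship(fx$G, 0.05)
  fitb <- reml_fit(fx$y, Gb, se = FALSE)
  aseb <- backsolve_ase(blup_values(fitb), fx$g, Gb)
  expect_gt(attr(aseb, "aggregation_error"), 0)
})

test_that("LG decomposition is additive and mean-zero per LG", {
  fx <- effects_fixture()
  ase <- backsolve_ase(blup_values(fx$fit), fx$g, fx$G)
  bk <- lg_decompose(ase, fx$g)
  lg_cols <- setdiff(names(bk), c("id", "total"))
  expect_equal(length(lg_cols), 5)
  parts <- as.matrix(bk[, lg_cols])
  expect_equal(unname(rowSums(parts)), bk$total, tolerance = 1e-10)
  expect_equal(unname(colMeans(parts)), rep(0, 5), tolerance = 1e-10)
  # total equals M alpha (= BLUP for exact G)
  expect_equal(bk$total, unname(fx$fit$blup), tolerance = 1e-8)
})

test_that("a single-LG genome decomposes to the total unchanged", {
  fx <- effects_fixture()
  map1 <- fx$g$map
  map1$lg <- 1L
  map1 <- dplyr::arrange(map1, bp)
  g1 <- genotype_matrix(fx$g$dosages[, map1$snp_id], map1)
  G1 <- vanraden_G(g1)
  fit1 <- reml_fit(fx$y, G1, se = FALSE)
  ase1 <- backsolve_ase(blup_values(fit1), g1, G1)
  bk1 <- lg_decompose(ase1, g1)
  expect_equal(bk1$LG1, bk1$total)
})

test_that("QTL concentrated on one LG dominate its partial-BV variance", {
  set.seed(311)
  fx <- effects_fixture(seed = 312)
  # build a trait whose QTL all sit on LG2
  on_lg2 <- which(fx$g$map$lg == 2)
  qtl <- sample(on_lg2, 8)
  b <- rnorm(8)
  gv <- drop(scale(fx$g$dosages[, qtl], scale = FALSE) %*% b)
  gv <- gv / sd(gv) * sqrt(0.5)
  y <- gv + rnorm(length(gv), sd = sqrt(0.5))
  names(y) <- names(fx$y)
  fit <- reml_fit(y, fx$G, se = FALSE)
  bk <- lg_decompose(backsolve_ase(blup_values(fit), fx$g, fx$G), fx$g)
  v <- sapply(setdiff(names(bk), c("id", "total")), function(cl) var(bk[[cl]]))
  expect_equal(names(which.max(v)), "LG2")
})

test_that("LG-level genetic correlations: identity, shared-QTL sign reversal, disjoint null", {
  fx <- effects_fixture()
  ase <- backsolve_ase(blup_values(fx$fit), fx$g, fx$G)
  bk <- lg_decompose(ase, fx$g)
  self <- lg_genetic_correlations(bk, bk)
  expect_true(all(self$r_g[!is.na(self$r_g)] == 1))
  expect_equal(self$lg[nrow(self)], "genome")

  # two traits: opposite-sign shared QTL on LG5, positively correlated
  # polygenes elsewhere -> LG5 r_g negative, genome-level r_g positive
  set.seed(313)
  on_lg5 <- which(fx$g$map$lg == 5)
  xq <- drop(scale(fx$g$dosages[, sample(on_lg5, 1)], scale = FALSE))
  other <- which(fx$g$map$lg != 5)
  bshared <- rnorm(length(other))
  poly <- drop(scale(fx$g$dosages[, other], scale = FALSE) %*% bshared)
  mk <- function(sign_q) {
    gvv <- sign_q * xq / sd(xq) * sqrt(0.3) + poly / sd(poly) * sqrt(0.3)
    y <- gvv + rnorm(length(gvv), sd = sqrt(0.4))
    names(y) <- names(fx$y)
    reml_fit(y, fx$G, se = FALSE)
  }
  fa <- mk(1); fb <- mk(-1)
  bka <- lg_decompose(backsolve_ase(blup_values(fa), fx$g, fx$G), fx$g)
  bkb <- lg_decompose(backsolve_ase(blup_values(fb), fx$g, fx$G), fx$g)
  rg <- lg_genetic_correlations(bka, bkb)
  expect_lt(rg$r_g[rg$lg == "LG5"], -0.3)
  expect_gt(rg$r_g[rg$lg == "genome"], 0)

  # disjoint QTL sets: per-LG r_g centered near zero
  set.seed(314)
  mk2 <- function(cols) {
    b <- rnorm(length(cols))
    gvv <- drop(scale(fx$g$dosages[, cols], scale = FALSE) %*% b)
    y <- gvv / sd(gvv) * sqrt(0.4) + rnorm(length(gvv), sd = sqrt(0.6))
    names(y) <- names(fx$y)
    reml_fit(y, fx$G, se = FALSE)
  }
  f1 <- mk2(which(fx$g$map$lg == 1)[1:6])
  f2 <- mk2(which(fx$g$map$lg == 3)[1:6])
  bk1 <- lg_decompose(backsolve_ase(blup_values(f1), fx$g, fx$G), fx$g)
  bk2 <- lg_decompose(backsolve_ase(blup_values(f2), fx$g, fx$G), fx$g)
  rg2 <- lg_genetic_correlations(bk1, bk2)
  expect_lt(abs(mean(rg2$r_g[rg2$lg != "genome"], na.rm = TRUE)), 0.35)
})

test_that("zero-variance LG partial values yield NA correlations", {
  bk_a <- tibble::tibble(id = c("a", "b", "c"), LG1 = c(0, 0, 0),
                         LG2 = c(1, 2, 3), total = c(1, 2, 3))
  class(bk_a) <- c("lg_breakdown", class(bk_a))
  bk_b <- bk_a
  rg <- lg_genetic_correlations(bk_a, bk_b)
  expect_true(is.na(rg$r_g[rg$lg == "LG1"]))
  expect_equal(rg$r_g[rg$lg == "LG2"], 1)
})

test_that("compare_ase trivial identities and scatter output", {
  fx <- effects_fixture()
  ase <- backsolve_ase(blup_values(fx$fit), fx$g, fx$G)
  self <- compare_ase(ase, ase)
  expect_equal(self$correlation, 1)
  flip <- ase
  flip$effect <- -flip$effect
  both_flipped <- compare_ase(flip, flip)
  expect_equal(both_flipped$correlation, 1)  # global sign flip invariant
  expect_named(self$scatter, c("snp_id", "effect_single", "effect_all"))
  expect_error(compare_ase(ase$effect, ase$effect[-1]), "length")
})

test_that("single-SNP and all-SNP effects correlate on polygenic traits", {
  fx <- effects_fixture(seed = 315, n = 400, m = 400)
  Gb <- blend_kinship(fx$G, 0.01)
  fit <- reml_fit(fx$y, Gb, se = FALSE)
  sc <- emmax_scan(fx$y, Gb, fx$g)
  ase <- backsolve_ase(blup_values(fit), fx$g, Gb)
  cmp <- compare_ase(sc, ase)
  expect_gt(cmp$correlation, 0.7)
})

test_that("single-major-QTL runs rank the same SNP top in both methods", {
  hits <- sapply(1:5, function(r) {
    fx <- effects_fixture(seed = 320 + r, n = 250, m = 250, n_qtl = 1,
                          h2 = 0.35)
    Gb <- blend_kinship(fx$G, 0.01)
    fit <- reml_fit(fx$y, Gb, se = FALSE)
    sc <- emmax_scan(fx$y, Gb, fx$g)
    ase <- backsolve_ase(blup_values(fit), fx$g, Gb)
    ase$snp_id[which.max(abs(ase$effect))] == sc$snp_id[which.max(abs(sc$t))]
  })
  expect_gte(mean(hits), 0.8)
})
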