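# Independent oracles used across test files. These deliberately use naive
# direct computations (dense inversions, gene dropping, closed forms) so they
# share no code path with the package implementations they check.

# Restricted log-likelihood by direct dense matrix algebra:
# V = sigma_a2 * (K + lambda I). Same constant convention as the package
# (the standard -1/2 [log|V| + log|X'V^-1 X| + y'Py] form), so values are
# directly comparable.
naive_reml_ll <- function(lambda, y, K, X) {
  n <- length(y)
  p <- ncol(X)
  H <- K + lambda * diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  S <- drop(t(r) %*% Hi %*% r)
  sigma_a2 <- S / (n - p)
  as.numeric(
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma_a2) + (n - p) +
              determinant(H)$modulus + determinant(XtHiX)$modulus))
}

# direct-inversion REML: profile over log(lambda) with optimize()
naive_reml_fit <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  opt <- optimize(function(ll) naive_reml_ll(exp(ll), y, K, X),
                  interval = log(c(1e-5, 1e5)), maximum = TRUE, tol = 1e-8)
  list(lambda = exp(opt$maximum), logl = opt$objective)
}

# realized IBD relationship by gene dropping through a pedigree
gene_drop_A <- function(ped, n_reps = 5000) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  acc <- matrix(0, n, n)
  next_allele <- 0L
  for (r in seq_len(n_reps)) {
    al <- matrix(0L, n, 2)
    for (i in seq_len(n)) {
      al[i, 1] <- if (is.na(si[i])) (next_allele <- next_allele + 1L) else
        al[si[i], sample(1:2, 1)]
      al[i, 2] <- if (is.na(di[i])) (next_allele <- next_allele + 1L) else
        al[di[i], sample(1:2, 1)]
    }
    # numerator relationship = 2 * realized kinship; the same allele-match
    # count formula covers the diagonal (giving 1 + realized inbreeding)
    for (i in seq_len(n)) {
      for (j in i:n) {
        share <- (sum(al[i, 1] == al[j, ]) + sum(al[i, 2] == al[j, ])) / 2
        acc[i, j] <- acc[i, j] + share
      }
    }
  }
  A <- acc / n_reps
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# small cached simulated populations (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

small_pop <- function(key = "default", seed = 101, contamination = 0,
                      family_sizes = c(40, 35, 30, 30, 25, 25, 15),
                      snps_per_lg = 30, n_lg = 5, arch = NULL,
                      missing_rate = 0) {
  cache <- paste0(key, seed)
  if (!is.null(.fixture_env[[cache]])) return(.fixture_env[[cache]])
  design <- sim_design(family_sizes = family_sizes, n_lg = n_lg,
                       snps_per_lg = snps_per_lg,
                       contamination_rate = contamination)
  if (is.null(arch)) {
    arch <- trait_architecture(
      traits = tibble::tibble(trait = "T1", h2 = 0.4, binary = FALSE,
                              prevalence = NA),
      qtl = tibble::tibble(trait = "T1", lg = 1L, bp = 2e7, share = 0.1,
                           sign = 1)
    )
  }
  pop <- sim_population(design, arch, seed = seed,
                        missing_rate = missing_rate)
  .fixture_env[[cache]] <- pop
  pop
}

# offspring-only, monomorphic-filtered genotypes of a population
offspring_genotypes <- function(pop) {
  filter_monomorphic(subset_genotypes(pop$genotypes, pop$true_parents$id))
}
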