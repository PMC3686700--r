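---
title: "Models and methods for family-based GWAS with realized relationships"
author: "fsgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for family-based GWAS with realized relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsgwas)
```

# The setting

Outbred perennial crops such as apple are bred in large full-sib families:
a handful of elite parents are crossed in a factorial design and a thousand
or more seedlings are phenotyped for fruit quality. Such populations are
attractive for association mapping — linkage disequilibrium (LD) extends
over hundreds of kilobases, so a few thousand SNPs cover the genome — but
every analysis must contend with strong, partly *cryptic* relatedness:
recorded pedigrees miss pollen contamination and historical co-ancestry.

`fsgwas` implements the full analysis chain for this setting:

1. expected (pedigree **A**) versus realized (marker **G**) relationship
   matrices and their comparison;
2. a single-kinship linear mixed model fitted by REML, with a
   likelihood-ratio measure of variance explained;
3. an EMMAX-style single-SNP association scan with BIC-selected principal
   component covariates;
4. back-solving of per-SNP allele substitution effects (ASEs) from genomic
   breeding values, linkage-group (LG) level decomposition and genetic
   correlations;
5. LD decay profiling; and
6. an analytic power calculator for related samples, with a Monte-Carlo
   validator.

Because no real data ship with the package, a synthetic-data module
generates populations with the statistical structure that the analysis
assumes; all tests run against it.

# The mixed model and R²_LR

The core model is

$$y = X\beta + a + \epsilon, \qquad
  a \sim N(0, K\sigma_a^2), \quad \epsilon \sim N(0, I\sigma_e^2),$$

with $K$ either the pedigree numerator relationship matrix **A** (built by
the tabular recursion in `pedigree_A()`) or the VanRaden genomic matrix
$G = MM'/(2\sum_i p_i q_i)$ (`vanraden_G()`), where $M$ holds dosages
centered by twice the observed allele frequency. `reml_fit()` maximizes the
*restricted* likelihood through a one-time eigendecomposition of $K$: the
profile over $\lambda = \sigma_e^2/\sigma_a^2$ is evaluated on a 100-point
log-spaced grid on $[10^{-5}, 10^{5}]$ and refined by Brent search to
$10^{-8}$ in $\log\lambda$. The ordinary (ML) likelihood is profiled the
same way and reported alongside.

Goodness of fit is summarized by the likelihood-ratio variance explained

$$R^2_{LR} = 1 - \exp\!\left(-\tfrac{2}{n}(\log L_M - \log L_0)\right),$$

with $\log L_0$ from the intercept-only model. Two conventions matter and
are fixed as follows:

* When the model and the null share the same fixed effects (comparing **A**
  with **G** fits), both likelihoods are *restricted*, which keeps the
  comparison internally consistent.
* When the fixed effects differ between numerator and null — the per-SNP
  and joint $R^2_{LR}$ of the association scan — restricted likelihoods of
  different fixed-effect sets are not comparable, so the scan uses profile
  *maximum* likelihoods at the null-model variance ratio (the EMMAX
  approximation). This choice makes $R^2_{LR}$ reduce exactly to the
  classical coefficient of determination for fixed-effects-only
  regressions, and makes the joint value of several SNPs nest above each
  single-SNP value.

## Two heritability scales

`reml_fit()` reports both `h2` $= \sigma_a^2/(\sigma_a^2+\sigma_e^2)$ and
`h2_realized`. The distinction is the reference base of $K$: $\sigma_a^2$
is the additive variance *per unit of K*, while the realized genetic
variance in the analyzed sample is
$\sigma_a^2\,(\overline{\mathrm{diag}\,K} - \overline{K}_{off})$. For a
marker matrix built with sample allele frequencies on a set of full-sib
families the mean diagonal of $G$ is well below 1 (about 0.86 in the
default simulated design), so the two scales differ by several points of
heritability. Parameter-recovery checks against the simulator — whose
heritability is defined as a realized variance ratio — therefore use
`h2_realized`; `h2` matches what REML software reports.

# The association scan

`emmax_scan()` fits the unified mixed model with the SNP and optional
principal components as fixed effects. Variance components are estimated
once, on the null model without any SNP, and reused for every test (the
EMMAX approximation): each SNP then requires only a generalized least
squares regression in the eigenspace of $K$, and the SNP coefficient is
tested two-sided against $t_{n-p}$ with $p = 1 + \#\text{PCs} + 1$ fixed
parameters. An exact check that re-estimates the variance ratio per SNP is
part of the test suite; at $n = 200$ the two agree to well under 0.05 in
$-\log_{10} p$.

The number of PC covariates is chosen by forward selection on
$\mathrm{BIC} = -2\log L + k\log n$ with $k$ the number of fixed-effect
parameters and $\log L$ the ML value (`select_pcs_bic()`); ties prefer
fewer PCs. Genome-wide significance uses a fixed per-test threshold
($p < 5\times10^{-7}$ by default); `genomewide_threshold()` reports the
implied genome-wide level (e.g. $2500 \times 5\times10^{-7} = 0.00125$) but
the per-test rule is what declares significance. `joint_r2()` prunes
significant SNPs greedily to the largest-|t| SNP per 5-Mb window within
each LG (windows anchored at the top SNP, ties to the smaller position) and
refits the kept SNPs jointly. `qq_data()` supplies Q-Q coordinates and the
genomic inflation factor $\lambda_{GC}$.

# SNP effects, LG decomposition and genetic correlations

With the **G**-based fit, the breeding values $\hat a$ are equivalent to
ridge regression on all SNPs (RR-BLUP), and per-SNP allele substitution
effects are recovered by

$$\hat\alpha = (2{\textstyle\sum_i} p_i q_i)^{-1} M' G^{-1} \hat a .$$

(Printed forms of this back-solving equation sometimes confuse $\hat a$
and $\hat\alpha$ on the right-hand side; the implementation uses the
breeding-value vector, the only reading under which the RR-BLUP
equivalence holds.) Because $G$ built from sample
frequencies is singular by construction ($G\mathbf{1} = 0$) the inverse is
taken as the eigendecomposition pseudo-inverse; $\hat\alpha$ is unaffected
by the null-space ambiguity since $\mathrm{null}(G) = \mathrm{null}(M')$.
With the exact $G$, $M\hat\alpha$ reproduces $\hat a$ to numerical
precision, and the test suite verifies the identity with ridge regression
to $10^{-8}$ relative. When a blended $G$ is used instead, the aggregation
error is reported rather than hidden.

`lg_decompose()` splits each seedling's breeding value into per-LG partial
values (centered dosages times effects, so partial values are mean-zero
per LG and sum exactly to $M\hat\alpha$), and
`lg_genetic_correlations()` correlates partial values across individuals
per LG, next to the genome-level correlation of total breeding values —
the BLUP-correlation proxy for genetic correlation, not a multi-trait REML
estimate. Genome-level values use **G**-based BLUPs.

# Power under cryptic relatedness

For a marker explaining a fraction $v_m = r^2 \cdot q$ of phenotypic
variance ($r^2$ the marker-QTL LD, $q$ the QTL variance fraction), the
regression t statistic has non-centrality

$$\delta_t = \sqrt{\frac{n\,v_m}{1 - v_m}}
  \cdot \frac{\Gamma(v/2)\sqrt{2/v}}{\Gamma((v-1)/2)}, \qquad v = n - 2,$$

assembled from the marker regression coefficient $b = D\alpha/(p_m q_m)$
and its sampling deviation $\sigma_b$. Note that at fixed $r^2$ and QTL
variance fraction the allele frequencies cancel exactly in this additive
derivation — they enter only through feasibility of the implied $D$ — and
the Monte-Carlo validator confirms the invariance empirically. A frequency
effect on power at fixed "LD" arises only under a different LD
parametrization (e.g. holding $D$ rather than $r^2$ fixed), which the
calculator does not adopt.

Relatedness enters through the ratio
$R \approx 1 - r^2 h^2 (1 - h^2)$ (here $r$ is the coefficient of
relationship): `power_t()` computes the non-central-t tail probability at
$\delta_t^* = \delta_t R$. Since $R$ is defined as a ratio of
non-centrality parameters, the linear scaling is the default; a
$\sqrt{R}$ variant is available (`ncp_scale = "sqrt"`) because designs
exist (notably related *pairs*) whose exact information ratio corresponds
to the square root.

The default test convention is two-sided, matching the $t_{\alpha/2}$
notation of the power expression. The printed headline value for this kind
of design — power 0.78 at $n = 1120$, $r^2 = 0.25$, a 2% QTL and
$p = q = 0.5$ — corresponds to the *directional* (one-sided) test at
$\alpha = 0.05$, which gives 0.766 analytically against 0.66 for the
two-sided version; the Monte-Carlo validator reproduces the one-sided
value. Reproduction of that number therefore uses `sided = "one"`.

## The Monte-Carlo validator

`mc_power_validate()` simulates marker/QTL haplotypes with
$D = r\sqrt{p_m q_m p_q q_q}$ and, for related samples, full-sib-like
families of 3 with exchangeable genotype correlation $r$ (each member
copies a family reference haplotype with probability $\sqrt{r}$) and a
shared polygenic effect giving within-family phenotype correlation
$r h^2$. The test applied per replicate is the regression t test computed
by GLS under the true block-equicorrelated covariance — the
structure-corrected association test whose information loss the ratio $R$
describes. A naive OLS test in related samples does *not* realize the $R$
correction: correlation between relatives' genotypes and phenotypes
inflates the variance of the OLS statistic rather than deflating its mean,
and the measured power loss is only about a fifth of the $R$ prediction.
The family size of 3 is a design choice made analytically: the exact
NCP² ratio of the equicorrelated family-GLS design,
$[m - \rho(m + m(m-1)r)/(1+(m-1)\rho)]/(m(1-\rho))$ with $\rho = r h^2$,
matches $R^2$ almost exactly at $m = 3$ for mid-range heritabilities, so
the validator's exact design and the analytic approximation coincide and
agreement within Monte-Carlo error is a meaningful check rather than a
coincidence.

# The synthetic-data generator

`sim_population()` emulates a factorial full-sib trial:

* **Mating design.** 4 female x 2 male founders, one failed cross, seven
  families with sizes (350, 300, 180, 120, 90, 120, 40) — 1,200 seedlings.
* **Genome.** 17 linkage groups of 40 Mb (80 cM at the default
  500 kb/cM), 147 SNPs per LG (2,499 total) at uniform random positions;
  LG length chosen so the default trait architecture's QTL positions (up
  to 32.8 Mb) fit on their linkage groups.
* **Founder LD.** Haplotypes are thresholded latent Gaussian AR(1)
  processes with correlation $e^{-d/\ell}$ over distance $d$; the
  correlation length $\ell$ defaults to 1 Mb, which puts the simulated
  offspring mean $r^2$ at 500 kb in the 0.20-0.30 range typical of
  advanced breeding material. Sites at identical positions are exact
  copies; founder-monomorphic sites get one flipped haplotype so every
  marker segregates.
* **Meiosis.** Poisson crossover counts from the map length per LG
  (Haldane, no interference), uniform placement.
* **Contamination.** A fraction of offspring (default 5%; the real rate in
  such trials is unknown, so it is a parameter) receive their paternal
  gamete from a separate pool of contaminant pollen donors while the
  pedigree keeps the design father — this is what makes pedigree and
  marker relationships genuinely disagree, and makes PCA show break-away
  groups.
* **Traits.** Six fruit-quality-like traits with mixed architectures:
  large-effect QTL (some shared between trait pairs, some hidden, i.e.
  not genotyped, so marker-QTL LD is below 1) plus per-LG polygenic
  background with optional between-trait correlation, plus Gaussian
  residual. The residual is orthogonalized against the genetic value and
  rescaled so the realized heritability equals the target exactly for
  continuous traits. Binary disorder traits are liability-thresholded at
  their prevalence and analyzed as 0/1 scores, as presence/absence
  disorder scores are in practice.

What the generator does *not* emulate: genotyping error beyond missingness
masking, dominance and epistasis, selection during the trial,
environmental trends, or sequence-level mutation. Tests passing on this
synthetic structure show that the estimators recover what they claim under
the model's own assumptions — not that any particular real dataset
satisfies those assumptions.

# Numerical choices and degenerate inputs

* Kinship matrices must be positive semi-definite; `blend_kinship()`
  ($(1-\epsilon)G + \epsilon I$, default $\epsilon = 0.01$) guarantees a
  positive-definite matrix where an inverse or a well-conditioned REML fit
  is needed.
* `reml_fit()` flags an identity kinship as unidentifiable (only the sum
  $\sigma_a^2 + \sigma_e^2$ is then estimable) instead of returning an
  arbitrary split silently.
* Monomorphic SNPs: rejected by `vanraden_G()` (they carry no relationship
  information and break the centering), skipped with missing results by
  the scan, removable with `filter_monomorphic()`.
* The QC order is fixed and reported: missingness filter first, then the
  opposite-homozygote Mendel check (default thresholds 5% for both; the
  Mendel threshold has no published value and is a package default).
* Mean-dosage imputation deliberately preserves observed-call allele
  frequencies; it is a linear-model-friendly stand-in for haplotype-aware
  imputation and the interface allows plugging alternatives.
* PCA uses the SVD of the column-centered (optionally standardized) dosage
  matrix with a deterministic sign convention (largest-magnitude loading
  positive).
* Half-open distance bins $[lo, hi)$ for LD profiles; empty bins are
  reported with missing means, never dropped.

# Problem sizes used by the checks

The acceptance-style tests run at desk scale, chosen to keep the full
suite comfortably within a half-hour on one core while leaving the
estimators' sampling error well inside the asserted tolerances: heritability
recovery uses 50 populations of 1,000 seedlings x 2,499 SNPs; the
EMMAX-versus-exact comparison uses n = 200, m = 500; the type-I error check
uses 50 null traits x ~2,500 SNPs at n = 400; the contaminated-pedigree
comparison uses 50 populations at n = 400, m ~ 800 with a 20% contamination
rate; the power grid uses 5,000 Monte-Carlo replicates per cell on a
3 x 3 grid of QTL variance x relatedness at $h^2 = 0.5$.

# Known limitations

* On traits with *no* familial component at all (iid noise), the scan is
  mildly conservative (empirical type-I error near 0.036 at nominal 0.05):
  the fitted variance component absorbs the trait's chance alignment with
  G and deflates exactly the directions that would otherwise drive
  rejections. On the polygenic null the model is built for — family
  resemblance present, no QTL — the scan is calibrated (0.050 measured in
  the test suite).
* The EMMAX approximation slightly misstates p-values when a SNP explains
  a large variance fraction (the null variance components are then wrong
  for that SNP). Exact per-SNP REML re-estimation is itself fragile at a
  few hundred individuals: the profile likelihood over the variance ratio
  is nearly flat, and for a small minority of SNPs the per-SNP refit
  crosses into a different regime (including the boundary
  $\sigma_a^2 = 0$), moving $-\log_{10} p$ by several tenths while the
  likelihood changes by a fraction of a nat. Median agreement between the
  two is well under 0.01 in $-\log_{10} p$ at $n = 200$; worst-case
  agreement over hundreds of SNPs is not a meaningful target at that
  sample size.
* The BLUP-correlation proxy for genetic correlations is shrinkage-biased
  towards the within-LG information content and is not a substitute for
  multi-trait REML.
* The analytic power formula treats the marker test in isolation; it does
  not model multiple testing across a panel.
* `h2_se` is an observed-information delta-method approximation; near the
  $\sigma_a^2 = 0$ boundary it is only indicative.
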