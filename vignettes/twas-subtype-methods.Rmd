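---
title: "Methods: summary-statistics TWAS with subtype heterogeneity and conditional analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics TWAS with subtype heterogeneity and conditional analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twaskit)
```

## The problem

A transcriptome-wide association study (TWAS) asks whether the genetically
regulated component of a gene's expression is associated with a trait. It
needs only two ingredients: (i) a modest reference panel of individuals with
both genotypes and expression in a relevant tissue, used to learn per-gene
SNP weights, and (ii) GWAS summary statistics (z-scores) for the trait.
`twaskit` implements this pipeline for the specific setting of disease
subtypes — here estrogen-receptor positive (ER+) and negative (ER−) breast
cancer — where four scans are available: overall disease, each subtype
against shared controls, and a *case-only* scan contrasting ER+ with ER−
patients directly.

## The statistic

For one gene, let $w$ be the expression-prediction weights over its cis
SNPs, $z$ the harmonized GWAS z-scores and $\Sigma$ the SNP correlation (LD)
matrix from the reference panel. Under the null that no weighted SNP is
associated with the trait,

$$ z_{TWAS} \;=\; \frac{w' z}{\sqrt{w' \Sigma w}} \;\sim\; N(0, 1). $$

Because the reference panel is small, $\Sigma$ is noisy and possibly
singular, so the pipeline uses the ridge-regularized form
$\Sigma_{adj} = (\Sigma + \lambda I)/(1+\lambda)$ with $\lambda = 0.1$.
Dividing by $1+\lambda$ (rather than leaving the raw diagonal inflation in
place) keeps the diagonal exactly 1, which has two consequences we consider
contractual: a single-SNP gene's statistic equals its GWAS z-score, and the
statistic keeps unit variance under the null. The smallest eigenvalue of
$\Sigma_{adj}$ is at least $\lambda/(1+\lambda)$, so downstream inversions
are well posed. Two-sided p-values use `pnorm`, whose complementary-error-
function tail is accurate far below the $10^{-30}$ scale that strong loci
reach.

## Which genes get weights

Genes are screened before testing:

1. **cis-heritability.** A single-variance-component model
   $y = Xb + g + e$, $g \sim N(0, \sigma^2_g A)$, $e \sim N(0, \sigma^2_e I)$,
   with $A$ the GCTA-style relationship matrix built from standardized
   cis dosages, is fit by average-information REML with
   expectation-maximization fallback steps (convergence when the relative
   change in restricted likelihood falls below $10^{-6}$; variance
   components clamped at $10^{-8}$ of the phenotypic variance so the
   likelihood stays finite). Because the alternative optimum frequently sits
   on the $\sigma^2_g = 0$ boundary, where EM creeps, the fit always
   compares against the boundary solution and adopts it when it is better —
   this guarantees the nesting $\ell_{alt} \ge \ell_{null}$. The
   significance of $\sigma^2_g$ comes from a likelihood-ratio test referred
   to the boundary-corrected 50:50 mixture of a point mass at zero and
   $\chi^2_1$; genes with $p > 0.01$ are excluded.
2. **Prediction accuracy.** Five weight models are trained on
   covariate-residualized expression and column-standardized dosages:
   ridge/BLUP with shrinkage fixed by the REML variance ratio; lasso and
   elastic net (mixing 0.5) by coordinate descent with the penalty chosen by
   inner fivefold cross-validation over 50 log-spaced penalties spanning
   three decades down from the all-zero point; the single best marginal
   eQTL; and a spike-and-slab Gibbs sampler (posterior-mean weights,
   inclusion probability given a Beta prior, slab variance initialized from
   the estimated heritability) standing in for the Bayesian sparse linear
   mixed model — a deliberate approximation, adopted because full BSLMM
   MCMC adds substantial machinery without changing any quantity this
   package reports, and its limiting behaviour (spike disabled) provably
   approaches the BLUP, which we test.
   Accuracy is the squared Pearson correlation between concatenated
   out-of-fold predictions and observed expression (fivefold, disjoint
   folds). A gene qualifies if *any* model reaches cv $r^2 \ge 0.01$; the
   best model supplies the weights, ties broken by a fixed order (enet,
   lasso, blup, sparse Bayes, top eQTL). This "any model qualifies, best
   model supplies" reading resolves an ambiguity in how the two filters
   interact and matches the gene counts the screens imply.

The cis window is a parameter. Published descriptions of this kind of
pipeline vary between a 500 *base-pair* window around the transcription
start site and 500 kb around the gene boundary; the package defaults to
**500 kb around the gene boundary**, the only reading compatible with
per-gene cis SNP counts in the tens to hundreds, and leaves the window
fully configurable.

## Harmonization and input filters

GWAS records are matched to the panel by SNP id with a
(chromosome, position, allele-set) fallback, z-signs are flipped when
effect/other alleles are swapped, strand flips are resolved by
complementation when unambiguous, and A/T, C/G SNPs are dropped by default
(no frequency-based disambiguation is attempted). Irreconcilable allele
pairs are dropped and counted, never silently kept; harmonization is
idempotent. Standard post-imputation filters (MAF > 0.005,
imputation $r^2$ > 0.3, both strict) are applied via per-SNP metadata.

## The case-only heterogeneity test

Applying the TWAS statistic to case-only z-scores tests
$H_0\!: \beta_2 - \beta_1 = 0$, where $\beta_1, \beta_2$ are the expression
log odds ratios for ER+ and ER− disease in a multinomial model. The
package fixes the orientation **effect allele increases the odds of ER−
versus ER+ disease**, so a positive case-only statistic means a stronger
ER− effect; the contrast direction is a pure convention (the statistic's
null is direction-free), and all sign-dependent outputs document it. Subtype labels are deterministic
functions of the four scan p-values at a threshold (shared or
scan-specific): ER+-specific means case-only *and* ER+ significant with
ER− not, etc.

## Conditional and joint analyses

All conditional algebra happens at the z-score level with the standardized
summary-statistics identities for linear-combination features — the
standard conditional-and-joint algebra, validated here against
individual-level regression oracles:

* SNP on genes: $z_{cond} = (z_s - \rho' R^{-1} z_g) / \sqrt{1 - \rho' R^{-1} \rho}$,
  with $\rho_s = (\Sigma w)_s / \sqrt{w' \Sigma w}$ the SNP-feature
  correlations and $R$ the feature correlation matrix
  $r_{jk} = w_j' \Sigma w_k / \sqrt{(w_j'\Sigma w_j)(w_k'\Sigma w_k)}$.
  When $1 - \rho' R^{-1}\rho \le 0$ the SNP is reported as fully explained
  (conditional p 1) rather than producing an imaginary standard error.
* Genes jointly: $b = R^{-1} z$, per-gene joint $z_i = b_i / \sqrt{(R^{-1})_{ii}}$.
  Features with $|r| > 0.95$ are collapsed before inversion, keeping the
  smallest marginal p — regions inside inversion polymorphisms can hold
  half a dozen near-identical features and unpruned inversion of their
  correlation matrix is numerically meaningless. If $R$ is still singular
  it is ridge-stabilized with $\epsilon = 10^{-6}$ and a warning. A gene is
  "retained" when its joint p < 0.05.
* Regions merge genes chained by pairwise distance ≤ 500 kb (transitive
  closure, implemented with `GenomicRanges::reduce`).
* Region summaries report the count of genome-wide-significant
  (p < 5×10⁻⁸) SNPs before and after conditioning, their ratio
  $(n_{before}-n_{after})/n_{before}$, and the magnitude of change in the
  minimum p, $p_{index}/p_{min,cond}$. When nothing was significant before
  conditioning the ratio is 1 by convention (nothing remained to explain)
  and flagged. The magnitude is *not* bounded below by 1; it equals 1
  exactly when the index SNP's p is unchanged.

Which scan feeds the conditional analyses is an explicit parameter (the
published tables used the ER+ scan; the analysis scripts follow that).

## The synthetic-data generator

No reference data ship with the package: the genotype-expression panel the
published analysis used is access-controlled, and the GWAS inputs are
hundreds of gigabytes. The generator therefore emulates the study
conditions with known truth:

* **Genotypes.** Haplotypes are a latent first-order autoregressive
  Gaussian field along the SNP index (autocorrelation `ld_rho`),
  thresholded at per-SNP allele-frequency quantiles drawn uniformly from
  `maf_range` (default [0.05, 0.5], the panel's MAF filter). This gives
  tunable, monotonically decaying LD without a coalescent simulator. It
  does not reproduce recombination hotspots, allele-frequency spectra or
  population stratification — so passing calibration here says the
  *statistics* behave, not that real-panel QC is unnecessary.
* **Expression.** A linear predictor over `n_causal_eqtl` standardized
  dosages plus Gaussian noise, variance fractions `h2_cis` and
  `1 - h2_cis`.
* **Summary statistics.** z-scores are drawn directly as multivariate
  normal with unit marginal variance and the panel LD as covariance —
  matching the summary-level inputs of the real pipeline and keeping
  desk-scale runtime — with per-SNP means set by the architecture:
  *mediated* routes everything through expression
  (mean $= \sqrt{N_{eff}}\,\alpha\,\mathrm{cor}(g_s, E)$, with
  $N_{eff} = 4/(1/n_{case}+1/n_{control})$), *pleiotropic* adds a direct
  effect at a zero-weight SNP adjacent to the causal eQTL, *colocalized*
  places the disease signal only at that neighbouring SNP, and *null* has
  zero means. The case-only mean is proportional to
  $\alpha_{-} - \alpha_{+}$, consistent with the test's orientation. The
  default GWAS sample sizes are the emulated study's (69,501 ER+ cases,
  21,468 ER− cases, 105,974 controls); expression-on-disease effect sizes
  are user-set, since no canonical effect-size distribution exists for
  these loci.
* **Seeds.** One master seed; per-stage sub-streams are derived
  deterministically, so identical configurations give byte-identical
  outputs.

## Numerical and scale choices

Monomorphic columns that the thresholding occasionally produces are given a
single minor-allele copy so every SNP is usable downstream. The REML solver
rotates into the relationship matrix's eigenbasis, making each iteration
linear in sample size and letting many phenotypes (genes, or simulation
replicates) share one decomposition via `grm_eigen()`. The test suite and
the acceptance script size their simulations to finish in minutes on one
core: type-I-error checks use 1000–2000 z-level replicates on 20-SNP loci;
heritability recovery uses panels of 500–1000 individuals with 50–60 SNPs
and 100–200 expression replicates; the brute-force restricted-likelihood
grid oracle runs on 40-individual toys. These sizes are the package's
choices for tight Monte-Carlo error at interactive runtimes; all are plain
function arguments.

## Known limitations

* The spike-and-slab sampler is an approximation to BSLMM; its cv-$r^2$ is
  competitive on simulated architectures but it is not the published
  sampler.
* Strand-ambiguous SNPs are dropped rather than frequency-disambiguated.
* The case-only equivalence to the multinomial contrast is an approximation
  whose accuracy degrades at extreme case imbalance; the package applies
  the test as stated and leaves that caveat to the reader.
* Single-tissue only; cross-tissue extensions are out of scope.
* No binary genotype formats (BGEN/PGEN), no liftover, no multi-allelic
  sites; genotype input is transposed-PLINK text or VCF.
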