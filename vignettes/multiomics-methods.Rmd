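---
title: "Multi-omics kernel models for complex traits: methods and design notes"
author: "omicpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics kernel models for complex traits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`omicpred` analyses complex traits measured on a panel of inbred plant
lines observed under a paired two-level treatment (here labelled
`control` and `water_scarce`), with three whole-genome omic layers
available as predictors: SNP genotypes, DNA methylation levels and gene
expression (TPM). The package covers the full analysis path: quality
control of each layer, similarity-kernel construction, a multi-kernel
Bayesian linear mixed model with posterior variance partitioning,
replicated cross-validated prediction accuracy with formal model
comparison, and a genome-wide three-path mediation scan. A synthetic-data
generator with recorded ground truth makes every stage testable without
any external download.

# The model

The central model regresses a trait on treatment means plus a sum of
random effects whose covariance structures come from the omic layers:

$$y_{ij} = \mu_j + L_i + u_i + g_{ij} + m_{ij} + \varepsilon_{ij}$$

where $y_{ij}$ is the phenotype of line $i$ under treatment $j \in \{1,2\}$,
$\mu_j$ are treatment means with flat priors, $L_i \sim N(0, \sigma_L^2)$ is
an iid line effect, and $u \sim \mathrm{MVN}(0, K_{SNP}\sigma_u^2)$,
$g \sim \mathrm{MVN}(0, K_{GE}\sigma_g^2)$,
$m \sim \mathrm{MVN}(0, K_{M}\sigma_m^2)$ are kernel-structured effects for
genotype, expression and methylation. Genotype and methylation are
measured once per line, so $u$ and $m$ index lines; expression is
sampled per (line, treatment) record, so $g$ indexes samples and its
kernel is built on samples. Residuals are iid Gaussian. Seven nested
variants are exposed through `model_variants()`: `L`, `LG`, `LM`, `LT`,
`LGM`, `LGT`, `LGMT`, where G/M/T add the SNP, methylation and
transcriptome kernels.

## Kernels

`similarity()` computes $K = WW'/p$ from the centered-scaled matrix $W$
(`center_scale()`: column mean 0, sample SD 1 with the $n-1$ denominator,
missing cells mean-imputed, zero-variance columns dropped). This is the
VanRaden-style additive relationship matrix when applied to dosages. With
sample-SD scaling the diagonal mean is exactly $(n-1)/n$, i.e. 1 up to a
finite-sample factor; tests assert this identity rather than an
asymptotic 1. An optional PCA truncation (`pca_var < 1`) replaces $W$ by
its leading principal components before forming $K$, a denoising option
for the expression layer; the default retains all components because no
principled component count is available a priori, and the truncated and
exact kernels coincide at `pca_var = 1` (a tested identity). Kernels that
develop small negative eigenvalues numerically are repaired by clipping
at zero.

## Priors and sampling

Every variance parameter has a scaled-inverse-$\chi^2$ prior with 5 prior
degrees of freedom. Prior scales follow the convention of standard
Bayesian genomic-prediction software: the prior mode of each non-residual
component is an equal share of half the phenotypic variance, divided by
the kernel's mean diagonal, and the residual prior mode is the other
half (`R2 = 0.5`, both configurable). The mode of a
scaled-inverse-$\chi^2(\nu, S)$ is taken as $\nu S/(\nu + 2)$.

The Gibbs sampler (compiled, single-threaded) works in the eigenbasis of
each kernel: with $K = VDV'$, the effect is $u = Va$ with independent
prior coordinates $a_r \sim N(0, d_r\sigma^2)$, and each coordinate has a
scalar Gaussian full conditional. Eigenvalues below `1e-10` are
truncated. Treatment means are drawn from their Gaussian full
conditionals (flat prior); variances from their conjugate
scaled-inverse-$\chi^2$ full conditionals. Chains default to 30,000
iterations, 5,000 burn-in, thinning 5; an effective-sample-size check
warns when any variance chain falls below ESS 200. Chains are bitwise
reproducible from the seed because all draws use R's RNG.

Records with a missing trait value never enter the likelihood, but their
effect coordinates are still drawn — for a held-out line the coordinate's
full conditional reduces to the conditional prior given the training
lines through the kernel cross-structure. The posterior-mean prediction
$\hat y = \bar\mu_j + \sum_c \bar u_c$ for such records is therefore an
honest out-of-sample prediction; cross-validation uses exactly this
mechanism. Kernels are built once on all lines: the omics are treated as
predictors and only phenotypes are held out, matching the prediction
contract that no held-out *phenotype* influences training (a tested
invariant: absurdly perturbing held-out trait values leaves their
predictions bitwise unchanged).

## Variance partitioning (PV²)

`pv2()` computes, per stored draw, the sample variance across
observations of each component's realized values (the treatment term uses
the draw's $\mu_j$ mapped to observations); the residual contribution is
the draw's $\sigma_\varepsilon^2$ parameter. Each draw's fractions sum to
1 exactly, and the reported PV² is the posterior mean. Using
realized-value variances rather than the raw variance parameters accounts
for covariance among features within a layer and makes PV² invariant to
kernel diagonal rescaling (a tested invariant). The SNP entry doubles as
the narrow-sense heritability estimate. When two layers' kernels overlap
(e.g. expression partly reflecting genotype), the joint model's shares
are smaller than the single-kernel shares — the expected covariance
effect, reproduced qualitatively in the acceptance suite with a
deliberately collinear pair of kernels.

# Cross-validation and model comparison

`run_cv()` replicates 5-fold CV with lines assigned to folds entirely at
random (fold sizes differ by at most one; identical folds across model
variants within a replicate). Both treatment records of a held-out line
are masked. After a replicate's five folds, every line has one
out-of-fold prediction per treatment and accuracy is the Pearson
correlation between predictions and observations *within* each treatment
— combining treatments mixes the treatment-mean contrast into the
correlation and is deliberately not the default. `tukey_compare()`
Fisher-z-transforms the replicate-level correlations, fits a one-way
layout with model as factor, applies Tukey's studentized-range
correction to all pairs and reports a compact letter display. Treating
CV replicates as independent observations overstates the effective
sample size (the same 75 lines are resampled); the letters are a
descriptive ranking aid, which is stated in the function documentation.

Per-fold chains are shortened to 6,000 iterations / 1,000 burn-in by
default: posterior means of predictions stabilise much faster than
variance quantiles, and replicated CV multiplies chain cost by
(models × folds × replicates). Full-length chains can be requested.

# Mediation scan

For one trait and one omic layer the scan fits, per feature, three
linear mixed models with a random line intercept:

* **path C** — `trait ~ treatment`: the marginal treatment effect
  $\beta_C$;
* **path A** — `feature ~ treatment`: the treatment effect on the
  feature;
* **path B** — `trait ~ treatment + feature`: the feature (mediator)
  effect $\beta_{B,med}$ and the adjusted treatment effect $\beta_{B,trt}$.

P-values are likelihood-ratio tests between nested ML fits
($\chi^2_1$), a choice made for reproducibility: it avoids
denominator-degree-of-freedom conventions that differ between software.
For the balanced paired design the per-feature ML profile has a closed
form after rotating each line's pair of records into its within-line
difference and sum, which makes genome-wide scans and permutation
re-scans cheap; unbalanced designs and features with missing cells fall
back to the generic REML/ML engine (the two routes agree on balanced
data, a tested property). Zero-variance features report $p = 1$;
features aliased with the treatment contrast are flagged and skipped
rather than failing the scan.

Multiplicity is controlled two ways: Benjamini–Hochberg at FDR 0.05, and
a permutation minimum-p threshold — treatment labels are permuted (1,000
times by default), each permutation's smallest p-value is collected, and
the threshold is the empirical 5% quantile of those minima. Permutations
swap labels *within line* by default, respecting the paired design; free
permutation is available. A feature is classified a mediator when its
path-B mediator term is significant and the adjusted treatment effect is
attenuated, $|\beta_{B,trt}| < |\beta_C|$. Path-A significance is not
required by default (the attenuation criterion conditions only on B and
C; path-A overlaps are reported separately by `overlap_summary()`), and a
strict mode adds it. A two-mediator path is intentionally not
implemented and says so.

# Synthetic data generator

The generator emulates the study design the analysis assumes — 75 inbred
lines, paired control/water-scarce records — with recorded truth:

* `simulate_genotypes()`: homozygous 0/2 dosages by thresholding latent
  Gaussians at per-SNP MAF (uniform on 0.05–0.5), with block LD from a
  shared latent factor (default 10-SNP blocks, within-block latent
  correlation 0.8–0.85). Block LD both mimics real marker panels and
  gives the SNP kernel the eigenvalue spread that separates kernel
  effects from the iid line effect. Thresholding attenuates the latent
  correlation, so dosage r-squared within blocks rarely exceeds the 0.9
  pruning threshold; the study-shaped panel therefore also contains
  near-duplicate markers (25% of SNPs copy their neighbour with 0.2%
  per-line discordance, the redundancy reduced-representation panels
  actually show), which is what the LD prune removes on its way to a
  ~7,000-marker panel.
* `simulate_methylation()`: per-site Beta(0.5, 0.5) baselines (bimodal,
  as plant cytosine methylation is), per-cell logit-normal line
  deviations (values stay in [0, 1]), multinomial CG/CHG/CHH contexts.
  Deliberately carries no treatment effect, mirroring the motivating
  study's finding of none detectable.
* `simulate_expression()`: per-sample log-scale expression with a
  genetic component from small random SNP subsets (heritability 0.3 by
  default), a treatment shift on a designated mediator subset, and
  exponentiation to TPM-like values. With `module_sd > 0` the mediator
  genes instead form a tightly co-regulated module (shared latent
  per-sample factor, per-gene noise SD 0.3) whose latent values the
  study-shaped dataset routes into grain yield and nitrogen uptake as a
  mediated 0.10 variance share — single-feature path-B scans only have
  realistic power against such co-regulated modules, and the shared
  module is why those two traits overlap in their mediator sets.
* `simulate_phenotypes()`: draws each model component from its kernel and
  rescales it so the realized sample-variance fraction hits the requested
  share *exactly*. Exact rather than expected scaling makes recovery
  tests sharp at small n. The treatment pair (requested share plus
  treatment effect, e.g. the study-like −0.78 for a yield-scale trait)
  fixes the phenotypic variance.
* `simulate_mediation_chain()`: a treatment-responsive co-expression
  module (latent factor `f = a·T + noise`) tagged by the mediator genes,
  with the trait loading on the module (`y = c·T + b·f + line + noise`).
  The module structure is what gives single-feature path-B scans
  realistic power; with independent mediators the per-feature partial
  correlation is bounded by the number of mediators regardless of effect
  size.

What the generator does *not* emulate: real barley LD maps and population
structure, bisulfite read-level noise, count-based expression error,
trait-specific genetic architectures. Passing tests therefore demonstrate
the statistical machinery under the assumed model, not performance on the
study's own data.

# Numerical choices and problem sizes

* REML/ML fitting profiles the line-to-residual variance ratio on the
  log scale with an exact boundary evaluation at zero; group structure
  reduces every likelihood evaluation to O(n).
* Kernel eigenvalues below `1e-10` are truncated; kernels failing PSD by
  more than `-1e-8` are an error pointing back to `similarity()`.
* LD pruning is a greedy left-to-right scan dropping the later member of
  an offending pair — deterministic and order-stable; `window = 0` means
  all pairs.
* The "high proportion of zero / missing" methylation thresholds default
  to 0.9 and 0.2 and are logged; the TPM exclusion rule is the literal
  AND of median-zero and mean < 1, with OR behind a switch.
* Statistical test sizes in the package's own suite: variance-component
  recovery uses 300 lines with 2,000 SNPs / 3,000 methylation sites /
  2,000 genes and a 30,000-iteration chain; calibration studies use 200
  replicates; CV ordering uses 50 replicates of 5-fold CV with the
  shortened per-fold chains. These sizes were chosen once as the
  smallest designs where the corresponding estimators are comfortably
  identified.

# Known limitations

* A single random line grouping; no treatment × omics interaction
  kernels (the model shifts means only).
* PV² shares of strongly overlapping line-level kernels (e.g.
  methylation vs iid line at small feature counts) are weakly identified
  at n = 75; the posterior then leans on the prior's equal split.
* The Tukey comparison inherits the CV-replicate dependence caveat above.
* Mediation is the regression criterion only: no indirect-effect
  confidence intervals, Sobel tests or sensitivity analyses.
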