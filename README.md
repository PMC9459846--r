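# omicpred

Multi-omics kernel models for complex-trait analysis in structured plant
populations.

`omicpred` is built for the common quantitative-genetics design in which a
panel of inbred lines is phenotyped under a paired two-level treatment
(irrigated control vs water scarcity) and profiled at three whole-genome
layers: SNP genotypes, DNA methylation and gene expression. It answers
three questions about agronomic traits such as grain yield, thousand
kernel weight, protein content and nitrogen uptake:

1. **How much phenotypic variance does each omic layer explain?**
   A Bayesian linear mixed model regresses the trait on treatment means
   plus kernel-structured random effects,

   *y*<sub>ij</sub> = μ<sub>j</sub> + L<sub>i</sub> + u<sub>i</sub> +
   g<sub>ij</sub> + m<sub>ij</sub> + ε<sub>ij</sub>,

   with u ~ MVN(0, K<sub>SNP</sub>σ²<sub>u</sub>),
   g ~ MVN(0, K<sub>GE</sub>σ²<sub>g</sub>),
   m ~ MVN(0, K<sub>M</sub>σ²<sub>m</sub>), similarity kernels
   K = WW′/p from centered-scaled omics matrices, flat priors on treatment
   means and scaled-inverse-χ² priors (5 prior df) on all variances.
   Seven nested variants (`L`, `LG`, `LM`, `LT`, `LGM`, `LGT`, `LGMT`)
   are fitted by a compiled Gibbs sampler, and `pv2()` turns posterior
   samples into per-draw proportions of variance explained (the SNP share
   is the narrow-sense heritability estimate).

2. **Does adding omic layers improve prediction?** `run_cv()` replicates
   5-fold cross-validation (lines randomly assigned to folds, both
   treatment records of held-out lines masked), reports within-treatment
   Pearson accuracy, and `tukey_compare()` ranks model variants with
   Tukey HSD on Fisher-z-transformed correlations.

3. **Do individual features mediate the treatment effect?**
   `mediation_scan()` runs the three-path scan — path C
   (treatment → trait), path A (treatment → feature), path B
   (feature → trait adjusting for treatment) — with per-feature linear
   mixed models, Benjamini–Hochberg FDR and a permutation minimum-p
   threshold, and classifies mediators by significance on path B plus
   attenuation |β<sub>B,trt</sub>| < |β<sub>C</sub>|.

The package also ships the standard upstream steps (SNP
missingness/monomorphism/LD filters, methylation coverage and presence
filters with CG/CHG/CHH context handling, TPM expression filtering) and a
fully deterministic synthetic-data generator
(`simulate_genotypes()`, `simulate_methylation()`,
`simulate_expression()`, `simulate_phenotypes()`,
`make_paper_like_dataset()`) that reproduces the study geometry — 75
lines × 2 treatments — with recorded ground truth, so the whole pipeline
is testable end to end.

## Worked example

```r
library(omicpred)

# 75 lines, paired control / water-scarce records, SNP panel in LD blocks
geno <- simulate_genotypes(n_lines = 75, n_snps = 600, ld_block = 10,
                           r_within = 0.85, seed = 11)
sim  <- simulate_phenotypes(list(snp = geno),
                            fractions = c(treatment = 0.05, line = 0.05,
                                          snp = 0.75, residual = 0.15),
                            treatment_effect = -0.78, seed = 12)

# marker QC and the additive relationship kernel
snps <- filter_snps(geno, max_missing = 0.20, ld_r2 = 0.9, window = 50)
print(snps$report)
K <- similarity(snps$matrix)
print(K)

# treatment effect (mediation path C)
pc <- path_C(sim$pheno, "trait")
cat(sprintf("path C: beta = %.3f (p = %.2g)\n", pc$beta_treatmentC, pc$p_C))

# multi-kernel Bayesian fit and variance partitioning
fit <- fit_bayesian(sim$pheno, "trait", list(snp = K),
                    model_spec(c("LINE", "SNP"), n_iter = 10000,
                               burn_in = 2000, seed = 13))
print(pv2(fit))

# replicated cross-validated accuracy, baseline vs genomic model
cv <- run_cv(sim$pheno, "trait", list(snp = K), models = c("L", "LG"),
             k = 5, reps = 20, seed = 14)
print(cv)
print(tukey_compare(cv, "control"))
```

This prints (numbers from this exact script):

```
<filter_report> snp: 600 -> 598 features
  missingness  -0
  monomorphic  -1
  ld           -1
<similarity_matrix> 75 x 75 from snp (598 features); mean diag 0.9867
path C: beta = -0.756 (p = 2.2e-09)
<pv2_table> trait 'trait', model {LINE,SNP}
       term   pv2_mean     pv2_sd  var_mean
1 TREATMENT 0.04839741 0.01546516 0.1468419
2      LINE 0.36216913 0.11361323 1.1050888
3       SNP 0.39448095 0.11621958 1.2106785
4     RESID 0.19495252 0.03503443 0.5903720
<cv_result> trait 'trait': 5-fold CV x 20 replicates
  model    treatment mean_accuracy
1     L      control    -0.1848090
2    LG      control     0.2312539
3     L water_scarce    -0.1673623
4    LG water_scarce     0.1870181
<tukey_groups> control (alpha = 0.05)
 model     mean_z mean_accuracy group
    LG  0.2372730     0.2329183     a
     L -0.1886403    -0.1864341     b
```

Reading it: the simulated trait carried 5% treatment, 5% iid line, 75%
genomic and 15% residual variance. The posterior PV2 recovers the
treatment share on the nose and splits the line-level genetic signal
between the `LINE` and `SNP` terms — with 75 unrelated lines the two are
only weakly separable (see the methods vignette) — the SNP share of 0.39
being the narrow-sense heritability estimate. Cross-validated accuracy of
the genomic model (`LG`, r of about 0.23 within control) clearly beats the
treatment+line baseline (`L`, r below zero: a mean-only model suffers the
usual negative fold-mean artifact of pooled CV correlations), and Tukey
HSD on the Fisher-z accuracies assigns the two models different letters.

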