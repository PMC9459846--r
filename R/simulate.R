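# Synthetic multi-omics generator. Emulates the study design the analysis
# modules assume -- inbred lines under a paired control / water-scarce
# contrast with SNP, methylation and expression layers -- with recorded
# ground truth, so every stage of the pipeline is testable without external
# data. All generators are pure functions of their arguments and seed.

.line_ids <- function(n) sprintf("L%03d", seq_len(n))

# observation grid used throughout: all lines under control, then all lines
# under water-scarce
.obs_grid <- function(line_ids) {
  data.frame(line_id = rep(line_ids, 2),
             treatment = rep(c("control", "water_scarce"), each = length(line_ids)),
             stringsAsFactors = FALSE)
}

#' Simulate inbred-line SNP genotypes with block LD
#'
#' Draws fully homozygous dosages (0/2) by thresholding a latent Gaussian
#' at each SNP's minor allele frequency. SNPs within a block of `ld_block`
#' consecutive markers share a latent factor with loading
#' `sqrt(r_within)`, giving pairwise latent correlation `r_within`
#' (block-diagonal LD); blocks are independent.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_snps number of SNPs.
#' @param maf_range range the per-SNP minor allele frequency is drawn from
#'   uniformly (default 0.05-0.5).
#' @param ld_block SNPs per LD block (1 = independent markers).
#' @param r_within latent within-block correlation (default 0.8).
#' @param missing_rate fraction of calls set missing at random.
#' @param near_dup_frac fraction of SNPs that are near-copies of their left
#'   neighbour within a block (per-line discordance 0.2%), emulating the
#'   redundant markers of reduced-representation panels that LD pruning is
#'   meant to remove.
#' @param seed RNG seed.
#' @return an [omics_matrix()] of kind `snp`.
#' @export
simulate_genotypes <- function(n_lines, n_snps, maf_range = c(0.05, 0.5),
                               ld_block = 10, r_within = 0.8,
                               missing_rate = 0, near_dup_frac = 0, seed = 1) {
  if (n_lines < 2) stop("need at least 2 lines")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] and increasing")
  }
  set.seed(seed)
  blocks <- rep(seq_len(ceiling(n_snps / ld_block)), each = ld_block)[1:n_snps]
  f <- matrix(stats::rnorm(n_lines * max(blocks)), n_lines)
  z <- sqrt(r_within) * f[, blocks, drop = FALSE] +
    sqrt(1 - r_within) * matrix(stats::rnorm(n_lines * n_snps), n_lines)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  G <- ifelse(sweep(z, 2, stats::qnorm(maf), "<"), 2, 0)
  if (near_dup_frac > 0) {
    dup <- which(stats::runif(n_snps) < near_dup_frac & blocks == c(blocks[1], blocks[-n_snps]))
    dup <- dup[dup > 1]
    for (j in dup) {
      col <- G[, j - 1]
      flip <- stats::runif(n_lines) < 0.002
      col[flip] <- 2 - col[flip]
      G[, j] <- col
    }
  }
  if (missing_rate > 0) {
    G[matrix(stats::runif(length(G)) < missing_rate, nrow(G))] <- NA
  }
  rownames(G) <- .line_ids(n_lines)
  colnames(G) <- sprintf("snp%05d", seq_len(n_snps))
  omics_matrix(G, "snp")
}

#' Simulate per-line methylation levels
#'
#' Each site gets a Beta-distributed baseline level (bimodal, as plant
#' cytosine methylation typically is) and each (line, site) cell deviates
#' from it on the logit scale with standard deviation `line_effect_sd`, so
#' values stay in \[0, 1\] and `line_effect_sd = 0` makes all lines
#' identical. Contexts are assigned multinomially.
#'
#' @param n_lines,n_sites dimensions.
#' @param context_props named proportions for `CG`, `CHG`, `CHH`.
#' @param line_effect_sd logit-scale between-line SD (default 0.5).
#' @param seed RNG seed.
#' @return an [omics_matrix()] of kind `methylation` with site coordinates
#'   and contexts in `feature_meta`.
#' @export
simulate_methylation <- function(n_lines, n_sites,
                                 context_props = c(CG = 0.4, CHG = 0.3, CHH = 0.3),
                                 line_effect_sd = 0.5, seed = 1) {
  set.seed(seed)
  base <- stats::rbeta(n_sites, 0.5, 0.5)
  base <- pmin(pmax(base, 1e-3), 1 - 1e-3)
  logit <- stats::qlogis(base)
  L <- matrix(stats::rnorm(n_lines * n_sites, sd = line_effect_sd), n_lines)
  M <- stats::plogis(sweep(L, 2, logit, "+"))
  rownames(M) <- .line_ids(n_lines)
  colnames(M) <- sprintf("meth%06d", seq_len(n_sites))
  ctx <- sample(names(context_props), n_sites, replace = TRUE,
                prob = context_props)
  meta <- data.frame(feature_id = colnames(M), chrom = "chr1H",
                     start = 100L * seq_len(n_sites),
                     end = 100L * seq_len(n_sites) + 1L,
                     context = ctx, stringsAsFactors = FALSE)
  omics_matrix(M, "methylation", feature_meta = meta)
}

#' Simulate TPM-like expression with treatment-responsive mediator genes
#'
#' Generates one expression profile per (line, treatment) sample on the
#' log scale: a genetic component (a linear effect of a small random SNP
#' subset per gene, scaled to heritability `trans_h2`), a treatment effect
#' `a` added to the first `n_mediators` genes under water scarcity, and
#' Gaussian noise; values are exponentiated around a per-gene baseline to
#' TPM-like positive levels.
#'
#' @param n_lines number of lines (must match `genotypes`).
#' @param n_genes number of genes.
#' @param genotypes an [omics_matrix()] of kind `snp` for the cis/trans
#'   genetic component.
#' @param n_mediators number of treatment-responsive genes (the first
#'   `n_mediators` columns).
#' @param a log-scale treatment effect on mediator genes.
#' @param trans_h2 fraction of log-expression variance that is genetic.
#' @param module_sd when positive, the mediator genes form a tightly
#'   co-regulated module: they share a latent per-sample factor with this
#'   SD and deviate from it with SD `mediator_noise_sd` (replacing their
#'   genetic + iid construction). The latent factor is returned as
#'   attribute `module` so trait simulation can route a mediated effect
#'   through it.
#' @param mediator_noise_sd per-gene noise around the module.
#' @param seed RNG seed.
#' @return an [omics_matrix()] of kind `expression` with rows
#'   `"<line>:<treatment>"`; attribute `mediators` lists the responsive
#'   gene ids, attribute `module` the latent module values (if any).
#' @export
simulate_expression <- function(n_lines, n_genes, genotypes, n_mediators = 0,
                                a = 0, trans_h2 = 0.3, module_sd = 0,
                                mediator_noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(genotypes, "omics_matrix"), nrow(genotypes) == n_lines)
  set.seed(seed)
  G <- unclass(genotypes)
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- mu[idx[, 2]]
  G <- scale(G)
  G[, !is.finite(colSums(G))] <- 0
  grid <- .obs_grid(rownames(genotypes))
  n_obs <- nrow(grid)
  gen_line <- matrix(0, n_lines, n_genes)
  if (trans_h2 > 0 && ncol(G) > 0) {
    n_qtl <- min(5L, ncol(G))
    for (g in seq_len(n_genes)) {
      snps <- sample.int(ncol(G), n_qtl)
      v <- G[, snps, drop = FALSE] %*% stats::rnorm(n_qtl)
      s <- stats::sd(v)
      if (s > 0) gen_line[, g] <- v / s * sqrt(trans_h2)
    }
  }
  E <- gen_line[match(grid$line_id, rownames(genotypes)), , drop = FALSE] +
    matrix(stats::rnorm(n_obs * n_genes, sd = sqrt(1 - trans_h2)), n_obs)
  module <- NULL
  n_med <- min(n_mediators, n_genes)
  if (n_med > 0) {
    scarce <- grid$treatment == "water_scarce"
    if (module_sd > 0) {
      module <- stats::rnorm(n_obs, sd = module_sd)
      E[, seq_len(n_med)] <- a * scarce + module +
        matrix(stats::rnorm(n_obs * n_med, sd = mediator_noise_sd), n_obs)
    } else if (a != 0) {
      E[scarce, seq_len(n_med)] <- E[scarce, seq_len(n_med)] + a
    }
  }
  baseline <- stats::rnorm(n_genes, mean = 1.5, sd = 1)
  TPM <- exp(sweep(E, 2, baseline, "+"))
  rownames(TPM) <- paste(grid$line_id, grid$treatment, sep = ":")
  colnames(TPM) <- sprintf("gene%05d", seq_len(n_genes))
  out <- omics_matrix(TPM, "expression")
  attr(out, "mediators") <- if (n_med > 0) colnames(TPM)[seq_len(n_med)] else character(0)
  attr(out, "module") <- module
  out
}

#' Simulate a trait from the multi-kernel model with exact variance shares
#'
#' Builds a trait on the paired two-treatment grid as the sum of a
#' treatment contrast, an iid line effect, kernel-structured effects drawn
#' as MVN(0, K) from each supplied omic layer, and residual noise. Every
#' random component is centered and rescaled so its realized sample
#' variance across observations hits the requested fraction of the
#' phenotypic variance exactly, which makes recovery tests sharp at small
#' n. The phenotypic variance itself is set by the treatment pair
#' (`fractions["treatment"]` and `treatment_effect` jointly determine it);
#' when the treatment fraction is 0 the trait is scaled to `trait_var`.
#'
#' @param omics named list with any of `snp`, `meth` (line-level rows) and
#'   `expr` (sample-level rows), as [omics_matrix()] objects; kernels are
#'   built internally with [similarity()].
#' @param fractions named variance fractions over
#'   `c("treatment", "line", "snp", "meth", "expr", "mediation",
#'   "residual")` (only the layers present in `omics` may be positive; a
#'   `mediation` share requires `mediation_values`); must sum to 1.
#' @param treatment_effect water-scarce minus control difference on the
#'   trait scale.
#' @param mediation_values optional per-observation latent module values
#'   (e.g. the `module` attribute of [simulate_expression()]); scaled to
#'   the `mediation` fraction and oriented along the sign of
#'   `treatment_effect`, so genes tagging the module mediate part of the
#'   treatment-trait association.
#' @param trait_name name of the trait column (default `"trait"`).
#' @param trait_var phenotypic variance when `fractions["treatment"] == 0`.
#' @param intercept grand mean added to the trait.
#' @param seed RNG seed.
#' @return list: `pheno` (a [phenotype_table()]), `truth` (class
#'   `synthetic_truth`: fractions, treatment effect, phenotypic variance,
#'   per-component realized values, kernels, seed).
#' @export
simulate_phenotypes <- function(omics, fractions, treatment_effect = 0,
                                trait_name = "trait", trait_var = 1,
                                intercept = 0, mediation_values = NULL,
                                seed = 1) {
  comp_names <- c("treatment", "line", "snp", "meth", "expr", "mediation",
                  "residual")
  fr <- stats::setNames(rep(0, length(comp_names)), comp_names)
  fr[names(fractions)] <- fractions
  if (abs(sum(fr) - 1) > 1e-8) stop("variance fractions must sum to 1")
  for (nm in c("snp", "meth", "expr")) {
    if (fr[nm] > 0 && is.null(omics[[nm]])) {
      stop("fraction for '", nm, "' is positive but omics$", nm, " is missing")
    }
  }
  line_ids <- rownames(if (!is.null(omics$snp)) omics$snp else
    if (!is.null(omics$meth)) omics$meth else omics$expr)
  if (!is.null(omics$expr) && is.null(omics$snp) && is.null(omics$meth)) {
    line_ids <- unique(sub(":(control|water_scarce)$", "", line_ids))
  }
  grid <- .obs_grid(line_ids)
  n_obs <- nrow(grid)
  scarce <- grid$treatment == "water_scarce"

  set.seed(seed)
  trt_term <- ifelse(scarce, treatment_effect / 2, -treatment_effect / 2)
  v_trt <- stats::var(trt_term)
  sigmaP2 <- if (fr["treatment"] > 0) {
    if (treatment_effect == 0) stop("treatment fraction > 0 needs a nonzero treatment_effect")
    v_trt / fr["treatment"]
  } else {
    if (v_trt > 0) stop("treatment_effect nonzero but treatment fraction is 0")
    trait_var
  }

  scale_to <- function(v, target) {
    v <- v - mean(v)
    s2 <- stats::var(v)
    if (target == 0) return(rep(0, length(v)))
    if (s2 == 0) stop("degenerate component draw; change the seed")
    v * sqrt(target / s2)
  }

  kernels <- list()
  comps <- list(treatment = trt_term)
  comps$line <- scale_to(stats::rnorm(length(line_ids))[match(grid$line_id, line_ids)],
                         fr["line"] * sigmaP2)
  for (nm in c("snp", "meth", "expr")) {
    if (is.null(omics[[nm]])) next
    K <- similarity(omics[[nm]])
    kernels[[c(snp = "snp", meth = "meth", expr = "expr")[nm]]] <- K
    ev <- eigen(unclass(K), symmetric = TRUE)
    keep <- ev$values > 1e-10
    u <- ev$vectors[, keep, drop = FALSE] %*%
      (sqrt(ev$values[keep]) * stats::rnorm(sum(keep)))
    rows <- rownames(K)
    map <- if (all(paste(grid$line_id, grid$treatment, sep = ":") %in% rows)) {
      match(paste(grid$line_id, grid$treatment, sep = ":"), rows)
    } else {
      match(grid$line_id, rows)
    }
    comps[[nm]] <- scale_to(u[map], fr[nm] * sigmaP2)
  }
  if (fr["mediation"] > 0) {
    if (is.null(mediation_values) || length(mediation_values) != n_obs) {
      stop("a 'mediation' fraction needs per-observation mediation_values")
    }
    orient <- if (treatment_effect < 0) -1 else 1
    comps$mediation <- orient *
      scale_to(as.numeric(mediation_values), fr["mediation"] * sigmaP2)
  }
  comps$residual <- scale_to(stats::rnorm(n_obs), fr["residual"] * sigmaP2)

  y <- intercept + Reduce(`+`, comps)
  pheno <- grid
  pheno[[trait_name]] <- y
  pheno <- phenotype_table(pheno)
  truth <- structure(list(fractions = fr, treatment_effect = treatment_effect,
                          sigmaP2 = unname(sigmaP2), components = comps,
                          kernels = kernels, trait_name = trait_name,
                          seed = seed),
                     class = "synthetic_truth")
  list(pheno = pheno, truth = truth)
}

#' Simulate a treatment -> expression -> trait mediation chain
#'
#' Builds the causal-chain benchmark for the mediation scan: a latent
#' treatment-responsive expression module `f = a * T + noise` (one value
#' per sample), `n_mediators` genes that tag the module with noise SD
#' `tau`, null genes with line structure but no trait link, and a trait
#' `y = c * T + b * f + line + noise`. The true mediators are the module
#' genes; the marginal treatment effect (path C) is `c + a * b` and the
#' adjusted effect after conditioning on a module gene is attenuated
#' towards `c`.
#'
#' @param n_lines lines (paired design; default 75).
#' @param n_genes total genes (default 2000).
#' @param n_mediators module genes (default 20).
#' @param a treatment effect on the module (default 1.5).
#' @param b module effect on the trait (default 0.8).
#' @param direct_c direct treatment effect on the trait (default 0.5).
#' @param tau per-gene noise SD around the module (default 0.3).
#' @param line_sd,resid_sd trait line-effect and residual SDs.
#' @param seed RNG seed.
#' @return list: `pheno`, `expr` (sample-level [omics_matrix()]),
#'   `mediators` (gene ids), `beta_C_true`.
#' @export
simulate_mediation_chain <- function(n_lines = 75, n_genes = 2000,
                                     n_mediators = 20, a = 1.5, b = 0.8,
                                     direct_c = 0.5, tau = 0.3,
                                     line_sd = 0.5, resid_sd = 0.5, seed = 1) {
  set.seed(seed)
  line_ids <- .line_ids(n_lines)
  grid <- .obs_grid(line_ids)
  n_obs <- nrow(grid)
  t01 <- as.numeric(grid$treatment == "water_scarce")
  f <- a * t01 + stats::rnorm(n_obs)
  E <- matrix(stats::rnorm(n_obs * n_genes), n_obs)
  med_idx <- seq_len(n_mediators)
  E[, med_idx] <- f + matrix(stats::rnorm(n_obs * n_mediators, sd = tau), n_obs)
  # null genes carry line structure only
  null_idx <- setdiff(seq_len(n_genes), med_idx)
  line_eff <- matrix(stats::rnorm(n_lines * length(null_idx), sd = 0.5), n_lines)
  E[, null_idx] <- E[, null_idx] + line_eff[match(grid$line_id, line_ids), ]
  rownames(E) <- paste(grid$line_id, grid$treatment, sep = ":")
  colnames(E) <- sprintf("gene%05d", seq_len(n_genes))
  L <- stats::rnorm(n_lines, sd = line_sd)
  y <- direct_c * t01 + b * f + L[match(grid$line_id, line_ids)] +
    stats::rnorm(n_obs, sd = resid_sd)
  pheno <- grid
  pheno$trait <- y
  list(pheno = phenotype_table(pheno),
       expr = omics_matrix(exp(E), "expression"),
       mediators = colnames(E)[med_idx],
       beta_C_true = direct_c + a * b)
}

#' Generate a full study-sized synthetic dataset
#'
#' Bundles the generators into one dataset shaped like the motivating
#' study: 75 lines under control and water-scarce treatment, ~9000 raw
#' SNPs in LD blocks with near-duplicate markers (so roughly 7000 survive
#' [filter_snps()]), 30,000 methylation sites in three contexts with no
#' treatment signal, 20,000 genes including a tightly co-regulated
#' treatment-responsive module, and four traits (grain yield, TKW,
#' nitrogen uptake, protein) built from the multi-kernel model. The
#' treatment effects (-0.78, -2.99, -9.87, 0.17) mimic the magnitudes the
#' motivating study reports, and grain yield and nitrogen uptake receive a
#' mediated component routed through the expression module (so those two
#' traits share true mediator genes); the variance fractions, LD
#' structure, methylation baselines and module parameters are invented
#' defaults of the generator.
#'
#' @param seed RNG seed.
#' @param n_lines,n_snps,n_meth_sites,n_genes sizes (study-like defaults).
#' @param fractions base variance fractions shared by the four traits; for
#'   the two mediated traits `mediation_fraction` is carved out of the
#'   residual share.
#' @param mediation_fraction variance share routed through the expression
#'   module for grain yield and nitrogen uptake.
#' @return list: `pheno` (four traits), `geno`, `meth`, `expr`, `truths`
#'   (per-trait `synthetic_truth`), `mediators` (true mediator gene ids).
#' @export
make_paper_like_dataset <- function(seed = 1, n_lines = 75, n_snps = 9000,
                                    n_meth_sites = 30000, n_genes = 20000,
                                    fractions = c(treatment = 0.05, line = 0.15,
                                                  snp = 0.30, meth = 0.10,
                                                  expr = 0.20, residual = 0.20),
                                    mediation_fraction = 0.10) {
  geno <- simulate_genotypes(n_lines, n_snps, ld_block = 10, r_within = 0.85,
                             missing_rate = 0.02, near_dup_frac = 0.25,
                             seed = seed)
  meth <- simulate_methylation(n_lines, n_meth_sites, seed = seed + 1)
  expr <- simulate_expression(n_lines, n_genes, geno,
                              n_mediators = max(1L, round(n_genes / 100)),
                              a = 1, trans_h2 = 0.3, module_sd = 1,
                              seed = seed + 2)
  traits <- list(grain_yield = -0.78, tkw = -2.99, nitrogen_uptake = -9.87,
                 protein = 0.17)
  mediated <- c("grain_yield", "nitrogen_uptake")
  omics <- list(snp = geno, meth = meth, expr = expr)
  pheno <- NULL
  truths <- list()
  for (i in seq_along(traits)) {
    tr <- names(traits)[i]
    fr <- fractions
    med_vals <- NULL
    if (tr %in% mediated && mediation_fraction > 0) {
      fr["residual"] <- fr["residual"] - mediation_fraction
      fr["mediation"] <- mediation_fraction
      med_vals <- attr(expr, "module")
    }
    sim <- simulate_phenotypes(omics, fr, treatment_effect = traits[[i]],
                               trait_name = tr, mediation_values = med_vals,
                               seed = seed + 10 + i)
    truths[[tr]] <- sim$truth
    if (is.null(pheno)) {
      pheno <- sim$pheno
    } else {
      pheno[[tr]] <- sim$pheno[[tr]]
    }
  }
  list(pheno = phenotype_table(pheno), geno = geno, meth = meth, expr = expr,
       truths = truths, mediators = attr(expr, "mediators"))
}
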