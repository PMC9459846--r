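#' Specify a multi-kernel Bayesian model
#'
#' Defines which variance components enter the model
#' `y_ij = mu_j + L_i + u_i + g_ij + m_ij + e_ij`: an iid line effect
#' (`LINE`) and kernel-structured effects for SNPs (`SNP`), gene expression
#' (`EXPR`) and DNA methylation (`METH`). Treatment means (flat priors) and
#' the residual are always present. Every variance parameter carries a
#' scaled-inverse-chi-square prior with `df0` prior degrees of freedom
#' (default 5) and, with `scale0 = "auto"`, a scale chosen so the prior
#' mode of each non-residual component equals an equal share of half the
#' phenotypic variance (divided by the kernel's mean diagonal) and the
#' residual prior mode equals the other half — the convention of standard
#' Bayesian genomic-prediction software.
#'
#' @param components character subset of `c("LINE", "SNP", "EXPR", "METH")`.
#' @param n_iter,burn_in,thin MCMC chain length, burn-in and thinning
#'   (defaults 30000 / 5000 / 5).
#' @param seed RNG seed; chains are bitwise reproducible given the seed.
#' @param df0 prior degrees of freedom for all variances (default 5).
#' @param scale0 `"auto"` or a named numeric vector of prior scales per
#'   component (including `RESID`).
#' @param R2 total variance fraction the non-residual prior modes share
#'   under `"auto"` (default 0.5).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(components = c("LINE", "SNP", "EXPR", "METH"),
                       n_iter = 30000, burn_in = 5000, thin = 5, seed = 1,
                       df0 = 5, scale0 = "auto", R2 = 0.5) {
  components <- match.arg(components, c("LINE", "SNP", "EXPR", "METH"),
                          several.ok = TRUE)
  stopifnot(burn_in < n_iter, thin >= 1, df0 > 0)
  structure(list(components = components, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = seed, df0 = df0, scale0 = scale0,
                 R2 = R2),
            class = "model_spec")
}

#' The seven standard model variants
#'
#' Returns named [model_spec()]s for the nested sequence from the baseline
#' treatment + line model (`L`) through the full multi-omics model
#' (`LGMT`): letters G, M, T add the SNP, methylation and transcriptome
#' kernels respectively.
#'
#' @param which character vector of variant names to return; default all
#'   seven.
#' @param ... passed on to [model_spec()] (chain settings, seed, priors).
#' @return named list of `model_spec` objects.
#' @export
model_variants <- function(which = c("L", "LG", "LM", "LT", "LGM", "LGT", "LGMT"),
                           ...) {
  defs <- list(L = "LINE",
               LG = c("LINE", "SNP"),
               LM = c("LINE", "METH"),
               LT = c("LINE", "EXPR"),
               LGM = c("LINE", "SNP", "METH"),
               LGT = c("LINE", "SNP", "EXPR"),
               LGMT = c("LINE", "SNP", "METH", "EXPR"))
  which <- match.arg(which, names(defs), several.ok = TRUE)
  out <- lapply(defs[which], function(comp) model_spec(components = comp, ...))
  out
}

# Map pheno rows to kernel rows: sample ids "line:treatment" first, bare
# line ids second. Errors list the unmatched records.
.kernel_row_map <- function(K, pheno) {
  ids <- rownames(K)
  sample_ids <- paste(pheno$line_id, pheno$treatment, sep = ":")
  if (all(sample_ids %in% ids)) return(match(sample_ids, ids))
  if (all(pheno$line_id %in% ids)) return(match(pheno$line_id, ids))
  miss <- setdiff(sample_ids, ids)
  if (length(setdiff(pheno$line_id, ids)) < length(miss)) {
    miss <- setdiff(pheno$line_id, ids)
  }
  stop("kernel rows do not cover phenotype records; unmatched: ",
       paste(utils::head(miss, 5), collapse = ", "))
}

# crude effective sample size from the autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' Fit the multi-kernel Bayesian mixed model by Gibbs sampling
#'
#' Fits one trait under a [model_spec()]. Kernel effects are sampled in the
#' eigenbasis of each similarity matrix (eigenvalues below 1e-10 are
#' truncated); treatment means have flat priors and are sampled from their
#' Gaussian full conditionals; all variances have scaled-inverse-chi-square
#' priors. Records with a missing trait value are excluded from the
#' likelihood but still receive predictions — their kernel effects are
#' drawn from the conditional given the training lines through the kernel
#' cross-structure, which is how cross-validation predictions are produced
#' without using any held-out phenotype.
#'
#' @param pheno a [phenotype_table()]; rows with missing `trait` are the
#'   prediction-only set.
#' @param trait trait column name (needs >= 10 non-missing observations).
#' @param kernels named list of [similarity()] matrices: `snp`, `expr`,
#'   `meth` as required by `spec$components`. Kernel rows are matched to
#'   records by `"line:treatment"` sample id or bare line id; a record
#'   absent from a kernel is a hard error.
#' @param spec a [model_spec()].
#' @param store_effects keep per-draw realized component values (needed by
#'   [pv2()]'s per-draw decomposition; default `TRUE`).
#' @param eigen_cache optional precomputed eigendecompositions (internal,
#'   used by [run_cv()] to share work across folds).
#' @param check_ess warn when a variance chain's effective sample size
#'   falls below 200 (disabled for the short per-fold CV chains).
#' @return object of class `posterior_samples`.
#' @export
fit_bayesian <- function(pheno, trait, kernels = list(), spec = model_spec(),
                         store_effects = TRUE, eigen_cache = NULL,
                         check_ess = TRUE) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(spec, "model_spec"))
  y_all <- pheno[[trait]]
  train <- !is.na(y_all)
  if (sum(train) < 10) stop("trait needs at least 10 non-missing observations")
  if (stats::var(y_all[train]) == 0) stop("trait has zero phenotypic variance")
  y <- y_all[train]
  vy <- stats::var(y)

  lv <- c("control", "water_scarce")
  X_all <- cbind(control = as.numeric(pheno$treatment == "control"),
                 water_scarce = as.numeric(pheno$treatment == "water_scarce"))
  comp_names <- spec$components
  kern_key <- c(SNP = "snp", EXPR = "expr", METH = "meth")

  B_list <- list(); d_list <- list(); Bp_list <- list(); mdiag <- numeric(0)
  for (comp in comp_names) {
    if (comp == "LINE") {
      lines <- unique(pheno$line_id)
      M <- outer(pheno$line_id, lines, "==") * 1
      B_list[[comp]] <- M[train, , drop = FALSE]
      Bp_list[[comp]] <- M
      d_list[[comp]] <- rep(1, length(lines))
      mdiag[comp] <- 1
    } else {
      key <- kern_key[[comp]]
      K <- kernels[[key]]
      if (is.null(K)) stop("spec includes ", comp, " but kernels$", key,
                           " is missing")
      ev <- if (!is.null(eigen_cache[[key]])) eigen_cache[[key]] else
        eigen(unclass(K), symmetric = TRUE)
      if (min(ev$values) < -1e-8) {
        stop("kernel '", key, "' is not PSD (min eigenvalue ",
             format(min(ev$values)), "); rebuild it with similarity()")
      }
      keep <- ev$values > 1e-10
      map <- .kernel_row_map(K, pheno)
      V <- ev$vectors[, keep, drop = FALSE]
      B_all <- V[map, , drop = FALSE]
      B_list[[comp]] <- B_all[train, , drop = FALSE]
      Bp_list[[comp]] <- B_all
      d_list[[comp]] <- ev$values[keep]
      mdiag[comp] <- mean(diag(unclass(K)))
    }
  }

  # prior scales: mode of scaled-inv-chi2(df, S) is df*S/(df + 2)
  df0 <- spec$df0
  if (identical(spec$scale0, "auto")) {
    mode_k <- spec$R2 / length(comp_names) * vy / mdiag
    S0 <- mode_k * (df0 + 2) / df0
    S0_e <- (1 - spec$R2) * vy * (df0 + 2) / df0
  } else {
    S0 <- spec$scale0[comp_names]
    S0_e <- spec$scale0[["RESID"]]
    if (anyNA(S0) || is.null(S0_e)) stop("scale0 must name every component and RESID")
  }

  set.seed(spec$seed)
  res <- .gibbs_multikernel(y, X_all[train, , drop = FALSE], B_list, d_list,
                            Bp_list, X_all, rep(df0, length(comp_names)),
                            as.numeric(S0), df0, S0_e,
                            spec$n_iter, spec$burn_in, spec$thin,
                            store_effects)

  colnames(res$mu) <- lv
  colnames(res$sigma2) <- c(comp_names, "RESID")
  colnames(res$comp_var) <- c("TREATMENT", comp_names)
  colnames(res$comp_pred) <- c("TREATMENT", comp_names)
  obs_ids <- paste(pheno$line_id, pheno$treatment, sep = ":")
  yhat <- stats::setNames(drop(res$yhat), obs_ids)
  effects <- NULL
  if (store_effects) {
    effects <- stats::setNames(res$effects, comp_names)
  }
  ess <- apply(res$sigma2, 2, .ess)
  if (check_ess && any(ess < 200)) {
    warning("low effective sample size for variance(s): ",
            paste(sprintf("%s (%.0f)", colnames(res$sigma2)[ess < 200],
                          ess[ess < 200]), collapse = ", "))
  }
  structure(list(trait = trait, spec = spec,
                 mu = res$mu, sigma2 = res$sigma2, comp_var = res$comp_var,
                 loglik = drop(res$loglik), yhat = yhat,
                 comp_pred = res$comp_pred, effects = effects,
                 obs_ids = obs_ids, train = train,
                 line_id = pheno$line_id, treatment = pheno$treatment,
                 ess = ess),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> trait '%s', model {%s}, %d stored draws\n",
              x$trait, paste(x$spec$components, collapse = ","), nrow(x$sigma2)))
  cat("  posterior mean variances:\n")
  pm <- colMeans(x$sigma2)
  for (nm in names(pm)) cat(sprintf("    %-10s %.4f\n", nm, pm[nm]))
  invisible(x)
}

#' Posterior-mean predictions from a fitted model
#'
#' Returns `E[mu_j + sum_k u_k]` for the requested (line, treatment)
#' records. Predictions are available for every record passed to
#' [fit_bayesian()] (phenotyped or not); a record that was not in the fit
#' — hence absent from the kernels used — is a hard error.
#'
#' @param object a `posterior_samples` object.
#' @param newdata optional data.frame with `line_id` and `treatment`;
#'   defaults to every record of the fit.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.posterior_samples <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$yhat)
  ids <- paste(newdata$line_id, newdata$treatment, sep = ":")
  miss <- setdiff(ids, names(object$yhat))
  if (length(miss)) {
    stop("no kernel information for record(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  object$yhat[ids]
}
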