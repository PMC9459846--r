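#' Assign lines to cross-validation folds
#'
#' Balanced random partition: fold sizes differ by at most one, and the
#' assignment is a pure function of the seed.
#'
#' @param line_ids character vector of line identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return named integer vector mapping each line to its fold.
#' @export
assign_folds <- function(line_ids, k = 5, seed = 1) {
  n <- length(line_ids)
  if (k > n) stop("k must not exceed the number of lines")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  stats::setNames(fold, line_ids)
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`; correlations within 1e-12 of +-1 are clipped first.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-12
  atanh(pmin(pmax(r, -lim), lim))
}

#' Replicated k-fold cross-validated prediction accuracy
#'
#' For each replicate, lines are randomly partitioned into `k` folds (the
#' same folds for every model variant); each model is trained with both
#' treatment records of the held-out lines removed from the likelihood and
#' the held-out records predicted through the kernels. After all folds,
#' every line has one out-of-fold prediction per treatment, and the
#' replicate's accuracy is the Pearson correlation between predictions and
#' observations computed within each treatment. Per-fold chains default to
#' short runs (`n_iter = 6000`, `burn_in = 1000`) to keep replicated CV
#' tractable; pass longer settings through `...` if desired.
#'
#' @param pheno a [phenotype_table()].
#' @param trait trait column name.
#' @param kernels named list of similarity matrices (see [fit_bayesian()]).
#' @param models character vector of variant names (see [model_variants()]).
#' @param k folds (default 5).
#' @param reps number of CV replicates (default 200).
#' @param seed base seed; fold assignments and chains derive from it.
#' @param return_predictions also keep each replicate's pooled out-of-fold
#'   prediction vectors (one per model), for leakage diagnostics.
#' @param ... chain settings forwarded to [model_spec()] (`n_iter`,
#'   `burn_in`, `thin`, `df0`, ...).
#' @return object of class `cv_result`: `replicates` data.frame with one
#'   row per (model, treatment, replicate) Pearson r, and `summary` with
#'   mean accuracies.
#' @export
run_cv <- function(pheno, trait, kernels, models = c("L", "LG"), k = 5,
                   reps = 200, seed = 1, return_predictions = FALSE, ...) {
  stopifnot(inherits(pheno, "phenotype_table"))
  dots <- list(...)
  if (is.null(dots$n_iter)) dots$n_iter <- 6000
  if (is.null(dots$burn_in)) dots$burn_in <- 1000
  if (is.null(dots$thin)) dots$thin <- 5
  lines <- unique(pheno$line_id)
  y_all <- pheno[[trait]]

  # eigendecompositions shared across folds, replicates and models
  cache <- lapply(kernels, function(K) eigen(unclass(K), symmetric = TRUE))

  rows <- list()
  preds <- if (return_predictions) list() else NULL
  for (rep_i in seq_len(reps)) {
    fold <- assign_folds(lines, k, seed = seed + 7919L * rep_i)
    pred <- lapply(models, function(m) rep(NA_real_, nrow(pheno)))
    names(pred) <- models
    for (f in seq_len(k)) {
      test_lines <- names(fold)[fold == f]
      ph <- pheno
      ph[[trait]][ph$line_id %in% test_lines] <- NA
      for (mi in seq_along(models)) {
        m <- models[mi]
        spec <- do.call(model_spec, c(
          list(components = model_variants(m)[[1]]$components,
               seed = (seed + 7919L * rep_i + 131L * f + mi) %% .Machine$integer.max),
          dots))
        fit <- fit_bayesian(ph, trait, kernels, spec, store_effects = FALSE,
                            eigen_cache = cache, check_ess = FALSE)
        idx <- pheno$line_id %in% test_lines
        pred[[m]][idx] <- fit$yhat[idx]
      }
    }
    if (return_predictions) {
      preds[[rep_i]] <- lapply(pred, stats::setNames,
                               paste(pheno$line_id, pheno$treatment, sep = ":"))
    }
    for (m in models) {
      for (trt in c("control", "water_scarce")) {
        sel <- pheno$treatment == trt & !is.na(y_all)
        obs <- y_all[sel]; prd <- pred[[m]][sel]
        r <- if (sum(!is.na(prd)) < 3 || stats::sd(prd, na.rm = TRUE) == 0 ||
                 stats::sd(obs[!is.na(prd)]) == 0) NA_real_ else
          stats::cor(obs, prd, use = "complete.obs")
        rows[[length(rows) + 1]] <- data.frame(
          model = m, trait = trait, treatment = trt, replicate = rep_i,
          pearson_r = r, stringsAsFactors = FALSE)
      }
    }
  }
  replicates <- do.call(rbind, rows)
  agg <- stats::aggregate(pearson_r ~ model + treatment, replicates, mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  names(agg)[names(agg) == "pearson_r"] <- "mean_accuracy"
  structure(list(replicates = replicates, summary = agg, trait = trait,
                 k = k, reps = reps, seed = seed, predictions = preds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> trait '%s': %d-fold CV x %d replicates\n",
              x$trait, x$k, x$reps))
  print(x$summary)
  invisible(x)
}

# compact letter display by insert-absorb over the non-significant pairs
.letter_display <- function(levels_sorted, nonsig_pairs) {
  groups <- list()
  for (lev in levels_sorted) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      ok <- all(vapply(groups[[gi]], function(other) {
        paste(sort(c(lev, other)), collapse = "|") %in% nonsig_pairs
      }, logical(1)))
      if (ok) {
        groups[[gi]] <- c(groups[[gi]], lev)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- lev
  }
  # absorb redundant groups
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i != j && keep[i] && keep[j] && all(groups[[i]] %in% groups[[j]])) {
      keep[i] <- FALSE
    }
  }
  groups <- groups[keep]
  letters_out <- stats::setNames(rep("", length(levels_sorted)), levels_sorted)
  for (gi in seq_along(groups)) {
    for (lev in groups[[gi]]) {
      letters_out[lev] <- paste0(letters_out[lev], letters[gi])
    }
  }
  letters_out
}

#' Tukey HSD comparison of model accuracies
#'
#' Compares the model variants of a [run_cv()] result within one treatment:
#' replicate-level Pearson correlations are Fisher z-transformed, analysed
#' in a one-way layout with model as the factor, and all pairwise
#' differences tested with Tukey's studentized-range correction. Models are
#' then labelled with a compact letter display: variants sharing a letter
#' are not significantly different at `alpha`. Replicates are treated as
#' independent observations; because the same lines are resampled across
#' replicates this is anti-conservative, so the letters should be read as a
#' descriptive ranking aid.
#'
#' @param cv a `cv_result`.
#' @param treatment `"control"` or `"water_scarce"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `tukey_groups`: `letters` (per model),
#'   `pairwise` (adjusted p-values, differences in z), `means` (mean z and
#'   back-transformed accuracy per model).
#' @export
tukey_compare <- function(cv, treatment = c("control", "water_scarce"),
                          alpha = 0.05) {
  treatment <- match.arg(treatment)
  d <- cv$replicates[cv$replicates$treatment == treatment &
                       !is.na(cv$replicates$pearson_r), ]
  if (length(unique(d$model)) < 2) stop("need at least 2 models to compare")
  if (min(table(d$model)) < 2) stop("need at least 2 replicates per model")
  d$z <- fisher_z(d$pearson_r)
  if (max(stats::aggregate(z ~ model, d, stats::var)$z) <= 1e-300) {
    stop("zero within-model variance; increase the number of CV replicates")
  }
  d$model <- factor(d$model)
  fit <- stats::aov(z ~ model, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  pw <- data.frame(pair = rownames(tk), diff_z = tk[, "diff"],
                   p_adj = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
  means <- stats::aggregate(z ~ model, d, mean)
  means <- means[order(-means$z), ]
  nonsig <- pw$pair[pw$p_adj > alpha]
  nonsig <- vapply(strsplit(nonsig, "-", fixed = TRUE),
                   function(v) paste(sort(v), collapse = "|"), "")
  letters_out <- .letter_display(as.character(means$model), nonsig)
  structure(list(letters = letters_out, pairwise = pw,
                 means = data.frame(model = means$model, mean_z = means$z,
                                    mean_accuracy = tanh(means$z)),
                 treatment = treatment, alpha = alpha),
            class = "tukey_groups")
}

#' @export
print.tukey_groups <- function(x, ...) {
  cat(sprintf("<tukey_groups> %s (alpha = %g)\n", x$treatment, x$alpha))
  df <- x$means
  df$group <- x$letters[as.character(df$model)]
  print(df, row.names = FALSE)
  invisible(x)
}
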