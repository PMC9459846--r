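# Genome-wide three-path mediation scan.
#
# Path C: treatment -> trait;  paths A: treatment -> omic feature;
# paths B: feature -> trait adjusting for treatment. All paths are linear
# mixed models with a random line effect (fit_lmm). For the balanced paired
# design (every line observed once per treatment) the per-feature fits have
# a closed form obtained by rotating each line's pair of observations into
# its within-line difference d_i (variance sigma2_e) and sum s_i (variance
# sigma2_e * c with c = 1 + 2*lambda): the profiled ML over c is then
# analytic for path A and a cheap 1-D optimization over 4x4 cross-products
# for path B. The generic fit_lmm route is used whenever the design is
# unbalanced or a feature has missing cells.

# Index pairs (control obs, water_scarce obs) per line, in line order;
# `balanced` is TRUE when every line has exactly one record per treatment.
.pair_index <- function(lines, treatment) {
  lv <- unique(lines)
  key <- paste(lines, treatment)
  ic <- match(paste(lv, "control"), key)
  iw <- match(paste(lv, "water_scarce"), key)
  list(lines = lv, control = ic, scarce = iw,
       balanced = length(lines) == 2L * length(lv) &&
         !anyNA(ic) && !anyNA(iw) && !anyDuplicated(key))
}

.is_balanced_paired <- function(lines, treatment) {
  .pair_index(lines, treatment)$balanced
}

# Profiled -2 logLik for the rotated balanced model given scatter A (difference
# part, fixed-effect-adjusted), scatter B (sum part, mean-adjusted). Vectorized.
.bal_neg2ll <- function(A, B, n, n_lines) {
  chat <- pmin(pmax(ifelse(A > 0, B / A, 1e12), 1), 1e12)
  s2 <- pmax((A + B / chat) / n, 1e-300)
  n * log(2 * pi * s2) + n_lines * log(chat) + n
}

#' Path C: treatment effect on a trait
#'
#' Fits `trait ~ treatment + (random line)` and returns the water-scarce
#' minus control effect with its likelihood-ratio p-value.
#'
#' @param pheno a [phenotype_table()] with both treatments observed.
#' @param trait trait column name.
#' @return list with `beta_treatmentC`, `p_C` and the underlying `fit`.
#' @export
path_C <- function(pheno, trait) {
  stopifnot(inherits(pheno, "phenotype_table"), trait %in% names(pheno))
  y <- pheno[[trait]]
  keep <- !is.na(y)
  if (length(unique(pheno$treatment[keep])) < 2) {
    stop("both treatments must be observed")
  }
  X <- cbind("(Intercept)" = 1,
             treatment = as.numeric(pheno$treatment == "water_scarce"))
  fit <- fit_lmm(y, X, pheno$line_id, test = "treatment")
  list(beta_treatmentC = unname(fit$beta_fixed["treatment"]),
       p_C = unname(fit$p_values["treatment"]), fit = fit)
}

#' Path A scan: treatment effect on each omic feature
#'
#' One mixed model per feature, `feature ~ treatment + (random line)`,
#' returning the treatment coefficient and its LRT p-value. Zero-variance
#' features get `beta_A = 0`, `p_A = 1`.
#'
#' @param omics an [omics_matrix()] (or plain matrix), one row per
#'   observation, aligned with `treatment`/`lines`.
#' @param treatment factor/character of `control`/`water_scarce` per row.
#' @param lines line identifier per row.
#' @return data.frame with `feature_id`, `beta_A`, `p_A`.
#' @export
path_A_scan <- function(omics, treatment, lines) {
  X <- unclass(as.matrix(omics))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (nrow(X) != length(treatment) || nrow(X) != length(lines)) {
    stop("omics rows, treatment and lines must be aligned")
  }
  treatment <- as.character(treatment)
  p <- ncol(X)
  beta <- numeric(p); pval <- rep(1, p)
  prs <- .pair_index(lines, treatment)
  balanced <- prs$balanced
  complete <- if (anyNA(X)) colSums(is.na(X)) == 0L else rep(TRUE, p)
  if (balanced && any(complete)) {
    nl <- length(prs$lines); n <- 2 * nl
    D <- X[prs$scarce, complete, drop = FALSE] - X[prs$control, complete, drop = FALSE]
    S <- X[prs$scarce, complete, drop = FALSE] + X[prs$control, complete, drop = FALSE]
    sumD2 <- colSums(D^2); mD <- colMeans(D)
    A_full <- (sumD2 - nl * mD^2) / 2
    A_red <- sumD2 / 2
    B <- (colSums(S^2) - nl * colMeans(S)^2) / 2
    lrt <- pmax(0, .bal_neg2ll(A_red, B, n, nl) - .bal_neg2ll(A_full, B, n, nl))
    pv <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    zero_var <- A_red + B <= 0
    pv[zero_var] <- 1
    b <- mD; b[zero_var] <- 0
    beta[complete] <- b
    pval[complete] <- pv
  }
  todo <- which(!(balanced & complete))
  X1 <- cbind("(Intercept)" = 1, treatment = as.numeric(treatment == "water_scarce"))
  for (j in todo) {
    xj <- X[, j]
    ok <- !is.na(xj)
    if (stats::var(xj[ok]) == 0 || !all(c(0, 1) %in% X1[ok, 2])) next
    fit <- fit_lmm(xj, X1, lines, test = "treatment")
    beta[j] <- unname(fit$beta_fixed["treatment"])
    pval[j] <- unname(fit$p_values["treatment"])
  }
  data.frame(feature_id = colnames(X), beta_A = beta, p_A = pval,
             stringsAsFactors = FALSE)
}

#' Path B scan: feature effect on a trait, adjusting for treatment
#'
#' One mixed model per feature, `trait ~ treatment + feature +
#' (random line)`, returning the mediator coefficient, the adjusted
#' treatment coefficient and the LRT p-value of the mediator term.
#' Features aliased with the treatment contrast (or constant) are skipped
#' with `p_B = 1` and missing coefficients, and flagged in the `aliased`
#' column.
#'
#' @inheritParams path_A_scan
#' @param trait numeric trait vector aligned with rows of `omics`.
#' @return data.frame with `feature_id`, `beta_mediatorB`,
#'   `beta_treatmentB`, `p_B`, `aliased`.
#' @export
path_B_scan <- function(omics, trait, treatment, lines) {
  X <- unclass(as.matrix(omics))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  y <- as.numeric(trait)
  if (nrow(X) != length(y) || nrow(X) != length(treatment) ||
      nrow(X) != length(lines)) {
    stop("omics rows, trait, treatment and lines must be aligned")
  }
  treatment <- as.character(treatment)
  p <- ncol(X)
  bmed <- rep(NA_real_, p); btrt <- rep(NA_real_, p)
  pval <- rep(1, p); aliased <- logical(p)

  ok_obs <- !is.na(y)
  prs <- .pair_index(lines, treatment)
  balanced <- prs$balanced && all(ok_obs)
  complete <- if (anyNA(X)) colSums(is.na(X)) == 0L else rep(TRUE, p)

  if (balanced && any(complete)) {
    nl <- length(prs$lines); n <- 2 * nl
    t01 <- as.numeric(treatment == "water_scarce")
    Xc <- X[prs$control, complete, drop = FALSE]
    Xw <- X[prs$scarce, complete, drop = FALSE]
    LX <- Xc + Xw
    sumx <- colSums(LX)                 # = Sigma x
    sumx_w <- colSums(Xw)               # Sigma t*x
    sumx2 <- colSums(Xc^2) + colSums(Xw^2)
    Ly <- y[prs$control] + y[prs$scarce]
    sumy <- sum(y); sumy2 <- sum(y^2); sumty <- sum(y[prs$scarce])
    sumxy <- drop(crossprod(X[, complete, drop = FALSE], y))
    sumLxLy <- drop(crossprod(LX, Ly))
    sumLx2 <- colSums(LX^2)
    sumLy2 <- sum(Ly^2)
    # reduced model trait ~ treatment (shared by all features)
    dy <- y[prs$scarce] - y[prs$control]
    A_red <- (sum(dy^2) - nl * mean(dy)^2) / 2
    B_red <- (sumLy2 / 2) - nl * mean(Ly / sqrt(2))^2
    crit_red <- .bal_neg2ll(A_red, B_red, n, nl)
    # per-feature aliasing: residual scatter of x given intercept + treatment
    rssx <- sumx2 - colSums(Xc)^2 / nl - colSums(Xw)^2 / nl
    totx <- sumx2 - sumx^2 / n
    ali <- totx <= 0 | rssx <= 1e-10 * pmax(totx, 1)
    cg_of <- function(cc) (cc - 1) / (2 * cc)
    for (jj in which(complete)) {
      j <- match(jj, which(complete))
      if (ali[j]) { aliased[jj] <- TRUE; next }
      M1 <- matrix(c(n,        nl,        sumx[j],   sumy,
                     nl,       nl,        sumx_w[j], sumty,
                     sumx[j],  sumx_w[j], sumx2[j],  sumxy[j],
                     sumy,     sumty,     sumxy[j],  sumy2), 4, 4)
      # per-line sums of (1, t, x, y) are (2, 1, LX_i, Ly_i)
      M2 <- matrix(c(4 * nl,      2 * nl,   2 * sumx[j], 2 * sumy,
                     2 * nl,      nl,       sumx[j],     sumy,
                     2 * sumx[j], sumx[j],  sumLx2[j],   sumLxLy[j],
                     2 * sumy,    sumy,     sumLxLy[j],  sumLy2), 4, 4)
      crit_fn <- function(logc) {
        cc <- exp(logc)
        Ac <- M1 - cg_of(cc) * M2
        Axx <- Ac[1:3, 1:3]; axy <- Ac[1:3, 4]
        beta <- tryCatch(solve(Axx, axy), error = function(e) NULL)
        if (is.null(beta)) return(Inf)
        rss <- max(Ac[4, 4] - sum(axy * beta), 1e-300)
        n * log(2 * pi * rss / n) + nl * log(cc) + n
      }
      opt <- stats::optimize(crit_fn, c(0, log(1e8)), tol = 1e-8)
      crit_full <- min(opt$objective, crit_fn(0))
      cc <- if (crit_fn(0) <= opt$objective) 1 else exp(opt$minimum)
      Ac <- M1 - cg_of(cc) * M2
      beta <- solve(Ac[1:3, 1:3], Ac[1:3, 4])
      bmed[jj] <- beta[3]; btrt[jj] <- beta[2]
      pval[jj] <- stats::pchisq(max(0, crit_red - crit_full), df = 1,
                                lower.tail = FALSE)
    }
  }

  todo <- which(!(balanced & complete) & !aliased)
  t01 <- as.numeric(treatment == "water_scarce")
  for (j in todo) {
    xj <- X[, j]
    ok <- ok_obs & !is.na(xj)
    if (sum(ok) < 4 || stats::var(xj[ok]) == 0) { aliased[j] <- TRUE; next }
    Xf <- cbind("(Intercept)" = 1, treatment = t01, feature = xj)
    r2 <- summary(stats::lm(xj[ok] ~ t01[ok]))$r.squared
    if (r2 > 1 - 1e-10) { aliased[j] <- TRUE; next }
    fit <- fit_lmm(y[ok], Xf[ok, , drop = FALSE], lines[ok], test = "feature")
    bmed[j] <- unname(fit$beta_fixed["feature"])
    btrt[j] <- unname(fit$beta_fixed["treatment"])
    pval[j] <- unname(fit$p_values["feature"])
  }
  data.frame(feature_id = colnames(X), beta_mediatorB = bmed,
             beta_treatmentB = btrt, p_B = pval, aliased = aliased,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @param alpha FDR level for the significance calls (default 0.05).
#' @return list with `q` (adjusted values) and `significant` (logical).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Permutation minimum-p significance threshold
#'
#' Re-runs a feature scan under `n_perm` permutations of the treatment
#' labels, collects the smallest p-value of each permutation, and returns
#' the empirical `alpha`-quantile of those minima as a family-wise
#' significance threshold. By default labels are swapped within line
#' (each line carries one control and one water-scarce record), which
#' respects the paired design; `unit = "free"` permutes labels freely.
#'
#' @param scan_fn function taking a permuted treatment vector and returning
#'   the vector of per-feature p-values.
#' @param treatment observed treatment labels, one per observation.
#' @param lines line identifier per observation (pairing structure).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha quantile level (default 0.05).
#' @param seed RNG seed; the threshold is a pure function of it.
#' @param unit `"within_line"` (default) or `"free"`.
#' @return the threshold (numeric scalar), with attribute `min_p` carrying
#'   the per-permutation minima.
#' @export
permutation_threshold <- function(scan_fn, treatment, lines, n_perm = 1000,
                                  alpha = 0.05, seed = 1,
                                  unit = c("within_line", "free")) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  unit <- match.arg(unit)
  treatment <- as.character(treatment)
  set.seed(seed)
  lv <- unique(lines)
  other <- c(control = "water_scarce", water_scarce = "control")
  minp <- vapply(seq_len(n_perm), function(b) {
    perm <- if (unit == "within_line") {
      flip <- stats::runif(length(lv)) < 0.5
      ifelse(flip[match(lines, lv)], other[treatment], treatment)
    } else {
      sample(treatment)
    }
    min(scan_fn(perm), na.rm = TRUE)
  }, numeric(1))
  thr <- unname(stats::quantile(minp, probs = alpha, type = 1))
  attr(thr, "min_p") <- minp
  thr
}

#' Run the full three-path mediation scan for one trait
#'
#' Convenience wrapper: computes path C on the phenotypes, paths A and B
#' across all features of `omics`, BH-adjusts both scans, optionally
#' computes permutation minimum-p thresholds, and classifies mediators.
#' Omics rows are matched to phenotype records via their row identifiers:
#' `"<line>:<treatment>"` sample ids first, bare line ids as fallback
#' (features then constant within line across treatments).
#'
#' @param pheno a [phenotype_table()].
#' @param trait trait column name.
#' @param omics an [omics_matrix()] of mediator features.
#' @param alpha FDR / threshold level (default 0.05).
#' @param n_perm permutations for the min-p thresholds; 0 skips them.
#' @param seed RNG seed for the permutations.
#' @return object of class `mediation_scan`: `features` data.frame
#'   (per-feature path A/B statistics and BH q-values), `beta_treatmentC`,
#'   `p_C`, permutation thresholds (or NA), `mediators` (BH rule).
#' @export
mediation_scan <- function(pheno, trait, omics, alpha = 0.05, n_perm = 0,
                           seed = 1) {
  stopifnot(inherits(pheno, "phenotype_table"))
  X <- .align_omics_obs(omics, pheno)
  trt <- as.character(pheno$treatment)
  lin <- pheno$line_id
  y <- pheno[[trait]]

  pc <- path_C(pheno, trait)
  pa <- path_A_scan(X, trt, lin)
  pb <- path_B_scan(X, y, trt, lin)
  qa <- bh_adjust(pa$p_A, alpha)
  qb <- bh_adjust(pb$p_B, alpha)
  features <- data.frame(pa, q_A = qa$q,
                         pb[, c("beta_mediatorB", "beta_treatmentB", "p_B", "aliased")],
                         q_B = qb$q, stringsAsFactors = FALSE)
  thr_A <- thr_B <- NA_real_
  if (n_perm > 0) {
    thr_A <- as.numeric(permutation_threshold(
      function(perm) path_A_scan(X, perm, lin)$p_A,
      trt, lin, n_perm = n_perm, alpha = alpha, seed = seed))
    thr_B <- as.numeric(permutation_threshold(
      function(perm) path_B_scan(X, y, perm, lin)$p_B,
      trt, lin, n_perm = n_perm, alpha = alpha, seed = seed + 1))
  }
  out <- structure(list(trait = trait, features = features,
                        beta_treatmentC = pc$beta_treatmentC, p_C = pc$p_C,
                        permutation_threshold_A = thr_A,
                        permutation_threshold_B = thr_B,
                        alpha = alpha),
                   class = "mediation_scan")
  out$mediators <- classify_mediators(out, rule = "bh")
  out
}

# Align omics rows to phenotype records; errors list unmatched records.
.align_omics_obs <- function(omics, pheno) {
  X <- unclass(as.matrix(omics))
  sample_ids <- paste(pheno$line_id, pheno$treatment, sep = ":")
  if (all(sample_ids %in% rownames(X))) {
    return(X[sample_ids, , drop = FALSE])
  }
  if (all(pheno$line_id %in% rownames(X))) {
    out <- X[pheno$line_id, , drop = FALSE]
    rownames(out) <- sample_ids
    return(out)
  }
  miss <- setdiff(sample_ids, rownames(X))
  miss <- if (length(miss)) miss else setdiff(pheno$line_id, rownames(X))
  stop("omics rows do not match phenotype records; unmatched: ",
       paste(utils::head(miss, 5), collapse = ", "))
}

#' Classify mediator features
#'
#' A feature is a mediator when its path-B mediator term is significant
#' (BH q-value at `alpha`, or p below the permutation min-p threshold) and
#' the treatment coefficient of the path-B model is attenuated relative to
#' path C: `|beta_treatmentB| < |beta_treatmentC|`. Path-A significance is
#' not required by default; `strict_path_A = TRUE` additionally demands it.
#'
#' @param scan a `mediation_scan` object.
#' @param rule `"bh"` or `"permutation"`.
#' @param alpha significance level for the BH rule (defaults to the scan's).
#' @param strict_path_A also require path-A significance.
#' @return character vector of mediator feature ids.
#' @export
classify_mediators <- function(scan, rule = c("bh", "permutation"),
                               alpha = NULL, strict_path_A = FALSE) {
  rule <- match.arg(rule)
  if (is.null(alpha)) alpha <- scan$alpha
  f <- scan$features
  sig_B <- if (rule == "bh") f$q_B <= alpha else {
    if (is.na(scan$permutation_threshold_B)) {
      stop("no permutation threshold available; rerun with n_perm > 0")
    }
    f$p_B < scan$permutation_threshold_B
  }
  atten <- !is.na(f$beta_treatmentB) &
    abs(f$beta_treatmentB) < abs(scan$beta_treatmentC)
  keep <- sig_B & atten
  if (strict_path_A) {
    sig_A <- if (rule == "bh") f$q_A <= alpha else f$p_A < scan$permutation_threshold_A
    keep <- keep & sig_A
  }
  f$feature_id[keep]
}

#' Overlap summary across mediation paths and traits
#'
#' Summarizes, per trait, the significant path-A set, significant path-B
#' set and the attenuated (mediator) set with all pairwise and triple
#' intersection counts, plus pairwise cross-trait mediator overlaps.
#'
#' @param scans named list of `mediation_scan` objects (one per trait).
#' @param alpha significance level (defaults to each scan's own).
#' @return object of class `overlap_summary`: per-trait set list and count
#'   tables.
#' @export
overlap_summary <- function(scans, alpha = NULL) {
  stopifnot(length(scans) >= 1)
  if (is.null(names(scans))) names(scans) <- vapply(scans, `[[`, "", "trait")
  sets <- lapply(scans, function(s) {
    a <- if (is.null(alpha)) s$alpha else alpha
    f <- s$features
    list(significant_A = f$feature_id[f$q_A <= a],
         significant_B = f$feature_id[f$q_B <= a],
         attenuated = classify_mediators(s, rule = "bh", alpha = a))
  })
  within <- do.call(rbind, lapply(names(sets), function(tr) {
    s <- sets[[tr]]
    data.frame(trait = tr,
               n_A = length(s$significant_A), n_B = length(s$significant_B),
               n_attenuated = length(s$attenuated),
               n_A_B = length(intersect(s$significant_A, s$significant_B)),
               n_A_att = length(intersect(s$significant_A, s$attenuated)),
               n_B_att = length(intersect(s$significant_B, s$attenuated)),
               n_A_B_att = length(Reduce(intersect, s)),
               stringsAsFactors = FALSE)
  }))
  traits <- names(sets)
  cross <- matrix(0L, length(traits), length(traits),
                  dimnames = list(traits, traits))
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    cross[i, j] <- length(intersect(sets[[i]]$attenuated, sets[[j]]$attenuated))
  }
  structure(list(sets = sets, within_trait = within, cross_trait = cross),
            class = "overlap_summary")
}

#' Two-mediator path (not supported)
#'
#' The two-mediator extension (one mediator influencing another) is not
#' implemented; single-mediator scans of each omic layer are the supported
#' analysis.
#'
#' @param ... ignored.
#' @export
two_mediator_path <- function(...) {
  stop("two-mediator analysis is not implemented; run single-mediator scans ",
       "per omic layer instead")
}
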