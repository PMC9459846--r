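# Linear mixed model with a single random grouping (line), fitted by
# profiling the variance ratio lambda = sigma2_line / sigma2_resid.
#
# With V* = I + lambda Z Z', the grouped structure gives O(n) evaluation of
# the profiled (restricted) likelihood: per group g of size n_g,
# (I + lambda J)^-1 = I - lambda/(1 + n_g lambda) J, so all GLS
# cross-products reduce to raw cross-products corrected by group sums.

# Cross-product pieces for a given lambda. Returns GLS quantities.
.lmm_parts <- function(lambda, XtX, Xty, yty, S, Sy, sizes) {
  cg <- lambda / (1 + sizes * lambda)
  Sc <- S * cg
  A <- XtX - crossprod(S, Sc)          # X' V*^-1 X
  b <- Xty - crossprod(Sc, Sy)         # X' V*^-1 y
  qyy <- yty - sum(cg * Sy^2)          # y' V*^-1 y
  beta <- solve(A, b)
  rss <- max(qyy - sum(b * beta), 1e-300)
  list(A = A, beta = beta, rss = rss, logdet = sum(log1p(sizes * lambda)))
}

.lmm_neg2ll <- function(lambda, XtX, Xty, yty, S, Sy, sizes, n, p, reml) {
  parts <- .lmm_parts(lambda, XtX, Xty, yty, S, Sy, sizes)
  if (reml) {
    s2 <- parts$rss / (n - p)
    (n - p) * log(2 * pi * s2) + parts$logdet +
      determinant(parts$A, logarithm = TRUE)$modulus[1] + (n - p)
  } else {
    s2 <- parts$rss / n
    n * log(2 * pi * s2) + parts$logdet + n
  }
}

.lmm_opt <- function(y, X, group, reml) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  GS <- rowsum(cbind(X, y), group)
  S <- GS[, seq_len(p), drop = FALSE]; Sy <- GS[, p + 1]
  sizes <- as.vector(rowsum(rep(1, n), group))
  f <- function(loglam) .lmm_neg2ll(exp(loglam), XtX, Xty, yty, S, Sy, sizes,
                                    n, p, reml)
  opt <- stats::optimize(f, c(-25, 25), tol = 1e-9)
  f0 <- .lmm_neg2ll(0, XtX, Xty, yty, S, Sy, sizes, n, p, reml)
  if (f0 <= opt$objective) {
    lambda <- 0; crit <- f0
  } else {
    lambda <- exp(opt$minimum); crit <- opt$objective
  }
  parts <- .lmm_parts(lambda, XtX, Xty, yty, S, Sy, sizes)
  s2 <- parts$rss / (if (reml) n - p else n)
  list(lambda = lambda, beta = drop(parts$beta), sigma2_resid = s2,
       sigma2_line = lambda * s2, neg2ll = crit, n = n, p = p)
}

#' Fit a linear mixed model with a random line effect
#'
#' Fits `y = X beta + l + e` with iid line effects `l ~ N(0, sigma2_line)`
#' and residuals `e ~ N(0, sigma2_resid)` by REML (estimates) and ML
#' (likelihood-ratio tests), profiling the likelihood over the variance
#' ratio with exact boundary handling at `sigma2_line = 0`. This is the
#' descriptive per-trait model `y_ij = T_j t + l_i + e_ij` for a
#' two-treatment design, and the per-feature engine of the mediation scan.
#'
#' P-values for fixed terms are likelihood-ratio tests between nested ML
#' fits (chi-square with 1 df), a reproducible choice that avoids
#' denominator degree-of-freedom approximations.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (include the intercept column);
#'   must be full column rank.
#' @param group factor/vector of line identifiers, one per observation.
#' @param test columns of `X` (by name) to test via LRT; defaults to all
#'   non-intercept columns. Use `character(0)` to skip tests.
#' @return list of class `lmm_fit`: `beta_fixed`, `sigma2_line`,
#'   `sigma2_resid`, `lambda`, `loglik_ML`, `loglik_REML`, `n_obs`,
#'   `p_values`.
#' @export
fit_lmm <- function(y, X, group, test = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(y) & !apply(X, 1, anyNA)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; group <- group[keep]
  if (length(unique(group)) < 2) stop("need observations from at least 2 lines")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  reml <- .lmm_opt(y, X, group, reml = TRUE)
  ml <- .lmm_opt(y, X, group, reml = FALSE)
  if (is.null(test)) {
    test <- setdiff(colnames(X), c("(Intercept)", "intercept"))
  }
  pv <- stats::setNames(numeric(0), character(0))
  if (length(test)) {
    pv <- vapply(test, function(term) {
      Xr <- X[, setdiff(colnames(X), term), drop = FALSE]
      ml0 <- .lmm_opt(y, Xr, group, reml = FALSE)
      lrt <- max(0, ml0$neg2ll - ml$neg2ll)
      stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    }, numeric(1))
  }
  structure(list(beta_fixed = stats::setNames(reml$beta, colnames(X)),
                 sigma2_line = reml$sigma2_line,
                 sigma2_resid = reml$sigma2_resid,
                 lambda = reml$lambda,
                 loglik_ML = -ml$neg2ll / 2,
                 loglik_REML = -reml$neg2ll / 2,
                 n_obs = reml$n,
                 p_values = pv),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>\n  fixed effects:\n")
  for (nm in names(x$beta_fixed)) {
    p <- x$p_values[nm]
    cat(sprintf("    %-14s %10.4f%s\n", nm, x$beta_fixed[nm],
                if (!is.na(p)) sprintf("  (LRT p = %.3g)", p) else ""))
  }
  cat(sprintf("  sigma2_line  = %.4f\n  sigma2_resid = %.4f\n  logLik(ML) = %.3f  n = %d\n",
              x$sigma2_line, x$sigma2_resid, x$loglik_ML, x$n_obs))
  invisible(x)
}
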