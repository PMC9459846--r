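#' Proportion of phenotypic variance explained per model term
#'
#' Decomposes the phenotypic variance from posterior samples: for each
#' stored draw s, the variance of component c is the sample variance across
#' observations of that component's realized values (the treatment term
#' uses the draw's treatment means mapped to observations), the total is
#' the sum of those variances plus the draw's residual variance parameter,
#' and PV2_c(s) is the ratio. Working with realized-value variances rather
#' than the raw variance parameters makes the decomposition account for the
#' covariance among features within an omic (and insensitive to kernel
#' diagonal rescaling). The genomic (`SNP`) entry is the narrow-sense
#' heritability estimate. Per draw the reported fractions sum to 1 exactly.
#'
#' @param samples a `posterior_samples` object from [fit_bayesian()].
#' @return data.frame of class `pv2_table` with one row per term
#'   (`TREATMENT`, the model components, `RESID`): posterior mean and SD of
#'   PV2, plus the posterior mean variance.
#' @export
pv2 <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  cv <- samples$comp_var
  if (is.null(cv)) stop("samples carry no realized component values")
  resid <- samples$sigma2[, "RESID"]
  V <- cbind(cv, RESID = resid)
  total <- rowSums(V)
  P <- V / total
  out <- data.frame(term = colnames(V),
                    pv2_mean = colMeans(P),
                    pv2_sd = apply(P, 2, stats::sd),
                    var_mean = colMeans(V),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("pv2_table", "data.frame"),
            trait = samples$trait,
            model = paste(samples$spec$components, collapse = ","))
}

#' @export
print.pv2_table <- function(x, ...) {
  cat(sprintf("<pv2_table> trait '%s', model {%s}\n", attr(x, "trait"),
              attr(x, "model")))
  NextMethod()
}
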