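# Small in-code fixtures shared across test files.

# balanced paired design: n_lines lines x {control, water_scarce}
paired_design <- function(n_lines) {
  lines <- sprintf("L%03d", seq_len(n_lines))
  list(lines = rep(lines, 2),
       treatment = rep(c("control", "water_scarce"), each = n_lines),
       line_levels = lines)
}

# phenotype table from a design and trait vector
paired_pheno <- function(design, y, trait = "trait") {
  df <- data.frame(line_id = design$lines, treatment = design$treatment,
                   stringsAsFactors = FALSE)
  df[[trait]] <- y
  phenotype_table(df)
}

# write a small TSV and return the path
write_fixture <- function(lines_of_text) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines_of_text, path)
  path
}

# dense REML log-likelihood for the single-grouping LMM, used as an
# independent oracle against the profiled implementation
dense_reml_loglik <- function(y, X, group, s2l, s2e) {
  Z <- outer(group, unique(group), "==") * 1
  V <- s2e * diag(length(y)) + s2l * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r +
                       (length(y) - ncol(X)) * log(2 * pi)))
}
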