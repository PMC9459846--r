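short_spec <- function(components, seed = 1, n_iter = 3000, burn_in = 500) {
  model_spec(components, n_iter = n_iter, burn_in = burn_in, thin = 2,
             seed = seed)
}

test_that("chains are bitwise reproducible given the seed", {
  set.seed(40)
  g <- simulate_genotypes(30, 200, seed = 40)
  sim <- simulate_phenotypes(list(snp = g),
                             c(snp = 0.5, line = 0.2, residual = 0.3),
                             seed = 41)
  K <- sim$truth$kernels
  f1 <- fit_bayesian(sim$pheno, "trait", K, short_spec(c("LINE", "SNP"), 7),
                     check_ess = FALSE)
  f2 <- fit_bayesian(sim$pheno, "trait", K, short_spec(c("LINE", "SNP"), 7),
                     check_ess = FALSE)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$yhat, f2$yhat)
  f3 <- fit_bayesian(sim$pheno, "trait", K, short_spec(c("LINE", "SNP"), 8),
                     check_ess = FALSE)
  expect_false(identical(f1$sigma2, f3$sigma2))
})

test_that("baseline model treatment effect matches the REML engine", {
  set.seed(42)
  g <- simulate_genotypes(75, 100, seed = 42)
  sim <- simulate_phenotypes(list(snp = g),
                             c(treatment = 0.1, line = 0.4, residual = 0.5),
                             treatment_effect = -0.9, seed = 43)
  fit <- fit_bayesian(sim$pheno, "trait", list(),
                      short_spec("LINE", seed = 3, n_iter = 6000,
                                 burn_in = 1000), check_ess = FALSE)
  dmu <- fit$mu[, "water_scarce"] - fit$mu[, "control"]
  pc <- path_C(sim$pheno, "trait")
  expect_lt(abs(mean(dmu) - pc$beta_treatmentC), 3 * sd(dmu))
})

test_that("identity-kernel variances recover simulation truth", {
  set.seed(44)
  n <- 250
  lines <- sprintf("L%03d", seq_len(n))
  u <- rnorm(n, sd = sqrt(2))
  df <- data.frame(line_id = rep(lines, 2),
                   treatment = rep(c("control", "water_scarce"), each = n))
  df$trait <- u[match(df$line_id, lines)] + rnorm(2 * n, sd = 1)
  ph <- phenotype_table(df)
  K <- structure(diag(n), dimnames = list(lines, lines))
  fit <- fit_bayesian(ph, "trait", list(snp = K),
                      short_spec("SNP", seed = 5, n_iter = 5000,
                                 burn_in = 1000), check_ess = FALSE)
  pm <- colMeans(fit$sigma2)
  expect_lt(abs(pm[["SNP"]] - 2) / 2, 0.15)
  expect_lt(abs(pm[["RESID"]] - 1) / 1, 0.15)
})

test_that("degenerate inputs raise the documented errors", {
  d <- paired_design(20)
  ph <- paired_pheno(d, rep(1, 40))
  expect_error(fit_bayesian(ph, "trait", list(), short_spec("LINE")),
               "zero phenotypic variance")
  ph2 <- paired_pheno(d, rnorm(40))
  expect_error(fit_bayesian(ph2, "trait", list(), short_spec(c("LINE", "SNP"))),
               "kernels\\$snp")
  K_small <- structure(diag(3), dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  expect_error(fit_bayesian(ph2, "trait", list(snp = K_small),
                            short_spec(c("LINE", "SNP"))),
               "unmatched")
  K_bad <- structure(matrix(c(1, 2, 2, 1), 2),
                     dimnames = list(c("L001", "L002"), c("L001", "L002")))
  ph3 <- paired_pheno(paired_design(2), rnorm(4))
  expect_error(suppressWarnings(
    fit_bayesian(ph3, "trait", list(snp = K_bad),
                 short_spec(c("LINE", "SNP")))))
})

test_that("a duplicated kernel row predicts like its twin line", {
  set.seed(45)
  n <- 25
  g <- simulate_genotypes(n, 300, seed = 45)
  G2 <- rbind(unclass(g), unclass(g)[n, , drop = FALSE])
  rownames(G2) <- c(rownames(g), "L_dup")
  K <- similarity(omics_matrix(G2, "snp"))
  sim <- simulate_phenotypes(list(snp = g),
                             c(snp = 0.6, residual = 0.4), seed = 46)
  ph <- sim$pheno
  extra <- data.frame(line_id = rep("L_dup", 2),
                      treatment = c("control", "water_scarce"))
  extra$trait <- NA_real_
  ph_all <- phenotype_table(rbind(as.data.frame(ph), extra))
  fit <- fit_bayesian(ph_all, "trait", list(snp = K),
                      short_spec("SNP", seed = 6), check_ess = FALSE)
  twin <- sprintf("L%03d", n)
  expect_equal(unname(fit$yhat[paste0("L_dup:control")]),
               unname(fit$yhat[paste0(twin, ":control")]), tolerance = 1e-8)
})

test_that("unseen lines under the baseline model get the treatment mean", {
  set.seed(47)
  d <- paired_design(30)
  y <- rnorm(60)
  ph <- paired_pheno(d, y)
  ph$trait[ph$line_id %in% c("L001", "L002")] <- NA
  fit <- fit_bayesian(ph, "trait", list(),
                      short_spec("LINE", seed = 2, n_iter = 20000,
                                 burn_in = 2000), check_ess = FALSE)
  # line effect posterior for an unphenotyped line is its prior (mean 0 up
  # to Monte Carlo error), so the prediction is the treatment mean
  mu_hat <- colMeans(fit$mu)
  expect_lt(abs(fit$yhat[["L001:control"]] - mu_hat[["control"]]), 0.1)
})

test_that("posterior summaries are stable under consistent line relabelling", {
  set.seed(48)
  g <- simulate_genotypes(40, 300, seed = 48)
  sim <- simulate_phenotypes(list(snp = g),
                             c(snp = 0.5, line = 0.2, residual = 0.3),
                             seed = 49)
  K <- sim$truth$kernels$snp
  perm <- sample(40)
  ph2 <- phenotype_table(as.data.frame(sim$pheno)[c(perm, perm + 40), ])
  f1 <- fit_bayesian(sim$pheno, "trait", list(snp = K),
                     short_spec(c("LINE", "SNP"), 9, n_iter = 8000,
                                burn_in = 2000), check_ess = FALSE)
  f2 <- fit_bayesian(ph2, "trait", list(snp = K),
                     short_spec(c("LINE", "SNP"), 9, n_iter = 8000,
                                burn_in = 2000), check_ess = FALSE)
  expect_equal(colMeans(f1$sigma2), colMeans(f2$sigma2), tolerance = 0.25)
  expect_equal(pv2(f1)$pv2_mean, pv2(f2)$pv2_mean, tolerance = 0.1)
})
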