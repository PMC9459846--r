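test_that("genotype generator respects MAF, inbreeding and independence", {
  g <- simulate_genotypes(500, 200, ld_block = 1, seed = 70)
  G <- unclass(g)
  expect_true(all(G %in% c(0, 2)))          # inbred: no heterozygotes
  maf <- colMeans(G) / 2
  expect_true(all(maf >= 0 & maf <= 0.6))
  expect_lt(abs(mean(maf) - 0.275), 0.05)   # mean of U(0.05, 0.5)
  C <- cor(G)^2
  expect_lt(mean(C[upper.tri(C)]), 0.05)    # block size 1 -> independent
})

test_that("LD blocks create within-block correlation", {
  g <- simulate_genotypes(400, 100, ld_block = 10, r_within = 0.9, seed = 71)
  C <- cor(unclass(g))^2
  within <- mean(C[1:10, 1:10][upper.tri(C[1:10, 1:10])])
  between <- mean(C[1:10, 11:20])
  expect_gt(within, 0.3)
  expect_lt(between, 0.05)
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.6, 0.7)),
               "maf_range")
})

test_that("methylation levels stay in range with requested contexts", {
  m <- simulate_methylation(20, 10000, context_props = c(CG = 0.5, CHG = 0.3,
                                                         CHH = 0.2), seed = 72)
  expect_true(all(m >= 0 & m <= 1))
  tab <- table(feature_meta(m)$context) / ncol(m)
  expect_equal(as.vector(tab[c("CG", "CHG", "CHH")]), c(0.5, 0.3, 0.2),
               tolerance = 0.03)
  m0 <- simulate_methylation(5, 50, line_effect_sd = 0, seed = 73)
  expect_equal(max(apply(unclass(m0), 2, function(v) diff(range(v)))), 0)
})

test_that("expression is positive, sample-indexed and treatment-responsive", {
  g <- simulate_genotypes(40, 100, seed = 74)
  e <- simulate_expression(40, 300, g, n_mediators = 30, a = 1.2,
                           trans_h2 = 0.3, seed = 75)
  expect_true(all(e > 0))
  expect_equal(nrow(e), 80)
  expect_length(attr(e, "mediators"), 30)
  lg <- log(unclass(e))
  scarce <- grepl("water_scarce", rownames(e))
  shift <- colMeans(lg[scarce, ]) - colMeans(lg[!scarce, ])
  expect_gt(mean(shift[1:30]), 0.8)
  expect_lt(abs(mean(shift[31:300])), 0.15)
})

test_that("null expression shows no treatment signal", {
  g <- simulate_genotypes(60, 80, seed = 76)
  e <- simulate_expression(60, 200, g, n_mediators = 0, a = 0, seed = 77)
  d <- paired_design(60)
  pa <- path_A_scan(log(unclass(e)), d$treatment, d$lines)
  expect_gt(mean(pa$p_A > 0.05), 0.9)
})

test_that("phenotype simulation hits requested variance shares exactly", {
  g <- simulate_genotypes(40, 200, seed = 78)
  m <- simulate_methylation(40, 300, seed = 79)
  fr <- c(treatment = 0.1, line = 0.2, snp = 0.4, meth = 0.1, residual = 0.2)
  sim <- simulate_phenotypes(list(snp = g, meth = m), fr,
                             treatment_effect = -0.78, seed = 80)
  comp <- sim$truth$components
  s2 <- sim$truth$sigmaP2
  for (nm in c("line", "snp", "meth", "residual")) {
    expect_equal(var(comp[[nm]]) / s2, unname(fr[nm]), tolerance = 1e-10)
  }
  expect_equal(var(comp$treatment) / s2, unname(fr["treatment"]),
               tolerance = 1e-10)
  expect_error(simulate_phenotypes(list(snp = g), c(snp = 0.7)),
               "sum to 1")
})

test_that("an all-residual trait is uncorrelated with every kernel effect", {
  g <- simulate_genotypes(75, 300, seed = 81)
  sim <- simulate_phenotypes(list(snp = g), c(residual = 1), seed = 82)
  y <- sim$pheno$trait
  K <- sim$truth$kernels$snp
  # correlation of the trait with the leading kernel eigenvectors
  ev <- eigen(unclass(K), symmetric = TRUE)
  lines <- rownames(K)
  y_line <- tapply(y, sim$pheno$line_id, mean)[lines]
  for (j in 1:3) expect_lt(abs(cor(y_line, ev$vectors[, j])), 0.3)
})

test_that("treatment effect scaled like the study is recovered by path C", {
  g <- simulate_genotypes(75, 400, seed = 83)
  sim <- simulate_phenotypes(list(snp = g),
                             c(treatment = 0.05, line = 0.25, snp = 0.3,
                               residual = 0.4),
                             treatment_effect = -0.78, seed = 84)
  pc <- path_C(sim$pheno, "trait")
  s2 <- sim$truth$sigmaP2
  se <- sqrt(2 * 0.4 * s2 / 75)  # paired-contrast standard error
  expect_lt(abs(pc$beta_treatmentC - (-0.78)), 3 * se)
})

test_that("generators are pure functions of their seeds", {
  expect_identical(unclass(simulate_genotypes(10, 20, seed = 85)),
                   unclass(simulate_genotypes(10, 20, seed = 85)))
  expect_identical(unclass(simulate_methylation(5, 30, seed = 86)),
                   unclass(simulate_methylation(5, 30, seed = 86)))
  g <- simulate_genotypes(8, 15, seed = 87)
  expect_identical(unclass(simulate_expression(8, 20, g, seed = 88)),
                   unclass(simulate_expression(8, 20, g, seed = 88)))
})

test_that("the bundled study-shaped dataset has the documented geometry", {
  ds <- make_paper_like_dataset(seed = 2, n_lines = 20, n_snps = 300,
                                n_meth_sites = 400, n_genes = 250)
  expect_equal(nrow(ds$pheno), 40)
  expect_setequal(trait_names(ds$pheno),
                  c("grain_yield", "tkw", "nitrogen_uptake", "protein"))
  expect_equal(dim(ds$geno), c(20L, 300L))
  expect_equal(nrow(ds$expr), 40)   # sample-level expression
  expect_equal(ds$truths$grain_yield$treatment_effect, -0.78)
  expect_true(all(abs(vapply(ds$truths,
                             function(t) sum(t$fractions), 0) - 1) < 1e-8))
})

test_that("near-duplicate markers are created and removed by LD pruning", {
  g <- simulate_genotypes(60, 200, ld_block = 10, near_dup_frac = 0.5,
                          seed = 90)
  res <- filter_snps(g, ld_r2 = 0.9, window = 50)
  expect_gt(res$report$removals[["ld"]], 30)
})

test_that("the study-shaped dataset wires the mediation chain into traits", {
  ds <- make_paper_like_dataset(seed = 3, n_lines = 30, n_snps = 200,
                                n_meth_sites = 150, n_genes = 300)
  expect_gt(length(ds$mediators), 0)
  fr <- ds$truths$grain_yield$fractions
  expect_equal(unname(fr[["mediation"]]), 0.10)
  expect_equal(sum(fr), 1)
  # non-mediated traits carry no mediation share
  expect_equal(unname(ds$truths$tkw$fractions[["mediation"]]), 0)
})
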