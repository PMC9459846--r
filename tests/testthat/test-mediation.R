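test_that("BH step-up matches the hand-derived example", {
  res <- bh_adjust(c(0.01, 0.02, 0.04, 0.5), alpha = 0.05)
  expect_equal(res$q, c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_equal(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_adjust(rep(1, 5))$q, rep(1, 5))
  expect_false(any(bh_adjust(rep(1, 5))$significant))
  expect_equal(bh_adjust(0.03)$q, 0.03)
  expect_true(all(bh_adjust(runif(20))$q >= bh_adjust(runif(20))$q * 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values never fall below p-values", {
  set.seed(30)
  p <- runif(200)
  expect_true(all(bh_adjust(p)$q >= p))
})

test_that("deterministic path contrasts are recovered exactly", {
  d <- paired_design(20)
  y <- as.numeric(d$treatment == "water_scarce")  # +1 under scarcity, no noise
  ph <- paired_pheno(d, y)
  pc <- path_C(ph, "trait")
  expect_equal(pc$beta_treatmentC, 1, tolerance = 1e-10)
})

test_that("path A flags perfect signal and degenerate features correctly", {
  set.seed(31)
  d <- paired_design(40)
  X <- cbind(signal = as.numeric(d$treatment == "water_scarce") +
               rnorm(80, sd = 0.1),
             flat = rep(1, 80),
             noise = rnorm(80))
  pa <- path_A_scan(X, d$treatment, d$lines)
  expect_lt(pa$p_A[1], 1e-6)
  expect_equal(pa$beta_A[2], 0)
  expect_equal(pa$p_A[2], 1)
  expect_gt(pa$p_A[3], 0.001)
})

test_that("fast balanced scans agree with the generic mixed-model route", {
  set.seed(32)
  d <- paired_design(30)
  X <- matrix(rnorm(60 * 6), 60, 6)
  X[, 1] <- X[, 1] + 0.6 * (d$treatment == "water_scarce")
  y <- 0.4 * (d$treatment == "water_scarce") + 0.5 * X[, 2] +
    rnorm(30, sd = 0.4)[match(d$lines, d$line_levels)] + rnorm(60, sd = 0.6)
  Xd <- cbind("(Intercept)" = 1,
              treatment = as.numeric(d$treatment == "water_scarce"))
  pa <- path_A_scan(X, d$treatment, d$lines)
  pb <- path_B_scan(X, y, d$treatment, d$lines)
  for (j in 1:6) {
    fa <- fit_lmm(X[, j], Xd, d$lines, test = "treatment")
    expect_equal(pa$beta_A[j], unname(fa$beta_fixed["treatment"]),
                 tolerance = 1e-8)
    expect_equal(log(pa$p_A[j]), log(unname(fa$p_values["treatment"])),
                 tolerance = 1e-6)
    fb <- fit_lmm(y, cbind(Xd, feature = X[, j]), d$lines, test = "feature")
    expect_equal(pb$beta_mediatorB[j], unname(fb$beta_fixed["feature"]),
                 tolerance = 2e-2)
    expect_equal(log(pb$p_B[j]), log(unname(fb$p_values["feature"])),
                 tolerance = 1e-6)
  }
})

test_that("features aliased with treatment are skipped, not fatal", {
  set.seed(33)
  d <- paired_design(15)
  X <- cbind(dup = as.numeric(d$treatment == "water_scarce"),
             ok = rnorm(30))
  y <- rnorm(30)
  pb <- path_B_scan(X, y, d$treatment, d$lines)
  expect_true(pb$aliased[1])
  expect_equal(pb$p_B[1], 1)
  expect_false(pb$aliased[2])
})

test_that("null features keep beta_mediatorB near zero", {
  set.seed(34)
  d <- paired_design(75)
  X <- matrix(rnorm(150 * 30), 150, 30)
  y <- rnorm(75)[match(d$lines, d$line_levels)] + rnorm(150)
  pb <- path_B_scan(X, y, d$treatment, d$lines)
  # 30 null features: none should be extreme (3 SE is approx 3/sqrt(n))
  expect_true(mean(abs(pb$beta_mediatorB) < 3 * sqrt(2 / 150)) > 0.8)
})

test_that("path C p-values are uniform under the null", {
  set.seed(35)
  nrep <- 300
  d <- paired_design(75)
  pvals <- vapply(seq_len(nrep), function(i) {
    y <- rnorm(75, sd = 0.7)[match(d$lines, d$line_levels)] + rnorm(150)
    path_C(paired_pheno(d, y), "trait")$p_C
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation threshold is deterministic and checks n_perm", {
  set.seed(36)
  d <- paired_design(20)
  X <- matrix(rnorm(40 * 10), 40, 10)
  fn <- function(perm) path_A_scan(X, perm, d$lines)$p_A
  t1 <- permutation_threshold(fn, d$treatment, d$lines, n_perm = 150, seed = 9)
  t2 <- permutation_threshold(fn, d$treatment, d$lines, n_perm = 150, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_error(permutation_threshold(fn, d$treatment, d$lines, n_perm = 2),
               "at least 100")
})

test_that("min-p threshold matches the Beta order-statistic oracle", {
  # exact-uniform per-feature p-values: paired t-test on Gaussian noise
  set.seed(37)
  d <- paired_design(40)
  m <- 100
  X <- matrix(rnorm(80 * m), 80, m)
  prs <- match(paste(d$line_levels, "water_scarce"),
               paste(d$lines, d$treatment))
  ctl <- match(paste(d$line_levels, "control"), paste(d$lines, d$treatment))
  fn <- function(perm) {
    s <- ifelse(perm[prs] == "water_scarce", 1, -1)
    D <- (X[prs, ] - X[ctl, ]) * s
    tt <- colMeans(D) / sqrt(apply(D, 2, var) / nrow(D))
    2 * pt(-abs(tt), df = nrow(D) - 1)
  }
  thr <- permutation_threshold(fn, d$treatment, d$lines, n_perm = 1000,
                               seed = 5)
  oracle <- qbeta(0.05, 1, m)   # alpha-quantile of min of m uniforms
  mc_se <- sqrt(0.05 * 0.95 / 1000) / (m * (1 - oracle)^(m - 1))
  expect_lt(abs(as.numeric(thr) - oracle), 4 * mc_se)
})

test_that("mediator classification applies the attenuation criterion", {
  scan <- structure(list(
    trait = "grain_yield",
    features = data.frame(
      feature_id = c("g1", "g2", "g3"),
      p_A = c(0.001, 0.5, 0.9), q_A = c(0.01, 0.7, 0.95),
      beta_mediatorB = c(0.4, 0.3, 0.1),
      beta_treatmentB = c(-0.50, -0.90, -0.20),
      p_B = c(0.001, 0.002, 0.8), q_B = c(0.01, 0.01, 0.9),
      aliased = FALSE, stringsAsFactors = FALSE),
    beta_treatmentC = -0.78, p_C = 1e-5,
    permutation_threshold_A = 0.005, permutation_threshold_B = 0.005,
    alpha = 0.05), class = "mediation_scan")
  expect_equal(classify_mediators(scan, "bh"), "g1")      # g2 fails |b|<|C|
  expect_equal(classify_mediators(scan, "permutation"), "g1")
  expect_equal(classify_mediators(scan, "bh", strict_path_A = TRUE), "g1")
  scan$features$q_B <- 1
  expect_length(classify_mediators(scan, "bh"), 0)
})

test_that("overlap summary obeys set identities", {
  mk <- function(trait, sigA, sigB, att, ids = paste0("f", 1:10)) {
    f <- data.frame(feature_id = ids, p_A = 1, q_A = 1, beta_mediatorB = 1,
                    beta_treatmentB = 10, p_B = 1, q_B = 1, aliased = FALSE)
    f$q_A[match(sigA, ids)] <- 0.01
    f$q_B[match(sigB, ids)] <- 0.01
    f$beta_treatmentB[match(att, ids)] <- 0.1
    structure(list(trait = trait, features = f, beta_treatmentC = 1,
                   p_C = 0.01, permutation_threshold_A = NA,
                   permutation_threshold_B = NA, alpha = 0.05),
              class = "mediation_scan")
  }
  s1 <- mk("yield", sigA = c("f1", "f2", "f3"), sigB = c("f2", "f3", "f4"),
           att = c("f2", "f3", "f4"))
  s2 <- mk("protein", sigA = "f9", sigB = "f9", att = "f9")
  ov <- overlap_summary(list(yield = s1, protein = s2))
  w <- ov$within_trait[ov$within_trait$trait == "yield", ]
  expect_equal(w$n_A, 3); expect_equal(w$n_B, 3)
  expect_equal(w$n_A_B, 2)
  # inclusion-exclusion: |A u B| = |A| + |B| - |A n B|
  expect_equal(length(union(ov$sets$yield$significant_A,
                            ov$sets$yield$significant_B)),
               w$n_A + w$n_B - w$n_A_B)
  expect_equal(ov$cross_trait["yield", "protein"], 0L)
  expect_equal(ov$cross_trait["yield", "yield"], w$n_attenuated)
  # mediators always a subset of the significant-B set
  expect_true(all(ov$sets$yield$attenuated %in% ov$sets$yield$significant_B))
})

test_that("the two-mediator path refuses clearly", {
  expect_error(two_mediator_path(), "not implemented")
})
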