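test_that("genotype simulation hits its LD target on the latent scale", {
  # independence limit
  g0 <- simulate_genotypes(5000, rep(0.3, 6), ld_rho = 0, seed = 11)
  r <- cor(g0$dosages)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # ld_rho = 0.9: invert the realized adjacent-pair haplotype correlation
  # back to the Gaussian scale via the thresholded-bivariate-normal oracle
  g <- simulate_genotypes(5000, rep(0.3, 10), ld_rho = 0.9, seed = 12)
  set.seed(12)
  n_hap <- 2 * 5000
  # reconstruct haplotype alleles exactly as the generator draws them
  z <- matrix(0, n_hap, 10)
  z[, 1] <- rnorm(n_hap)
  s <- sqrt(1 - 0.9^2)
  for (k in 2:10) z[, k] <- 0.9 * z[, k - 1] + s * rnorm(n_hap)
  hap <- (z < qnorm(0.3)) * 1
  r_bin <- mean(vapply(1:9, function(k) cor(hap[, k], hap[, k + 1]),
                       numeric(1)))
  rho_hat <- latent_corr_from_binary(r_bin, 0.3)
  expect_gt(rho_hat, 0.85)
  expect_lt(rho_hat, 0.95)

  # sample allele frequency tracks the target MAF
  expect_lt(max(abs(g$variants$eaf - 0.3)), 0.05)
})

test_that("genotype simulation is deterministic in its seed", {
  g1 <- simulate_genotypes(200, rep(0.2, 5), 0.5, seed = 99)
  g2 <- simulate_genotypes(200, rep(0.2, 5), 0.5, seed = 99)
  expect_identical(g1$dosages, g2$dosages)
})

test_that("trait simulation encodes the configured causal architecture", {
  # null effect: outcome uncorrelated with the causal variant
  cfg0 <- scenario_config("shared", theta = 0, n_exposure = 5000,
                          m_variants = 20, seed = 3)
  g <- simulate_genotypes(5000, cfg0$maf, cfg0$ld_rho, seed = 3)
  tr0 <- simulate_traits(g, cfg0, seed = 4)
  gc <- g$dosages[, tr0$truth$exposure_causal_idx[1]]
  expect_lt(abs(cor(tr0$outcome, gc)), 2 / sqrt(5000))

  # theta = 0.3 recovered by OLS of Y on X on the simulated individuals
  cfg <- scenario_config("shared", theta = 0.3, var_explained_cis = 0.1,
                         n_exposure = 10000, m_variants = 20, seed = 5)
  g2 <- simulate_genotypes(10000, cfg$maf, cfg$ld_rho, seed = 5)
  tr <- simulate_traits(g2, cfg, seed = 6)
  ols <- unname(coef(lm(tr$outcome ~ tr$exposure))[2])
  expect_lt(abs(ols - 0.3), 0.03)

  # exposure is standardized and explains the configured cis variance
  expect_equal(var(tr$exposure), 1, tolerance = 1e-9)
  r2 <- summary(lm(tr$exposure ~
                     g2$dosages[, tr$truth$exposure_causal_idx]))$r.squared
  expect_lt(abs(r2 - 0.1), 0.02)

  # distinct scenario: outcome causal variant differs from the exposure's
  cfgd <- scenario_config("distinct", n_exposure = 2000, m_variants = 20,
                          seed = 7)
  trd <- simulate_traits(g2, cfgd, seed = 7)
  expect_false(trd$truth$outcome_direct_causal_idx %in%
                 trd$truth$exposure_causal_idx)
})

test_that("null_assoc p-values are uniform across SNPs", {
  cfg <- scenario_config("null_assoc", n_exposure = 2000, m_variants = 200,
                         ld_rho = 0, seed = 21)
  g <- simulate_genotypes(2000, cfg$maf, 0, seed = 21)
  tr <- simulate_traits(g, cfg, seed = 22)
  ss <- compute_sumstats(g, tr$outcome, "y")
  ks <- suppressWarnings(ks.test(ss$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("marginal regression summary statistics match their definition", {
  g <- simulate_genotypes(500, rep(0.3, 4), 0.2, seed = 31)
  # exact linear relation: beta = 2, p at the underflow guard
  y <- 2 * g$dosages[, 2]
  ss <- compute_sumstats(g, y, "t")
  expect_equal(ss$beta[ss$variant_id == "rs00002"], 2, tolerance = 1e-12)
  expect_equal(min(ss$pvalue), .Machine$double.xmin)

  # agreement with lm() per variant on noisy data
  set.seed(32)
  y2 <- 0.3 * g$dosages[, 1] + rnorm(500)
  ss2 <- compute_sumstats(g, y2, "t")
  for (j in 1:4) {
    fit <- summary(lm(y2 ~ g$dosages[, j]))$coefficients
    expect_equal(ss2$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(ss2$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(ss2$pvalue[j], fit[2, 4], tolerance = 1e-10)
  }

  # duplicated dosage column gives identical statistics
  gd <- g
  gd$dosages <- cbind(g$dosages, g$dosages[, 1])
  colnames(gd$dosages)[5] <- "rs_dup"
  gd$variants <- dplyr::bind_rows(
    g$variants,
    dplyr::mutate(g$variants[1, ], variant_id = "rs_dup", pos = 999999L))
  ss3 <- compute_sumstats(gd, y2, "t")
  expect_equal(ss3$beta[ss3$variant_id == "rs_dup"],
               ss3$beta[ss3$variant_id == "rs00001"])
  expect_equal(ss3$se[ss3$variant_id == "rs_dup"],
               ss3$se[ss3$variant_id == "rs00001"])
})

test_that("type-I error of the marginal scan is calibrated", {
  g <- simulate_genotypes(5000, rep(0.3, 200), 0, seed = 41)
  set.seed(42)
  y <- rnorm(5000)
  ss <- compute_sumstats(g, y, "null")
  frac <- mean(ss$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("case-control simulation calibrates its intercept and effect", {
  g <- simulate_genotypes(5000, rep(0.3, 2), 0, seed = 51)
  y <- simulate_case_control(g, 1, log_or = 0, prevalence = 0.5, seed = 52)
  expect_gte(mean(y), 0.47)
  expect_lte(mean(y), 0.53)

  # OR recovery at the PheWAS effect scale
  gbig <- simulate_genotypes(200000, 0.3, 0, seed = 53, m = 1)
  ybig <- simulate_case_control(gbig, 1, log_or = log(1.13),
                                prevalence = 0.05, seed = 54)
  fit <- logistic_assoc(gbig$dosages[, 1], ybig)
  expect_gte(exp(fit$log_or), 1.08)
  expect_lte(exp(fit$log_or), 1.18)

  expect_error(simulate_case_control(g, 1, log_or = 0, prevalence = 1e-9,
                                     seed = 55),
               class = "csfmr_degenerate_phenotype")
})

test_that("scenario artifacts are mutually consistent and reproducible", {
  cfg <- scenario_config("shared", n_exposure = 300, n_outcome = 400,
                         m_variants = 12, seed = 61)
  sc1 <- simulate_scenario(cfg)
  sc2 <- simulate_scenario(cfg)
  expect_identical(sc1$exposure_sumstats$beta, sc2$exposure_sumstats$beta)
  expect_identical(sc1$outcome_sumstats$pvalue, sc2$outcome_sumstats$pvalue)
  expect_identical(rownames(sc1$ld), sc1$exposure_sumstats$variant_id)
  expect_true(all(sc1$exposure_sumstats$pos >= sc1$region$start &
                    sc1$exposure_sumstats$pos <= sc1$region$end))

  # identical seeds give byte-identical summary-statistics files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_sumstats(sc1$exposure_sumstats, f1)
  write_sumstats(sc2$exposure_sumstats, f2)
  expect_identical(readLines(f1), readLines(f2))
})
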