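test_that("Wald ratio matches its defining arithmetic", {
  e <- wald_ratio(toy_pair(beta_exp = 0.5, beta_out = 0.115, se_out = 0.05))
  expect_equal(e$theta, 0.23, tolerance = 1e-12)
  expect_equal(e$se, 0.10, tolerance = 1e-12)
  expect_equal(e$ci_low, 0.23 - 1.959964 * 0.10, tolerance = 1e-9)

  # null outcome effect: theta 0, p 1
  e0 <- wald_ratio(toy_pair(beta_out = 0))
  expect_equal(e0$theta, 0)
  expect_equal(e0$pvalue, 1)

  # sign symmetry in the exposure effect
  en <- wald_ratio(toy_pair(beta_exp = -0.5, beta_out = 0.115,
                            se_out = 0.05))
  expect_equal(en$theta, -0.23, tolerance = 1e-12)
  expect_equal(en$se, 0.10, tolerance = 1e-12)

  expect_error(wald_ratio(toy_pair(beta_exp = 0)),
               class = "csfmr_domain_error")
})

test_that("IVW reproduces the two-instrument worked example exactly", {
  pairs <- pairs_from_ratios(c(0.2, 0.4), c(0.1, 0.2))
  e <- mr_ivw(pairs)
  expect_equal(e$theta, 0.24, tolerance = 1e-9)
  expect_equal(e$se, 1 / sqrt(125), tolerance = 1e-9)  # 0.08944; Q < k-1
  expect_equal(e$Q, 0.8, tolerance = 1e-9)
  expect_equal(e$I2, 0, tolerance = 1e-9)
  expect_equal(e$pvalue, 2 * pnorm(-0.24 * sqrt(125)), tolerance = 1e-9)
})

test_that("IVW agrees with a numerical weighted-least-squares oracle", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:12, 1)
    ratios <- rnorm(k, 0.2, 0.3)
    ses <- runif(k, 0.02, 0.5)
    e <- mr_ivw(pairs_from_ratios(ratios, ses))
    expect_equal(e$theta, oracle_ivw_theta(ratios, ses), tolerance = 1e-7)
    w <- 1 / ses^2
    Q <- sum(w * (ratios - e$theta)^2)
    expect_equal(e$Q, Q, tolerance = 1e-7)
    expect_gte(e$I2, 0); expect_lte(e$I2, 100)
    expect_equal(e$se, max(1, sqrt(Q / (k - 1))) / sqrt(sum(w)),
                 tolerance = 1e-7)
    # Q and theta invariant to instrument ordering
    perm <- sample.int(k)
    e2 <- mr_ivw(pairs_from_ratios(ratios[perm], ses[perm]))
    expect_equal(e2$theta, e$theta, tolerance = 1e-12)
    expect_equal(e2$Q, e$Q, tolerance = 1e-10)
  }
})

test_that("degenerate IVW inputs behave as documented", {
  # duplicated identical pair: theta equals the single-pair Wald, Q = 0
  p <- toy_pair()
  dup <- dplyr::bind_rows(p, p)
  e <- mr_ivw(dup)
  expect_equal(e$theta, wald_ratio(p)$theta, tolerance = 1e-12)
  expect_equal(e$Q, 0, tolerance = 1e-12)
  expect_equal(e$I2, 0)

  # three identical ratios: no heterogeneity whatever the ses
  e3 <- mr_ivw(pairs_from_ratios(c(0.2, 0.2, 0.2), c(0.1, 0.3, 0.5)))
  expect_equal(e3$Q, 0, tolerance = 1e-12)
  expect_equal(e3$I2, 0)

  expect_error(mr_ivw(toy_pair()), class = "csfmr_domain_error")
})

test_that("weighted median interpolates the precision-weighted order", {
  # equal weights, symmetric estimates: the middle value
  e <- mr_weighted_median(pairs_from_ratios(c(0.1, 0.2, 0.3),
                                            c(0.1, 0.1, 0.1)),
                          n_boot = 200, seed = 1)
  expect_equal(e$theta, 0.2, tolerance = 1e-9)

  # weight concentrated on the smallest estimate pulls theta below 0.2
  ses <- 1 / sqrt(c(100, 1, 1))
  e2 <- mr_weighted_median(pairs_from_ratios(c(0.1, 0.2, 0.3), ses),
                           n_boot = 200, seed = 1)
  expect_lt(e2$theta, 0.2)
  expect_gt(e2$theta, 0.09)

  # brute-force oracle agreement on random inputs
  set.seed(5)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    b <- rnorm(k); s <- runif(k, 0.05, 0.5)
    e3 <- mr_weighted_median(pairs_from_ratios(b, s), n_boot = 50, seed = 2)
    expect_equal(e3$theta, oracle_weighted_median(b, 1 / s^2),
                 tolerance = 1e-9)
  }

  # seeded bootstrap is reproducible
  p <- pairs_from_ratios(c(0.1, 0.25, 0.3), c(0.1, 0.2, 0.15))
  expect_identical(mr_weighted_median(p, 500, seed = 7)$se,
                   mr_weighted_median(p, 500, seed = 7)$se)
  expect_error(mr_weighted_median(pairs_from_ratios(c(0.1, 0.2),
                                                    c(0.1, 0.1))),
               class = "csfmr_not_applicable")
})

test_that("weighted median resists corruption below half the weight", {
  valid <- pairs_from_ratios(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1))
  for (n_bad in 1:2) {
    bad <- pairs_from_ratios(rep(1.5, n_bad), rep(0.1, n_bad))
    bad$variant_id <- paste0("bad", seq_len(n_bad))
    e <- mr_weighted_median(dplyr::bind_rows(valid, bad), n_boot = 100,
                            seed = 3)
    expect_gte(e$theta, 0.25)
    expect_lte(e$theta, 0.35)
  }
})

test_that("BH step-up matches the brute-force definition", {
  fdr <- bh_fdr(c(0.001, 0.01, 0.02, 0.8), alpha = 0.05)
  expect_equal(sum(fdr$significant), 3)

  all1 <- bh_fdr(rep(1, 5))
  expect_false(any(all1$significant))
  expect_true(all(all1$qvalue == 1))

  single <- bh_fdr(0.04)
  expect_true(single$significant)
  expect_equal(single$qvalue, 0.04)

  expect_equal(nrow(bh_fdr(numeric(0))), 0)

  set.seed(13)
  for (rep in 1:25) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- bh_fdr(p, alpha = 0.05)
    want <- oracle_bh(p, alpha = 0.05)
    expect_equal(got$qvalue, want$qvalue, tolerance = 1e-12)
    expect_identical(got$significant, want$significant)
    expect_true(all(got$qvalue >= p - 1e-15))
    # q-values are monotone in p
    ord <- order(p)
    expect_true(all(diff(got$qvalue[ord]) >= -1e-15))
  }
})

test_that("mr_fit dispatches methods by instrument count", {
  f1 <- mr_fit(toy_pair())
  expect_equal(tidy(f1)$method, "wald")

  f2 <- mr_fit(pairs_from_ratios(c(0.2, 0.4), c(0.1, 0.2)))
  expect_equal(tidy(f2)$method, "ivw_re")

  f3 <- mr_fit(pairs_from_ratios(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1)),
               n_boot = 100, seed = 1)
  expect_setequal(tidy(f3)$method, c("ivw_re", "weighted_median"))
  expect_equal(glance(f3)$method, "ivw_re")
  expect_s3_class(ggplot2::autoplot(f3), "ggplot")
  expect_error(mr_fit(toy_pair()[0, ]), class = "csfmr_no_instruments")
})
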