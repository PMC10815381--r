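out_rec <- function(ea, oa, beta = -0.10, eaf = 0.7, se = 0.02) {
  tibble::tibble(variant_id = "rs001", effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se)
}
exp_rec <- function(ea = "A", oa = "G", beta = 0.30, eaf = 0.3, se = 0.05) {
  tibble::tibble(variant_id = "rs001", effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se)
}

test_that("allele alignment handles swaps, strand flips and palindromes", {
  # swapped labels: outcome beta sign-flips, eaf reflects
  h <- harmonize_pair(exp_rec(), out_rec("G", "A", beta = -0.10, eaf = 0.7))
  expect_equal(h$action, "flipped_outcome")
  expect_equal(h$beta_out, 0.10)
  expect_equal(h$eaf_out, 0.3)

  # identical labels: kept untouched
  h2 <- harmonize_pair(exp_rec(), out_rec("A", "G", beta = 0.1, eaf = 0.3))
  expect_equal(h2$action, "kept")
  expect_equal(h2$beta_out, 0.1)

  # strand flip, same orientation: A/G vs T/C kept with unchanged beta
  h3 <- harmonize_pair(exp_rec(), out_rec("T", "C", beta = 0.1, eaf = 0.3))
  expect_equal(h3$action, "kept")
  expect_equal(h3$beta_out, 0.1)

  # strand flip with swapped labels: complement then flip
  h4 <- harmonize_pair(exp_rec(), out_rec("C", "T", beta = 0.1, eaf = 0.7))
  expect_equal(h4$action, "flipped_outcome")
  expect_equal(h4$beta_out, -0.1)

  # ambiguous palindrome at eaf 0.5 dropped
  h5 <- harmonize_pair(exp_rec("A", "T", eaf = 0.5),
                       out_rec("A", "T", eaf = 0.5))
  expect_equal(h5$action, "dropped_palindromic")

  # palindrome with informative, concordant frequencies kept
  h6 <- harmonize_pair(exp_rec("A", "T", eaf = 0.2),
                       out_rec("A", "T", beta = 0.1, eaf = 0.25))
  expect_equal(h6$action, "kept")
  expect_equal(h6$beta_out, 0.1)

  # palindrome with discordant frequencies: opposite strand, flip
  h7 <- harmonize_pair(exp_rec("A", "T", eaf = 0.2),
                       out_rec("A", "T", beta = 0.1, eaf = 0.8))
  expect_equal(h7$action, "flipped_outcome")
  expect_equal(h7$beta_out, -0.1)

  # palindrome with a missing frequency dropped (conservative)
  h8 <- harmonize_pair(exp_rec("C", "G", eaf = 0.2),
                       out_rec("C", "G", eaf = NA))
  expect_equal(h8$action, "dropped_palindromic")

  # irreconcilable alleles dropped as mismatch
  h9 <- harmonize_pair(exp_rec("A", "G"), out_rec("A", "C"))
  expect_equal(h9$action, "dropped_mismatch")

  # indel alleles align by identity/swap but are never complemented
  h10 <- harmonize_pair(exp_rec("AT", "A"), out_rec("A", "AT", beta = 0.1))
  expect_equal(h10$action, "flipped_outcome")
  expect_equal(h10$beta_out, -0.1)
})

random_pair <- function() {
  alleles <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("A", "T"),
                  c("C", "G"))
  al <- alleles[[sample.int(5, 1)]]
  if (runif(1) < 0.5) al <- rev(al)
  f1 <- runif(1, 0.05, 0.95)
  exp <- exp_rec(al[1], al[2], beta = rnorm(1), eaf = f1)
  # outcome reported either as-is, label-swapped, strand-flipped, or both
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  oal <- al
  if (runif(1) < 0.5) oal <- unname(comp[oal])
  f2 <- max(0.01, min(0.99, f1 + rnorm(1, 0, 0.03)))
  swap <- runif(1) < 0.5
  if (swap) {
    out <- out_rec(oal[2], oal[1], beta = rnorm(1), eaf = 1 - f2)
  } else {
    out <- out_rec(oal[1], oal[2], beta = rnorm(1), eaf = f2)
  }
  list(exp = exp, out = out)
}

test_that("harmonization is idempotent and label-flip symmetric", {
  set.seed(2024)
  for (i in 1:200) {
    pr <- random_pair()
    h <- harmonize_pair(pr$exp, pr$out)
    if (h$action %in% c("kept", "flipped_outcome")) {
      # idempotence: feeding the aligned pair back changes nothing
      again <- harmonize_pair(
        pr$exp,
        tibble::tibble(variant_id = h$variant_id,
                       effect_allele = h$effect_allele,
                       other_allele = h$other_allele,
                       eaf = h$eaf_out, beta = h$beta_out, se = h$se_out))
      expect_equal(again$action, "kept")
      expect_equal(again$beta_out, h$beta_out)
      expect_equal(again$eaf_out, h$eaf_out)
    }
    # relabelling the outcome's effect allele never changes the result
    flipped <- pr$out
    flipped$effect_allele <- pr$out$other_allele
    flipped$other_allele <- pr$out$effect_allele
    flipped$beta <- -pr$out$beta
    flipped$eaf <- 1 - pr$out$eaf
    h2 <- harmonize_pair(pr$exp, flipped)
    if (h$action %in% c("kept", "flipped_outcome")) {
      expect_equal(h2$beta_out, h$beta_out)
      expect_equal(h2$beta_exp, h$beta_exp)
      expect_equal(h2$eaf_out, h$eaf_out)
    } else {
      expect_match(h2$action, "^dropped")
    }
  }
})

test_that("harmonize_set audits every action and tolerates empties", {
  instruments <- as_sumstats(toy_sumstats_df(3), "prot")
  outcome <- as_sumstats(toy_sumstats_df(3), "out")
  h <- harmonize_set(instruments, outcome)
  expect_equal(nrow(h), 3)
  expect_true(all(h$action == "kept"))

  # one palindromic instrument with missing outcome eaf: dropped
  inst2 <- toy_sumstats_df(2)
  inst2$effect_allele <- c("A", "A")
  inst2$other_allele <- c("G", "T")
  out2 <- inst2
  out2$eaf <- c(0.3, NA)
  h2 <- harmonize_set(as_sumstats(inst2, "p"), as_sumstats(out2, "o"))
  expect_equal(nrow(h2), 1)
  expect_equal(nrow(attr(h2, "audit")), 2)
  expect_equal(sum(attr(h2, "audit")$action == "dropped_palindromic"), 1)

  empty <- harmonize_set(instruments[0, ], outcome)
  expect_equal(nrow(empty), 0)
})
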