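# Small in-code fixtures shared across test files.

toy_sumstats_df <- function(n = 5, chrom = "11", pos_start = 1000L,
                            p = NULL) {
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = pos_start + (seq_len(n) - 1L) * 100L,
    effect_allele = "A",
    other_allele = "G",
    eaf = seq(0.1, 0.4, length.out = n),
    beta = seq(0.1, 0.5, length.out = n),
    se = rep(0.05, n),
    pvalue = if (is.null(p)) rep(1e-10, n) else p,
    n = 835
  )
}

toy_ld <- function(ids, r = NULL) {
  m <- diag(length(ids))
  if (!is.null(r)) {
    for (k in seq_len(nrow(r))) {
      m[r[k, 1], r[k, 2]] <- r[k, 3]
      m[r[k, 2], r[k, 1]] <- r[k, 3]
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

toy_pair <- function(variant_id = "rs001", ea = "A", oa = "G",
                     beta_exp = 0.5, se_exp = 0.05, eaf_exp = 0.3,
                     beta_out = 0.115, se_out = 0.05, eaf_out = 0.3) {
  tibble::tibble(variant_id = variant_id, effect_allele = ea,
                 other_allele = oa, beta_exp = beta_exp, se_exp = se_exp,
                 eaf_exp = eaf_exp, beta_out = beta_out, se_out = se_out,
                 eaf_out = eaf_out, action = "kept")
}

# harmonized set built directly from per-variant ratio targets
pairs_from_ratios <- function(ratios, ratio_ses, beta_exp = 1) {
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_along(ratios)),
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = 1e-6, eaf_exp = 0.3,
    beta_out = ratios * beta_exp, se_out = ratio_ses * abs(beta_exp),
    eaf_out = 0.3, action = "kept"
  )
}

# regional summary stats with prescribed z-scores for coloc tests
region_from_z <- function(z, se = 0.1, prefix = "rs") {
  tibble::tibble(
    variant_id = sprintf("%s%03d", prefix, seq_along(z)),
    beta = z * se, se = se
  )
}

run_shared_pipeline <- function(seed, n_exposure = 20000, n_outcome = 20000,
                                theta = 0.3, n_causal = 3,
                                var_explained_cis = 0.3, m = 30,
                                ld_rho = 0.6) {
  cfg <- scenario_config("shared", n_exposure = n_exposure,
                         n_outcome = n_outcome, m_variants = m,
                         ld_rho = ld_rho, theta = theta,
                         var_explained_cis = var_explained_cis,
                         n_causal = n_causal, seed = seed)
  sc <- simulate_scenario(cfg)
  ins <- select_instruments(sc$exposure_sumstats, sc$region,
                            sc$outcome_sumstats, sc$ld)
  h <- harmonize_set(ins, sc$outcome_sumstats)
  est <- if (nrow(h) >= 2) mr_ivw(h) else wald_ratio(h)
  list(estimate = est, scenario = sc, n_instruments = nrow(h))
}

coloc_from_scenario <- function(scenario, seed, n_outcome = 10000,
                                theta = 0.3, m = 60, ld_rho = 0.9) {
  cfg <- scenario_config(scenario, n_outcome = n_outcome, m_variants = m,
                         ld_rho = ld_rho, theta = theta, seed = seed)
  sc <- simulate_scenario(cfg)
  shared_ids <- intersect(sc$exposure_sumstats$variant_id,
                          sc$outcome_sumstats$variant_id)
  t1 <- sc$exposure_sumstats[match(shared_ids,
                                   sc$exposure_sumstats$variant_id), ]
  t2 <- sc$outcome_sumstats[match(shared_ids,
                                  sc$outcome_sumstats$variant_id), ]
  list(fit = coloc_abf(t1, t2), truth = sc$truth)
}
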