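# Synthetic two-sample GWAS generator. Haplotypes follow an AR(1) Gaussian
# copula thresholded at each variant's MAF, which gives a one-parameter
# control over pairwise LD -- the only LD feature clumping and single-causal
# colocalization are sensitive to. Exposure and outcome cohorts are always
# drawn independently (no sample overlap, as two-sample MR assumes).

#' Scenario configuration for the synthetic generator
#'
#' Defaults mirror the study conditions the pipeline is designed for: a CSF
#' protein GWAS of 835 individuals instrumenting a protein whose cis variant
#' explains 10% of its variance, and a much larger outcome GWAS.
#'
#' @param scenario One of `"shared"` (outcome genetic signal flows only
#'   through the exposure's causal variant(s)), `"distinct"` (the outcome has
#'   its own causal variant in LD with, but different from, the exposure's),
#'   `"null_protein_effect"` (the protein has cis signal but no effect on the
#'   outcome) or `"null_assoc"` (neither trait has any genetic signal).
#' @param n_exposure,n_outcome Cohort sizes for the exposure and outcome
#'   GWAS (non-overlapping draws).
#' @param m_variants Number of variants in the cis region panel.
#' @param maf Minor-allele frequency, scalar or length-`m_variants` vector in
#'   (0, 0.5].
#' @param ld_rho AR(1) adjacent-haplotype correlation on the latent Gaussian
#'   scale, in \[0, 1).
#' @param theta Causal effect of the exposure on the outcome (SD outcome per
#'   1 log-RFU exposure). Default 0.23, the scale of a strong protein
#'   effect on cognition.
#' @param var_explained_cis Fraction of exposure variance explained by its
#'   causal cis variant(s) jointly, in (0, 1).
#' @param n_causal Number of causal cis variants for the exposure (split
#'   `var_explained_cis` equally; variants are spaced across the panel so
#'   they are mutually in low LD).
#' @param var_explained_direct In `scenario = "distinct"`, the fraction of
#'   outcome variance explained directly by the outcome's own causal variant.
#' @param seed Integer seed; every random draw derives from it.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("shared", "distinct",
                                         "null_protein_effect", "null_assoc"),
                            n_exposure = 835, n_outcome = 10000,
                            m_variants = 60, maf = 0.3, ld_rho = 0.9,
                            theta = 0.23, var_explained_cis = 0.1,
                            n_causal = 1, var_explained_direct = 0.01,
                            seed = 1) {
  scenario <- match.arg(scenario)
  maf <- rep_len(maf, m_variants)
  stopifnot(all(maf > 0 & maf <= 0.5), ld_rho >= 0, ld_rho < 1,
            var_explained_cis > 0, var_explained_cis < 1,
            n_causal >= 1, n_exposure >= 2, n_outcome >= 2)
  if (scenario == "distinct" && m_variants < 2) {
    abort("scenario 'distinct' needs at least 2 variants",
          class = "csfmr_config_error")
  }
  structure(list(scenario = scenario, n_exposure = n_exposure,
                 n_outcome = n_outcome, m_variants = m_variants, maf = maf,
                 ld_rho = ld_rho, theta = theta,
                 var_explained_cis = var_explained_cis, n_causal = n_causal,
                 var_explained_direct = var_explained_direct,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate LD-structured genotype dosages
#'
#' Each haplotype is a zero-mean AR(1) Gaussian vector across variants,
#' thresholded at `qnorm(maf)` to yield an allele; two haplotypes per
#' individual are summed into a 0/1/2 dosage. Adjacent variants' latent
#' haplotype correlation converges to `ld_rho` as n grows.
#'
#' @param n Number of individuals.
#' @param maf MAF vector (recycled to `m`).
#' @param ld_rho AR(1) latent correlation in \[0, 1).
#' @param seed Integer seed.
#' @param m Number of variants (defaults to `length(maf)`).
#' @param chrom,pos_start,pos_step Variant panel coordinates: variants are
#'   placed at `pos_start + (0:(m-1)) * pos_step` on `chrom`.
#'
#' @return A list of class `csf_genotypes`: `dosages` (n x m integer
#'   matrix), `variants` (tibble of variant records with sample `eaf`),
#'   `maf`, `ld_rho`.
#' @export
simulate_genotypes <- function(n, maf, ld_rho, seed, m = length(maf),
                               chrom = "11", pos_start = 1e6L,
                               pos_step = 5000L, id_prefix = "rs") {
  maf <- rep_len(maf, m)
  set.seed(seed)
  n_hap <- 2L * n
  z <- matrix(0, n_hap, m)
  z[, 1] <- rnorm(n_hap)
  if (m > 1) {
    s <- sqrt(1 - ld_rho^2)
    for (k in 2:m) z[, k] <- ld_rho * z[, k - 1] + s * rnorm(n_hap)
  }
  thresh <- qnorm(maf)
  alleles <- sweep(z, 2, thresh, "<") * 1L
  dosages <- alleles[seq_len(n), , drop = FALSE] +
    alleles[n + seq_len(n), , drop = FALSE]
  ids <- sprintf("%s%05d", id_prefix, seq_len(m))
  colnames(dosages) <- ids
  variants <- tibble::tibble(
    variant_id = ids,
    chrom = chrom,
    pos = as.integer(pos_start + (seq_len(m) - 1L) * pos_step),
    effect_allele = "A", other_allele = "G",
    eaf = colMeans(dosages) / 2
  )
  structure(list(dosages = dosages, variants = variants, maf = maf,
                 ld_rho = ld_rho),
            class = "csf_genotypes")
}

causal_indices <- function(m, n_causal) {
  # evenly spaced across the panel so AR(1) decay keeps them near-independent
  unique(round(seq(1, m, length.out = n_causal + 2)))[2:(n_causal + 1)]
}

#' Simulate exposure and outcome phenotypes on one genotype cohort
#'
#' The exposure X carries genetic signal at the causal cis variant(s) and is
#' standardized to zero mean / unit variance; the outcome Y depends on the
#' scenario (see [scenario_config()]). Calling this on two independently
#' drawn genotype tables (one per cohort) yields the two-sample structure:
#' the exposure GWAS uses X from one cohort, the outcome GWAS uses Y from the
#' other.
#'
#' @param g A `csf_genotypes` object.
#' @param cfg A `scenario_config`.
#' @param seed Integer seed for the environmental noise draws.
#'
#' @return A list: `exposure` (numeric vector), `outcome` (numeric vector),
#'   `truth` (list of class `scenario_truth` with `theta_true`,
#'   `exposure_causal_idx`, `outcome_direct_causal_idx`, `scenario`,
#'   `causal_r` -- the realized dosage correlation between the exposure and
#'   direct-outcome causal variants in `scenario = "distinct"`).
#' @export
simulate_traits <- function(g, cfg, seed = cfg$seed) {
  stopifnot(inherits(g, "csf_genotypes"), inherits(cfg, "scenario_config"))
  set.seed(seed)
  n <- nrow(g$dosages)
  m <- ncol(g$dosages)
  has_cis <- cfg$scenario != "null_assoc"
  idx_exp <- causal_indices(m, cfg$n_causal)
  v_each <- cfg$var_explained_cis / length(idx_exp)
  if (has_cis) {
    gc <- g$dosages[, idx_exp, drop = FALSE]
    a <- sqrt(v_each / pmax(apply(gc, 2, var), 1e-12))
    x <- drop(gc %*% a) + rnorm(n, sd = sqrt(1 - cfg$var_explained_cis))
  } else {
    x <- rnorm(n)
  }
  x <- as.numeric(scale(x))

  idx_out <- NA_integer_
  causal_r <- NA_real_
  theta_true <- 0
  if (cfg$scenario == "shared") {
    theta_true <- cfg$theta
    y <- cfg$theta * x + rnorm(n)
  } else if (cfg$scenario == "distinct") {
    # outcome causal variant: the panel position farthest (in LD) from the
    # exposure causal set, i.e. max index distance
    idx_out <- which.max(vapply(seq_len(m),
                                function(j) min(abs(j - idx_exp)), numeric(1)))
    gd <- g$dosages[, idx_out]
    b <- sqrt(cfg$var_explained_direct / max(var(gd), 1e-12))
    y <- b * (gd - mean(gd)) + rnorm(n, sd = sqrt(1 - cfg$var_explained_direct))
    causal_r <- cor(g$dosages[, idx_exp[1]], gd)
  } else {
    y <- rnorm(n)
  }
  truth <- structure(list(theta_true = theta_true,
                          exposure_causal_idx = if (has_cis) idx_exp else NA,
                          outcome_direct_causal_idx = idx_out,
                          causal_r = causal_r,
                          scenario = cfg$scenario),
                     class = "scenario_truth")
  list(exposure = x, outcome = y, truth = truth)
}

#' Per-variant marginal GWAS summary statistics
#'
#' Simple linear regression of the phenotype on each dosage column: beta =
#' cov(y, g) / var(g), residual-based standard error, p from a t distribution
#' on n - 2 df. Monomorphic variants get beta 0 and infinite SE (they are
#' then dropped by [as_sumstats()] validation on the read side).
#'
#' @param g A `csf_genotypes` object.
#' @param y Phenotype vector, one value per row of `g$dosages`.
#' @param trait_id Trait name.
#' @param trait_type Passed through to [as_sumstats()].
#' @return A `csf_sumstats` tibble (monomorphic variants excluded).
#' @export
compute_sumstats <- function(g, y, trait_id, trait_type = "quantitative") {
  d <- g$dosages
  n <- nrow(d)
  stopifnot(length(y) == n)
  gm <- colMeans(d)
  yc <- y - mean(y)
  sxy <- drop(crossprod(d, yc)) / (n - 1)
  sxx <- (colSums(d^2) - n * gm^2) / (n - 1)
  syy <- sum(yc^2) / (n - 1)
  mono <- sxx <= 0
  beta <- ifelse(mono, 0, sxy / sxx)
  rss <- pmax((n - 1) * (syy - beta * sxy), 0)
  # exact linear relations give rss = 0; floor the SE at the smallest
  # positive normal so the record survives validation with p at its guard
  se <- ifelse(mono, Inf,
               pmax(sqrt(rss / (n - 2) / ((n - 1) * sxx)),
                    .Machine$double.xmin))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - 2)
  pval <- pmax(pval, .Machine$double.xmin)
  out <- g$variants
  out$eaf <- gm / 2
  out$beta <- beta
  out$se <- se
  out$pvalue <- pval
  out$n <- n
  as_sumstats(out, trait_id = trait_id, trait_type = trait_type)
}

#' Simulate a binary phenotype from a logistic model
#'
#' Case status is Bernoulli with logit = intercept + `log_or` * dosage +
#' covariate effects; the intercept is solved numerically so that the
#' expected prevalence matches `prevalence`.
#'
#' @param g A `csf_genotypes` object.
#' @param variant_idx Column index of the causal variant.
#' @param log_or Per-allele log odds ratio.
#' @param covariates Optional numeric matrix (n rows) of covariates.
#' @param covariate_effects Coefficients for `covariates` (recycled).
#' @param prevalence Target expected case fraction in (0, 1).
#' @param seed Integer seed.
#' @return Integer 0/1 vector of case status.
#' @export
simulate_case_control <- function(g, variant_idx, log_or, covariates = NULL,
                                  covariate_effects = 0.2, prevalence = 0.1,
                                  seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1)
  set.seed(seed)
  lp <- log_or * g$dosages[, variant_idx]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    lp <- lp + drop(covariates %*% rep_len(covariate_effects,
                                           ncol(covariates)))
  }
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - prevalence,
                c(-40, 40), tol = 1e-10)$root
  status <- rbinom(length(lp), 1, plogis(b0 + lp))
  if (all(status == 0) || all(status == 1)) {
    abort("degenerate phenotype: no cases or no controls generated",
          class = "csfmr_degenerate_phenotype")
  }
  status
}

#' Run a full two-sample scenario
#'
#' Draws independent exposure and outcome cohorts, simulates coupled
#' phenotypes under the configured causal architecture, and emits the
#' artifacts the downstream pipeline consumes: summary statistics for both
#' traits, a sample LD matrix (signed dosage correlation in the exposure
#' cohort), the gene region, and the ground truth.
#'
#' @param cfg A [scenario_config()].
#' @return A list: `exposure_sumstats`, `outcome_sumstats` (`csf_sumstats`),
#'   `ld` (signed r matrix), `region` (one-row tibble `gene_id`, `chrom`,
#'   `start`, `end`, `strand`), `truth` (`scenario_truth`),
#'   `genotypes_exposure`, `genotypes_outcome`.
#' @export
simulate_scenario <- function(cfg, chrom = "11", id_prefix = "rs",
                              gene_id = "GENE1") {
  stopifnot(inherits(cfg, "scenario_config"))
  g_exp <- simulate_genotypes(cfg$n_exposure, cfg$maf, cfg$ld_rho,
                              seed = cfg$seed, chrom = chrom,
                              id_prefix = id_prefix)
  g_out <- simulate_genotypes(cfg$n_outcome, cfg$maf, cfg$ld_rho,
                              seed = cfg$seed + 500000L, chrom = chrom,
                              id_prefix = id_prefix)
  tr_exp <- simulate_traits(g_exp, cfg, seed = cfg$seed + 1000000L)
  tr_out <- simulate_traits(g_out, cfg, seed = cfg$seed + 1500000L)
  exposure_sumstats <- compute_sumstats(g_exp, tr_exp$exposure,
                                        trait_id = gene_id)
  outcome_sumstats <- compute_sumstats(g_out, tr_out$outcome,
                                       trait_id = "outcome")
  ld <- stats::cor(g_exp$dosages)
  region <- tibble::tibble(
    gene_id = gene_id,
    chrom = g_exp$variants$chrom[1],
    start = min(g_exp$variants$pos),
    end = max(g_exp$variants$pos),
    strand = "+"
  )
  list(exposure_sumstats = exposure_sumstats,
       outcome_sumstats = outcome_sumstats,
       ld = ld, region = region, truth = tr_out$truth,
       genotypes_exposure = g_exp, genotypes_outcome = g_out)
}

#' Simulate a multi-protein screen panel
#'
#' Runs one scenario per protein, each in its own (unlinked) genomic region,
#' and assembles the artifacts [run_screen()] consumes. Per-region outcome
#' summary statistics are concatenated into a single outcome GWAS; because
#' the regions are unlinked, estimates across regions are independent.
#'
#' @param scenarios Character vector of scenario tags, one per protein.
#' @param cfg_base A [scenario_config()] providing all other settings.
#' @param seed Integer master seed; per-protein seeds derive from it.
#' @return A list: `panel` (a [screen_panel()] tibble), `outcome`
#'   (`csf_sumstats` across all regions), `truths` (named list of
#'   `scenario_truth`).
#' @export
simulate_panel <- function(scenarios, cfg_base = scenario_config(),
                           seed = cfg_base$seed) {
  stopifnot(all(scenarios %in% c("shared", "distinct", "null_protein_effect",
                                 "null_assoc")))
  n_prot <- length(scenarios)
  sims <- purrr::map(seq_len(n_prot), function(i) {
    cfg <- cfg_base
    cfg$scenario <- scenarios[i]
    cfg$seed <- as.integer((seed + i * 7919) %% .Machine$integer.max)
    simulate_scenario(cfg, chrom = as.character(i),
                      id_prefix = sprintf("rs%02d_", i),
                      gene_id = sprintf("PROT%02d", i))
  })
  outcome_all <- dplyr::bind_rows(purrr::map(sims, "outcome_sumstats"))
  outcome <- as_sumstats(outcome_all, trait_id = "outcome")
  list(
    panel = screen_panel(
      protein_id = purrr::map_chr(sims, ~ .x$region$gene_id),
      exposure = purrr::map(sims, "exposure_sumstats"),
      ld = purrr::map(sims, "ld"),
      region = purrr::map(sims, "region")
    ),
    outcome = outcome,
    truths = setNames(purrr::map(sims, "truth"),
                      purrr::map_chr(sims, ~ .x$region$gene_id))
  )
}
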