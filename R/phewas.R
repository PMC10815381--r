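# Phenome-wide scan of a single variant's dosage against many binary
# diagnoses via covariate-adjusted logistic regression, with a minimum-case
# power filter and BH-FDR control across the fitted phenotypes.

#' PheWAS configuration
#'
#' @param min_cases Minimum case count for a phenotype to enter the scan
#'   (default 200).
#' @param alpha_fdr FDR level across fitted phenotypes (default 0.05).
#' @param max_abs_logor Separation guard: fits with |log-OR| above this are
#'   flagged non-converged (default 15).
#' @return A list of class `phewas_config`.
#' @export
phewas_config <- function(min_cases = 200, alpha_fdr = 0.05,
                          max_abs_logor = 15) {
  stopifnot(min_cases >= 1, alpha_fdr > 0, alpha_fdr < 1)
  structure(list(min_cases = min_cases, alpha_fdr = alpha_fdr,
                 max_abs_logor = max_abs_logor),
            class = "phewas_config")
}

#' Covariate-adjusted logistic association of a dosage with case status
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of case status
#' on additive dosage plus covariates; Wald SE and p for the dosage
#' coefficient. Non-convergence, separation (|log-OR| > `max_abs_logor`) or
#' a constant dosage is flagged rather than raised.
#'
#' @param dosage Numeric 0/1/2 vector.
#' @param status Binary 0/1 case status with at least one case and one
#'   control.
#' @param covariates Optional numeric matrix / data frame (n rows).
#' @param max_abs_logor Separation guard threshold.
#' @return A one-row tibble: `log_or`, `se`, `pvalue`, `converged`, `reason`.
#' @export
logistic_assoc <- function(dosage, status, covariates = NULL,
                           max_abs_logor = 15) {
  stopifnot(length(dosage) == length(status),
            any(status == 1), any(status == 0))
  if (length(unique(dosage)) < 2) {
    return(tibble::tibble(log_or = NA_real_, se = NA_real_,
                          pvalue = NA_real_, converged = FALSE,
                          reason = "constant_dosage"))
  }
  dat <- data.frame(status = status, dosage = dosage)
  form <- status ~ dosage
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("dosage", names(covariates)),
                               response = "status")
  }
  fit <- suppressWarnings(
    glm(form, data = dat, family = binomial(), control = list(maxit = 100)))
  cf <- summary(fit)$coefficients
  log_or <- cf["dosage", "Estimate"]
  se <- cf["dosage", "Std. Error"]
  p <- cf["dosage", "Pr(>|z|)"]
  ok <- fit$converged && is.finite(log_or) && is.finite(se) &&
    abs(log_or) <= max_abs_logor
  reason <- if (ok) NA_character_
            else if (!fit$converged) "not_converged" else "separation"
  tibble::tibble(log_or = log_or, se = se, pvalue = p,
                 converged = ok, reason = reason)
}

#' Run a phenome-wide association scan for one variant
#'
#' Phenotypes with fewer than `min_cases` cases are skipped; the rest are
#' fitted with [logistic_assoc()]; failed fits are excluded from the FDR
#' family; BH-FDR is applied across the converged fits and rows are sorted
#' by p.
#'
#' @param dosage Numeric dosage vector (one variant).
#' @param phenotypes Data frame / matrix of binary 0/1 outcomes, one column
#'   per phenotype, rows aligned with `dosage`.
#' @param covariates Optional covariate matrix, rows aligned.
#' @param cfg A [phewas_config()].
#' @return A tibble of per-phenotype rows: `phenotype_id`, `n_cases`,
#'   `n_controls`, `odds_ratio`, `ci_low`, `ci_high`, `pvalue`, `qvalue`,
#'   `significant`, `converged`, `status` in `{fitted, skipped_min_cases,
#'   failed}`. Attribute `counts` holds the filter accounting.
#' @export
run_phewas <- function(dosage, phenotypes, covariates = NULL,
                       cfg = phewas_config()) {
  phenotypes <- as.data.frame(phenotypes)
  if (ncol(phenotypes) == 0) {
    warn("no phenotypes supplied")
  }
  rows <- purrr::map(names(phenotypes), function(ph) {
    y <- phenotypes[[ph]]
    n_cases <- sum(y == 1)
    n_controls <- sum(y == 0)
    base <- tibble::tibble(phenotype_id = ph, n_cases = n_cases,
                           n_controls = n_controls)
    if (n_cases < cfg$min_cases) {
      return(dplyr::mutate(base, odds_ratio = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, pvalue = NA_real_,
                           converged = NA, status = "skipped_min_cases"))
    }
    fit <- logistic_assoc(dosage, y, covariates,
                          max_abs_logor = cfg$max_abs_logor)
    dplyr::mutate(base,
                  odds_ratio = exp(fit$log_or),
                  ci_low = exp(fit$log_or - CI_Z * fit$se),
                  ci_high = exp(fit$log_or + CI_Z * fit$se),
                  pvalue = fit$pvalue, converged = fit$converged,
                  status = if (fit$converged) "fitted" else "failed")
  })
  out <- dplyr::bind_rows(rows)
  out$qvalue <- NA_real_
  out$significant <- NA
  fitted <- !is.na(out$status) & out$status == "fitted"
  if (any(fitted)) {
    fdr <- bh_fdr(out$pvalue[fitted], alpha = cfg$alpha_fdr)
    out$qvalue[fitted] <- fdr$qvalue
    out$significant[fitted] <- fdr$significant
  }
  if (nrow(out) > 0 && !any(fitted)) {
    warn("no phenotypes eligible for fitting")
  }
  out <- dplyr::arrange(out, !fitted, .data$pvalue)
  attr(out, "counts") <- c(total = ncol(phenotypes),
                           fitted = sum(fitted),
                           skipped = sum(out$status == "skipped_min_cases"),
                           failed = sum(out$status == "failed"))
  out
}
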