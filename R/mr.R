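# Two-sample MR estimators on harmonized summary statistics. Per-variant
# ratio estimates use the first-order delta-method SE (se_out / |beta_exp|),
# the convention for strong instruments selected at genome-wide significance.

mr_row <- function(method, nsnp, theta, se, pvalue, Q = NA_real_,
                   I2 = NA_real_) {
  tibble::tibble(method = method, nsnp = as.integer(nsnp), theta = theta,
                 se = se, ci_low = theta - CI_Z * se,
                 ci_high = theta + CI_Z * se, pvalue = pvalue, Q = Q, I2 = I2)
}

ratio_estimates <- function(pairs) {
  if (any(pairs$beta_exp == 0)) {
    abort("beta_exp = 0: Wald ratio undefined", class = "csfmr_domain_error")
  }
  tibble::tibble(variant_id = pairs$variant_id,
                 ratio = pairs$beta_out / pairs$beta_exp,
                 ratio_se = pairs$se_out / abs(pairs$beta_exp))
}

#' Wald ratio estimate from a single harmonized instrument
#'
#' theta = beta_out / beta_exp with first-order delta-method SE
#' se_out / |beta_exp|; two-sided normal p; 95% CI theta +/- 1.959964 se.
#'
#' @param pair One-row harmonized tibble (see [harmonize_set()]).
#' @return A one-row MR estimate tibble (`method`, `nsnp`, `theta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `Q`, `I2`).
#' @export
wald_ratio <- function(pair) {
  stopifnot(nrow(pair) == 1)
  r <- ratio_estimates(pair)
  p <- 2 * pnorm(-abs(r$ratio / r$ratio_se))
  mr_row("wald", 1L, r$ratio, r$ratio_se, p)
}

#' Random-effects inverse-variance-weighted estimate
#'
#' Meta-analyses per-variant ratio estimates with weights 1/se^2. Reports the
#' IVW point estimate, Cochran's Q, I-squared = max(0, (Q - (k-1))/Q) * 100,
#' and a multiplicative random-effects SE: the fixed-effect SE inflated by
#' max(1, sqrt(Q/(k-1))).
#'
#' @param pairs Harmonized tibble with at least 2 rows.
#' @return A one-row MR estimate tibble.
#' @export
mr_ivw <- function(pairs) {
  k <- nrow(pairs)
  if (k < 2) {
    abort("IVW needs at least 2 instruments; use wald_ratio()",
          class = "csfmr_domain_error")
  }
  r <- ratio_estimates(pairs)
  w <- 1 / r$ratio_se^2
  theta <- sum(w * r$ratio) / sum(w)
  se0 <- 1 / sqrt(sum(w))
  Q <- sum(w * (r$ratio - theta)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  se <- se0 * max(1, sqrt(Q / (k - 1)))
  p <- 2 * pnorm(-abs(theta / se))
  mr_row("ivw_re", k, theta, se, p, Q = Q, I2 = I2)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  ws <- w[ord] / sum(w)
  s <- cumsum(ws) - ws / 2
  approx(s, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Orders per-variant ratio estimates and interpolates the
#' precision-weighted median (cumulative standardized weight 0.5); the SE
#' comes from a seeded parametric bootstrap that resamples each beta from a
#' normal with its observed mean and SE and recomputes the estimator.
#' Consistent while valid instruments carry more than half the weight.
#'
#' @param pairs Harmonized tibble with at least 3 rows.
#' @param n_boot Bootstrap draws (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row MR estimate tibble.
#' @export
mr_weighted_median <- function(pairs, n_boot = 5000, seed = 1) {
  k <- nrow(pairs)
  if (k < 3) {
    abort("weighted median needs at least 3 instruments",
          class = "csfmr_not_applicable")
  }
  r <- ratio_estimates(pairs)
  w <- 1 / r$ratio_se^2
  theta <- weighted_median_point(r$ratio, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    be <- rnorm(k, pairs$beta_exp, pairs$se_exp)
    bo <- rnorm(k, pairs$beta_out, pairs$se_out)
    ok <- be != 0
    weighted_median_point(bo[ok] / be[ok], w[ok])
  }, numeric(1))
  se <- sd(boot)
  p <- 2 * pnorm(-abs(theta / se))
  mr_row("weighted_median", k, theta, se, p)
}

#' Fit all applicable MR estimators for one protein-outcome pair
#'
#' Wald ratio when a single instrument is available, random-effects IVW for
#' two or more, and additionally the weighted median when three or more.
#'
#' @param pairs Harmonized tibble from [harmonize_set()].
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return An object of class `mr_fit`: use [tidy()] for the per-method
#'   estimate table, [glance()] for a one-row summary of the primary
#'   estimate, `autoplot()` for a forest plot of per-variant ratios.
#' @export
mr_fit <- function(pairs, n_boot = 5000, seed = 1) {
  k <- nrow(pairs)
  if (k == 0) {
    abort("no harmonized instruments", class = "csfmr_no_instruments")
  }
  estimates <- if (k == 1) wald_ratio(pairs) else mr_ivw(pairs)
  if (k >= 3) {
    estimates <- dplyr::bind_rows(
      estimates, mr_weighted_median(pairs, n_boot = n_boot, seed = seed))
  }
  structure(list(estimates = estimates, pairs = pairs,
                 ratios = ratio_estimates(pairs)),
            class = "mr_fit")
}

#' @export
tidy.mr_fit <- function(x, ...) x$estimates

#' @export
glance.mr_fit <- function(x, ...) {
  primary <- x$estimates[1, ]
  tibble::tibble(nsnp = primary$nsnp, method = primary$method,
                 theta = primary$theta, se = primary$se,
                 pvalue = primary$pvalue, Q = primary$Q, I2 = primary$I2)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("MR fit (", nrow(x$pairs), " instrument(s))\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `alpha` across one family of tests, with
#' q-values from the standard monotone transform.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return A tibble: `pvalue`, `qvalue`, `significant` (in input order).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) {
    return(tibble::tibble(pvalue = numeric(0), qvalue = numeric(0),
                          significant = logical(0)))
  }
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  q <- p.adjust(pvalues, method = "BH")
  m <- length(pvalues)
  # step-up: largest rank j with p_(j) <= j * alpha / m; all smaller ranks in
  ord <- order(pvalues)
  ps <- pvalues[ord]
  pass <- ps <= seq_len(m) * alpha / m
  jmax <- if (any(pass)) max(which(pass)) else 0L
  sig <- logical(m)
  if (jmax > 0) sig[ord[seq_len(jmax)]] <- TRUE
  tibble::tibble(pvalue = pvalues, qvalue = q, significant = sig)
}
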