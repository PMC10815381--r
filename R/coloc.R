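# Single-causal-variant Bayesian colocalization over a region from two
# traits' summary statistics: per-SNP Wakefield log approximate Bayes
# factors, enumeration of the five causal-configuration hypotheses H0-H4 in
# log space, posterior probabilities, and per-SNP shared-signal posteriors.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association: `p1` with trait 1 only, `p2`
#' with trait 2 only, `p12` with both (shared causal variant).
#'
#' @param p1,p2,p12 Priors (defaults 1e-4, 1e-4, 1e-5).
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 + p2 + p12 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' Closed-form log Bayes factor for association versus null at one variant,
#' from its estimate, standard error and a prior effect variance W:
#' `log-ABF = 0.5 * (log(1 - r) + r * z^2)` with `r = W / (W + se^2)` and
#' `z = beta / se`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior variance of the true effect (default 0.15^2, the
#'   conventional quantitative-trait prior SD of 0.15).
#' @return Numeric log-ABF, vectorized over inputs.
#' @export
wakefield_labf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) abort("se must be positive", class = "csfmr_domain_error")
  if (any(W < 0)) abort("W must be non-negative", class = "csfmr_domain_error")
  V <- se^2
  r <- W / (W + V)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log( sum_{i != j} exp(l1_i + l2_j) ): subtracted-product identity with an
# exact O(n^2) fallback when cancellation leaves nothing representable
log_cross_sum <- function(l1, l2) {
  n <- length(l1)
  if (n < 2) return(-Inf)
  s1 <- logsumexp(l1); s2 <- logsumexp(l2); s12 <- logsumexp(l1 + l2)
  total <- s1 + s2
  if (s12 < total) {
    d <- 1 - exp(s12 - total)
    if (d > 1e-12) return(total + log(d))
  }
  # near-complete cancellation: sum the off-diagonal terms directly
  terms <- outer(l1, l2, "+")
  diag(terms) <- -Inf
  logsumexp(as.vector(terms))
}

#' Bayesian colocalization of two traits over a shared variant panel
#'
#' Assumes at most one causal variant per trait. Hypotheses: H0 no
#' association; H1/H2 association with one trait only; H3 two distinct
#' causal variants; H4 one shared causal variant. Posteriors are computed by
#' enumerating causal configurations in log space with per-SNP Wakefield
#' ABFs: `H1 = p1 * sum_i ABF1_i`, `H2 = p2 * sum_j ABF2_j`,
#' `H3 = p1 * p2 * sum_{i != j} ABF1_i * ABF2_j`,
#' `H4 = p12 * sum_i ABF1_i * ABF2_i`, against `H0 = 1`.
#'
#' @param trait1,trait2 Regional summary statistics (data frames with
#'   `variant_id`, `beta`, `se`) over an identical ordered variant panel.
#' @param priors A [coloc_priors()].
#' @param W1,W2 Prior effect variances for traits 1 and 2 (default 0.0225).
#' @return An object of class `coloc_fit`: `pp` (named PPH0..PPH4 summing
#'   to 1), `n_snps`, `lead_shared_variant`, and a per-SNP table with the
#'   log-ABFs and normalized shared-signal posterior `snp_pp_h4`. [tidy()]
#'   returns the per-SNP table, [glance()] the posteriors.
#' @export
coloc_abf <- function(trait1, trait2, priors = coloc_priors(),
                      W1 = 0.15^2, W2 = 0.15^2) {
  if (nrow(trait1) == 0 || nrow(trait2) == 0) {
    abort("empty region", class = "csfmr_empty_region")
  }
  if (nrow(trait1) != nrow(trait2) ||
      !all(trait1$variant_id == trait2$variant_id)) {
    abort("traits must share an identical ordered variant panel",
          class = "csfmr_alignment_error")
  }
  l1 <- wakefield_labf(trait1$beta, trait1$se, W1)
  l2 <- wakefield_labf(trait2$beta, trait2$se, W2)
  lh <- c(
    h0 = 0,
    h1 = log(priors$p1) + logsumexp(l1),
    h2 = log(priors$p2) + logsumexp(l2),
    h3 = log(priors$p1) + log(priors$p2) + log_cross_sum(l1, l2),
    h4 = log(priors$p12) + logsumexp(l1 + l2)
  )
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PPH", 0:4)
  l12 <- l1 + l2
  snp_pp_h4 <- exp(l12 - logsumexp(l12))
  per_snp <- tibble::tibble(
    variant_id = trait1$variant_id,
    labf1 = l1, labf2 = l2, snp_pp_h4 = snp_pp_h4
  )
  if ("pos" %in% names(trait1)) per_snp$pos <- trait1$pos
  structure(list(pp = pp, n_snps = nrow(trait1),
                 lead_shared_variant =
                   trait1$variant_id[which.max(snp_pp_h4)],
                 per_snp = per_snp, priors = priors),
            class = "coloc_fit")
}

#' @export
tidy.coloc_fit <- function(x, ...) x$per_snp

#' @export
glance.coloc_fit <- function(x, ...) {
  tibble::tibble(pph0 = x$pp[["PPH0"]], pph1 = x$pp[["PPH1"]],
                 pph2 = x$pp[["PPH2"]], pph3 = x$pp[["PPH3"]],
                 pph4 = x$pp[["PPH4"]], n_snps = x$n_snps,
                 lead_shared_variant = x$lead_shared_variant)
}

#' @export
print.coloc_fit <- function(x, ...) {
  cat("Colocalization over", x$n_snps, "SNPs\n")
  print(round(x$pp, 4))
  cat("lead shared variant:", x$lead_shared_variant, "\n")
  invisible(x)
}

#' Colocalization decision gate
#'
#' `TRUE` iff the posterior probability of a shared causal variant meets the
#' cutoff (inclusive; default 0.70). Sub-threshold results remain available
#' for exploratory reporting.
#'
#' @param result A `coloc_fit`.
#' @param cutoff H4 posterior cutoff (default 0.70).
#' @return Logical scalar.
#' @export
coloc_gate <- function(result, cutoff = 0.70) {
  result$pp[["PPH4"]] >= cutoff
}
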