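# Independent brute-force oracles, written from the defining formulas rather
# than the package's implementation paths.

# Benjamini-Hochberg step-up from its definition: sort p ascending, find the
# largest rank j with p_(j) <= j * alpha / m; q-values as the running
# minimum of m * p_(j) / j from the largest rank down.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  jmax <- 0
  for (j in seq_len(m)) if (ps[j] <= j * alpha / m) jmax <- j
  sig_sorted <- seq_len(m) <= jmax
  q_sorted <- numeric(m)
  running <- 1
  for (j in rev(seq_len(m))) {
    running <- min(running, m * ps[j] / j)
    q_sorted[j] <- running
  }
  out <- list(qvalue = numeric(m), significant = logical(m))
  out$qvalue[ord] <- q_sorted
  out$significant[ord] <- sig_sorted
  out
}

# IVW point estimate as the minimizer of the weighted sum of squares,
# located numerically instead of via the closed form.
oracle_ivw_theta <- function(ratios, ses) {
  w <- 1 / ses^2
  stats::optimize(function(t) sum(w * (ratios - t)^2),
                  range(ratios) + c(-1, 1), tol = 1e-12)$minimum
}

# Weighted median by brute-force evaluation of the interpolation rule on the
# ordered estimates (re-derived, loop form).
oracle_weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- numeric(length(b))
  acc <- 0
  for (j in seq_along(b)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (s[1] >= 0.5) return(b[1])
  if (s[length(b)] <= 0.5) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Wakefield ABF by numerical integration of the normal-normal marginal
# likelihood ratio: BF = int N(bhat; b, V) N(b; 0, W) db / N(bhat; 0, V).
oracle_labf_integrate <- function(beta, se, W) {
  V <- se^2
  num <- stats::integrate(function(b)
    stats::dnorm(beta, b, sqrt(V)) * stats::dnorm(b, 0, sqrt(W)),
    -Inf, Inf, rel.tol = 1e-12)$value
  log(num / stats::dnorm(beta, 0, sqrt(V)))
}

# Exhaustive causal-configuration enumeration for single-causal-variant
# colocalization, on the raw (non-log) ABF scale. Feasible for n <= ~10.
oracle_coloc_enum <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(l1)
  bf1 <- exp(l1); bf2 <- exp(l2)
  h <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(n)) {
    h["h1"] <- h["h1"] + p1 * bf1[i]
    h["h2"] <- h["h2"] + p2 * bf2[i]
    h["h4"] <- h["h4"] + p12 * bf1[i] * bf2[i]
    for (j in seq_len(n)) {
      if (i != j) h["h3"] <- h["h3"] + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  unname(h / sum(h))
}

# Greedy min-p clumping, re-implemented recursively and independently of the
# package's loop: take the global best candidate, discard its LD/distance
# conflicts, recurse on the remainder.
oracle_clump_ids <- function(cand, ld, r2 = 0.01, window = 1e6) {
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(cand$pvalue, cand$pos, cand$variant_id), , drop = FALSE]
  idx <- cand[1, ]
  rest <- cand[-1, , drop = FALSE]
  conflict <- ld[idx$variant_id, rest$variant_id]^2 >= r2 &
    abs(rest$pos - idx$pos) <= window
  c(idx$variant_id, oracle_clump_ids(rest[!conflict, , drop = FALSE],
                                     ld, r2, window))
}

# Expected binary (haplotype-allele) correlation implied by a latent
# bivariate-normal correlation rho at threshold t = qnorm(maf), via
# one-dimensional numerical integration of the orthant probability.
binary_corr_from_latent <- function(rho, maf) {
  t <- qnorm(maf)
  p11 <- stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((t - rho * x) / sqrt(1 - rho^2)),
    -Inf, t, rel.tol = 1e-10)$value
  (p11 - maf^2) / (maf * (1 - maf))
}

# Invert the observed binary haplotype correlation back to the latent
# Gaussian-scale correlation.
latent_corr_from_binary <- function(r_bin, maf) {
  stats::uniroot(function(rho) binary_corr_from_latent(rho, maf) - r_bin,
                 c(-0.999, 0.999), tol = 1e-8)$root
}
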