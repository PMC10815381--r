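---
title: "Methods: proteome-wide cis-MR screening with colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide cis-MR screening with colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmr)
```

# The estimand and the causal model

The pipeline estimates θ, the change in an outcome (SD units of cognitive
performance, mm³ of brain volume, log-odds of a diagnosis) per 1 log-RFU
increase in the genetically predicted level of a CSF protein. The
identifying assumptions are the standard instrumental-variable triplet for
*cis*-MR: the instrument is associated with the protein (enforced by the
p < 5×10⁻⁸ filter), shares no confounder with the outcome (randomly
allocated genotypes), and affects the outcome only through the protein
(made more plausible by restricting to *cis* variants, and probed by the
heterogeneity statistics, the weighted-median estimator and
colocalization).

Two-sample designs estimate the variant–exposure and variant–outcome
associations in non-overlapping cohorts, so only summary statistics are
needed. All estimators work on harmonized per-variant pairs
(β_exp, se_exp, β_out, se_out).

# Estimators

**Wald ratio** (single instrument): θ = β_out/β_exp, with the first-order
delta-method SE se_out/|β_exp|. This SE neglects the sampling error of
β_exp; it is the dominant convention for instruments selected at
genome-wide significance, and it is accurate when the exposure z-statistic
is large relative to the outcome z-statistic (see *Calibration
experiments* below for where this matters).

**Random-effects IVW** (k ≥ 2): per-variant ratios θⱼ are meta-analysed
with weights wⱼ = 1/seⱼ². Cochran's Q = Σwⱼ(θⱼ−θ)² and
I² = max(0, (Q−(k−1))/Q)·100% summarize heterogeneity, a global signal of
pleiotropy. The random-effects treatment is multiplicative
over-dispersion: the fixed-effect SE (Σwⱼ)^(−1/2) is inflated by
max(1, √(Q/(k−1))). The floor at 1 means the random-effects and
fixed-effect intervals coincide under homogeneity; with the small
instrument counts typical of cis-pQTL panels (1–3 per protein) the
inflation rarely binds.

**Weighted median** (k ≥ 3): ratio estimates are ordered and the estimate
interpolated at cumulative standardized weight 0.5
(sⱼ = (Σ_{i≤j} wᵢ − wⱼ/2)/Σw). It is consistent while valid instruments
carry > 50% of the weight, which is what makes it a useful pleiotropy
sensitivity analysis. Its SE comes from a seeded parametric bootstrap
(default 5000 draws): each β is resampled from a normal with its observed
mean and SE and the estimator recomputed. A screen declares the
weighted-median estimate *concordant* when it has the same sign as the
primary estimate and p < 0.05; only concordant FDR-significant proteins
proceed to colocalization. The "concordant" rule is a declared
operationalization — the literature typically leaves it qualitative — and
is recorded per protein.

**FDR**: Benjamini–Hochberg at α = 0.05 across all proteins with at least
one harmonized instrument in a screen invocation; proteins with no
instruments are excluded from the family (their rows carry a reason code
so the family size is auditable). The realized p-value threshold
corresponding to the 5% FDR is a property of each panel's p-value
distribution and is never hard-coded.

# Colocalization

A significant MR estimate can be genetic confounding: a variant in LD with
the pQTL may affect the outcome through a different gene. The
colocalization stage assumes at most one causal variant per trait in the
region and enumerates five hypotheses — H0 no association, H1/H2 one trait
only, H3 two distinct causal variants, H4 one shared variant. Per-SNP
evidence is the Wakefield approximate Bayes factor,
log-ABF = ½[log(1−r) + r·z²] with r = W/(W+se²): a closed-form
normal-normal Bayes factor requiring only the estimate, its SE and a prior
effect variance W. W defaults to 0.15² for quantitative traits (the
conventional prior SD of 0.15); it is configurable per trait.

Unnormalized hypothesis weights are H0 = 1, H1 = p1·ΣABF₁,
H2 = p2·ΣABF₂, H3 = p1·p2·Σ_{i≠j}ABF₁ᵢABF₂ⱼ, H4 = p12·ΣᵢABF₁ᵢABF₂ᵢ, with
priors p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵ per SNP. All arithmetic is in log
space with a stable log-sum-exp. The H3 cross-term uses the
subtracted-product identity log(e^{S1+S2} − e^{S12}); when cancellation
makes the difference numerically void the code falls back to an exact
O(n²) off-diagonal log-sum, so the result is exact at regional panel
sizes. With a single SNP, H3 is impossible and its posterior is exactly
zero. Per-SNP shared-signal posteriors are the softmax of l₁+l₂; the lead
shared variant is their argmax. A protein *colocalizes* when PPH4 ≥ 0.70
(inclusive); sub-threshold posteriors are always written to an exploratory
table rather than discarded, since values like PPH4 ≈ 0.5 can still be
biologically suggestive.

The coloc region defaults to the instrument cis window (gene ± 1 Mb);
`coloc_window_bp = 1e5` reproduces the narrower ±100 kb convention some
regional analyses prefer. Beta/SE inputs are the primary mode; a
p-value + MAF mode is deliberately not implemented.

# Instruments, clumping and harmonization

Instrument selection applies, in order: cis window (positions within
1 Mb of the gene start/end, boundary inclusive), significance
(p < 5×10⁻⁸, strict), presence in the outcome GWAS, then greedy clumping
(take the smallest-p unclaimed variant, prune unclaimed variants with
r² ≥ 0.01 within 1 Mb, repeat). The filter order
significance → presence → clump is a declared choice; per-stage counts are
attached to every instrument set so the order is auditable. Variants
absent from the LD panel are dropped with a warning (conservative).
Ties on p break by smaller position then lexicographic variant id, which
makes clumping invariant to input row order. Pairs farther apart than the
clumping window are never pruned regardless of r².

Harmonization aligns the outcome estimate to the exposure's effect allele:
identical alleles are kept; swapped labels flip the outcome beta and
reflect its allele frequency; strand flips are resolved by complementing
single-base alleles (indels are never complemented and never treated as
palindromic). Palindromic variants (A/T, C/G) are oriented by
allele-frequency concordance only when both frequencies are available and
both lie outside [0.42, 0.58] — a common default window in two-sample MR
tooling — and are dropped otherwise. The full action audit (kept /
flipped / dropped and why) is retained and written by `make_report()`.
Harmonization is idempotent and symmetric under relabelling of the
outcome's alleles; both properties are tested.

# The synthetic generator

`simulate_genotypes()` draws each haplotype as a zero-mean AR(1) Gaussian
vector across variants (adjacent latent correlation `ld_rho`), thresholds
at qnorm(MAF) to get alleles, and sums two haplotypes per individual. The
one-parameter LD model is deliberate: clumping and single-causal-variant
colocalization respond only to pairwise r, so an autoregressive decay is
the simplest structure that exercises them. It does **not** emulate real
human LD blocks, recombination hotspots, imputation uncertainty,
relatedness or population stratification — so passing tests demonstrate
algorithmic correctness and statistical calibration under the stated
model, not robustness to those real-data features.

`simulate_traits()` builds the exposure X as a·G_c + noise, standardized
to unit variance, with a set so the causal cis variant(s) explain
`var_explained_cis` of the variance. Scenarios: `shared`
(Y = θ·X + noise — the outcome's genetic signal flows only through the
exposure's causal variant), `distinct` (Y depends on a different variant,
chosen as the panel position farthest in LD from the exposure's causal
set; this induces the exchangeability violation that colocalization is
meant to catch), `null_protein_effect` (cis signal but θ = 0) and
`null_assoc` (no genetic signal at all, which yields proteins with no
instruments). Exposure and outcome cohorts are always independent draws —
the two-sample, no-overlap design. Marginal per-SNP regressions (not joint
fits) produce the summary statistics, mirroring how deposited GWAS
estimates are computed; the sample LD matrix is the signed dosage
correlation in the exposure cohort.

Although the configuration exposes a single `var_explained_cis`, the
generator accepts `n_causal` causal cis variants (evenly spaced so they
are mutually in low LD, splitting the variance equally). This is needed to
emulate proteins instrumented by 2–3 independent pQTLs, which the
multi-instrument estimators require.

Defaults are the study conditions the package is designed around: exposure
GWAS n = 835 (the CSF proteomic GWAS scale), outcome GWAS n = 10,000,
MAF 0.3, `ld_rho` 0.9, `var_explained_cis` 0.1 (a strong cis-pQTL:
detectable at genome-wide significance with n = 835), θ = 0.23 for
demonstrations (the scale of the strongest protein effects on cognition).

# Calibration experiments and problem sizes

The test suite runs, among others:

- **Estimator oracles**: Wald/IVW/weighted-median/BH against brute-force
  reimplementations on panels of up to 12 instruments, at 10⁻⁹; clumping
  against an independent recursive oracle on random panels of up to 12
  candidates.
- **Coloc enumeration**: posteriors against exhaustive
  causal-configuration enumeration for up to 10 SNPs, at 10⁻⁹; the
  Wakefield closed form against numerical integration of the
  normal-normal Bayes factor.
- **Recovery**: θ = 0.3, 3 instruments, 200 seeded replicates,
  outcome n = 20,000. The exposure GWAS here has n = 20,000 rather than
  835: the first-order Wald SE is only calibrated when the exposure
  z-statistics dominate the outcome z-statistics, and with n = 835 and an
  outcome signal this strong the neglected exposure-error term is material
  (measured interval coverage drops to ≈ 0.90). The calibration experiment
  therefore runs in the regime the estimator's SE assumes (exposure
  z ≈ 4× outcome z), where measured coverage is ≈ 0.95. This is a known
  limitation of the first-order SE, not of the implementation, and is the
  reason the recovery panel uses `ld_rho = 0.6` with 30 variants (so three
  evenly spaced causal variants stay below the clumping r² threshold and
  all three instruments survive selection).
- **Scenario discrimination**: 100 shared and 100 distinct replicates
  (outcome n = 10,000, 60-SNP regions, `ld_rho` 0.9; the distinct
  scenario's two causal variants have |r| ≤ 0.3).
- **Screen calibration**: 100 all-null 20-protein panels (no FDR
  discoveries expected) and 100 panels of 10 proteins with 2 true effects
  (both expected to pass the FDR and colocalization gates), with 20-SNP
  regions and outcome n = 10,000.
- **PheWAS calibration**: 100 null logistic fits at n = 5,000 (uniform
  p by Kolmogorov–Smirnov), a collapsible 2×2 table against the
  closed-form odds ratio, and odds-ratio recovery at the OR = 1.13,
  n = 200,000, 5% prevalence scale.

These sizes were chosen so the full suite exercises every stochastic claim
at meaningful replicate counts while remaining runnable on a laptop.

# Numerical and degenerate-input choices

- p-values of exactly 0 in input files are replaced by the smallest
  positive normal double, with a warning (log-domain safety).
- Exact linear relations in the synthetic marginal regressions would give
  SE = 0; the SE is floored at the smallest positive normal double so the
  record survives validation with p at its underflow guard.
- Monomorphic variants get β = 0, SE = ∞ and are dropped by summary-stats
  validation.
- LD matrices are symmetrized by averaging with the transpose within a
  1e-6 tolerance; entries beyond |r| > 1 + 1e-6 are format errors.
- BED regions convert half-open 0-based to the package's 1-based inclusive
  convention at the boundary; internally all positions are 1-based GRCh37.
- The case-control generator solves its intercept by root-finding so the
  expected prevalence matches exactly; degenerate draws (no cases or no
  controls) are errors, and PheWAS fits flag separation
  (|log-OR| > 15 or non-convergence within 100 IRLS iterations) and
  exclude such rows from the FDR family.
- Results tables print 95% CIs as estimate ± 1.959964·SE.

# Known limitations

- The first-order Wald SE undercovers when instruments are weak relative
  to the outcome signal (see above); a second-order SE is a possible
  extension.
- Single-causal-variant colocalization cannot represent allelic
  heterogeneity; regions with multiple true causal pQTLs dilute PPH4.
- The palindromic-variant frequency rule misorients variants whose
  frequencies are discordant between cohorts for reasons other than
  strand (e.g., ancestry mismatch).
- The generator's LD model is exchangeable along the panel; tests on it do
  not certify behavior on real LD block structure.
- Proxy-variant substitution for instruments missing from an outcome is
  deliberately not implemented: instruments must be present in the
  outcome GWAS.
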