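# Effect-allele harmonization between exposure and outcome GWAS: align the
# outcome estimate to the exposure's effect allele, resolving label swaps and
# strand flips, and dropping palindromic (A/T, C/G) variants whose
# orientation cannot be resolved from allele frequencies.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  # single-base SNV alleles only; indels are never complemented
  ifelse(nchar(a) == 1 & a %in% names(COMPLEMENT), COMPLEMENT[a], NA_character_)
}

is_palindromic <- function(effect, other) {
  nchar(effect) == 1 & nchar(other) == 1 &
    !is.na(complement_allele(effect)) & other == complement_allele(effect)
}

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome association estimate to the exposure's effect allele.
#' Outcomes: alleles already identical (`kept`); labels swapped, so the
#' outcome beta is sign-flipped and its EAF replaced by 1 - EAF
#' (`flipped_outcome`); alleles matching only after strand complementation
#' (complement, then the same two rules); palindromic variants resolved by
#' allele-frequency concordance when both EAFs are available and both lie
#' outside \[`ambiguous_eaf`\[1\], `ambiguous_eaf`\[2\]\], otherwise
#' `dropped_palindromic`; anything irreconcilable is `dropped_mismatch`.
#'
#' @param exp_rec,out_rec One-row data frames with `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param ambiguous_eaf Frequency window within which a palindromic variant's
#'   orientation is considered ambiguous (default `c(0.42, 0.58)`).
#' @return A one-row tibble: `variant_id`, `effect_allele`, `other_allele`
#'   (the exposure orientation), `beta_exp`, `se_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `eaf_out`, `action` in
#'   `{kept, flipped_outcome, dropped_palindromic, dropped_mismatch}`.
#' @export
harmonize_pair <- function(exp_rec, out_rec, ambiguous_eaf = c(0.42, 0.58)) {
  stopifnot(exp_rec$variant_id[1] == out_rec$variant_id[1])
  e1 <- exp_rec$effect_allele[1]; o1 <- exp_rec$other_allele[1]
  e2 <- out_rec$effect_allele[1]; o2 <- out_rec$other_allele[1]
  beta_out <- out_rec$beta[1]; eaf_out <- out_rec$eaf[1]

  flip <- function() {
    beta_out <<- -beta_out
    if (!is.na(eaf_out)) eaf_out <<- 1 - eaf_out
  }

  action <-
    if (is_palindromic(e1, o1)) {
      if (!is_palindromic(e2, o2) || !all(c(e2, o2) %in% c(e1, o1))) {
        "dropped_mismatch"
      } else {
        f1 <- exp_rec$eaf[1]; f2 <- eaf_out
        ambiguous <- function(f) is.na(f) ||
          (f >= ambiguous_eaf[1] && f <= ambiguous_eaf[2])
        if (ambiguous(f1) || ambiguous(f2)) {
          "dropped_palindromic"
        } else {
          # orient by frequency concordance: the exposure effect allele on the
          # outcome side is whichever allele matches its minor/major status
          same_side <- (f1 < 0.5) == (f2 < 0.5)
          aligned_labels <- e2 == e1
          if (same_side == aligned_labels) {
            if (aligned_labels) "kept" else { flip(); "flipped_outcome" }
          } else {
            # labels agree but frequencies disagree (or vice versa): the
            # outcome is reported on the opposite strand orientation
            if (aligned_labels) { flip(); "flipped_outcome" } else "kept"
          }
        }
      }
    } else if (e2 == e1 && o2 == o1) {
      "kept"
    } else if (e2 == o1 && o2 == e1) {
      flip(); "flipped_outcome"
    } else {
      ce2 <- complement_allele(e2); co2 <- complement_allele(o2)
      if (!is.na(ce2) && !is.na(co2) && ce2 == e1 && co2 == o1) {
        "kept"
      } else if (!is.na(ce2) && !is.na(co2) && ce2 == o1 && co2 == e1) {
        flip(); "flipped_outcome"
      } else {
        "dropped_mismatch"
      }
    }

  tibble::tibble(
    variant_id = exp_rec$variant_id[1],
    effect_allele = e1, other_allele = o1,
    beta_exp = exp_rec$beta[1], se_exp = exp_rec$se[1],
    eaf_exp = exp_rec$eaf[1],
    beta_out = beta_out, se_out = out_rec$se[1], eaf_out = eaf_out,
    action = action
  )
}

#' Harmonize an instrument set against an outcome GWAS
#'
#' Applies [harmonize_pair()] to every instrument found in the outcome
#' summary statistics. Instruments absent from the outcome should not occur
#' after [select_cis_variants()]; any that do are recorded with action
#' `"absent_in_outcome"`. The full audit table (all actions) is attached as
#' attribute `"audit"`; the returned tibble keeps only aligned pairs.
#'
#' @param instruments Instrument tibble (rows of a `csf_sumstats` for the
#'   exposure).
#' @param outcome A `csf_sumstats` tibble for the outcome.
#' @param ambiguous_eaf Passed to [harmonize_pair()].
#' @return Tibble of harmonized pairs (actions `kept` / `flipped_outcome`
#'   only), with attributes `audit` (all rows incl. drops) and
#'   `action_counts`.
#' @export
harmonize_set <- function(instruments, outcome, ambiguous_eaf = c(0.42, 0.58)) {
  empty <- tibble::tibble(
    variant_id = character(0), effect_allele = character(0),
    other_allele = character(0), beta_exp = numeric(0), se_exp = numeric(0),
    eaf_exp = numeric(0), beta_out = numeric(0), se_out = numeric(0),
    eaf_out = numeric(0), action = character(0)
  )
  if (nrow(instruments) == 0) {
    attr(empty, "audit") <- empty
    attr(empty, "action_counts") <- integer(0)
    return(empty)
  }
  rows <- purrr::map(seq_len(nrow(instruments)), function(i) {
    exp_rec <- instruments[i, ]
    j <- match(exp_rec$variant_id, outcome$variant_id)
    if (is.na(j)) {
      return(tibble::tibble(
        variant_id = exp_rec$variant_id,
        effect_allele = exp_rec$effect_allele,
        other_allele = exp_rec$other_allele,
        beta_exp = exp_rec$beta, se_exp = exp_rec$se, eaf_exp = exp_rec$eaf,
        beta_out = NA_real_, se_out = NA_real_, eaf_out = NA_real_,
        action = "absent_in_outcome"
      ))
    }
    harmonize_pair(exp_rec, outcome[j, ], ambiguous_eaf = ambiguous_eaf)
  })
  audit <- dplyr::bind_rows(rows)
  out <- dplyr::filter(audit, .data$action %in% c("kept", "flipped_outcome"))
  attr(out, "audit") <- audit
  attr(out, "action_counts") <- table(audit$action)
  out
}

#' Write the harmonization audit table
#' @param harmonized Output of [harmonize_set()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(harmonized, path) {
  audit <- attr(harmonized, "audit") %||% harmonized
  readr::write_tsv(audit, path, na = "NA", progress = FALSE)
  invisible(path)
}
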