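# cis-pQTL instrument selection: cis-window restriction around the encoding
# gene, genome-wide significance, presence in the outcome GWAS, then greedy
# distance-bounded LD clumping so retained instruments are near-independent.

#' Instrument-selection configuration
#'
#' @param cis_window_bp Window around the gene start/end defining "cis"
#'   (default 1 Mb, closed at exactly the boundary).
#' @param p_threshold Genome-wide significance threshold; strictly
#'   `p < p_threshold` (default 5e-8).
#' @param clump_r2 Pairwise LD r-squared above which the weaker variant is
#'   pruned (default 0.01).
#' @param clump_window_bp Distance beyond which pairs are never pruned,
#'   whatever their r-squared (default 1 Mb).
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(cis_window_bp = 1e6, p_threshold = 5e-8,
                              clump_r2 = 0.01, clump_window_bp = 1e6) {
  stopifnot(cis_window_bp > 0, p_threshold > 0,
            clump_r2 > 0, clump_r2 < 1, clump_window_bp > 0)
  structure(list(cis_window_bp = cis_window_bp, p_threshold = p_threshold,
                 clump_r2 = clump_r2, clump_window_bp = clump_window_bp),
            class = "instrument_config")
}

#' Select candidate cis variants for one protein
#'
#' Retains exposure variants on the gene's chromosome with position within
#' `cis_window_bp` of the gene start or end, association p strictly below
#' `p_threshold`, and present (by variant id) in the outcome summary
#' statistics. Counts at each filter stage are attached as the
#' `"provenance"` attribute.
#'
#' @param exposure A `csf_sumstats` tibble with `chrom` and `pos` filled.
#' @param region A one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param outcome A `csf_sumstats` tibble for the outcome trait.
#' @param cfg An [instrument_config()].
#' @return The candidate subset of `exposure` (a tibble), with attribute
#'   `provenance` = named counts (`n_input`, `n_cis`, `n_significant`,
#'   `n_in_outcome`, `absent_in_outcome`).
#' @export
select_cis_variants <- function(exposure, region, outcome,
                                cfg = instrument_config()) {
  lo <- region$start[1] - cfg$cis_window_bp
  hi <- region$end[1] + cfg$cis_window_bp
  cis <- dplyr::filter(exposure,
                       !is.na(.data$chrom), .data$chrom == region$chrom[1],
                       !is.na(.data$pos), .data$pos >= lo, .data$pos <= hi)
  sig <- dplyr::filter(cis, .data$pvalue < cfg$p_threshold)
  present <- dplyr::filter(sig, .data$variant_id %in% outcome$variant_id)
  out <- tibble::as_tibble(present)
  attr(out, "provenance") <- c(
    n_input = nrow(exposure), n_cis = nrow(cis), n_significant = nrow(sig),
    n_in_outcome = nrow(present),
    absent_in_outcome = nrow(sig) - nrow(present)
  )
  out
}

#' Greedy distance-bounded LD clumping
#'
#' Repeatedly takes the unclaimed candidate with the smallest p-value as an
#' index variant and removes every unclaimed candidate with r-squared at or
#' above `clump_r2` against it lying within `clump_window_bp`. Ties on p are
#' broken by smaller position, then lexicographic variant id, making the
#' result invariant to input row order. Candidates absent from the LD panel
#' are dropped with a warning.
#'
#' @param candidates Candidate tibble from [select_cis_variants()].
#' @param ld Signed LD correlation matrix with variant-id dimnames.
#' @param cfg An [instrument_config()].
#' @return The retained instrument tibble, sorted by p; attribute
#'   `provenance` carries the candidate provenance plus `absent_in_ld` and
#'   `n_clumped`.
#' @export
clump <- function(candidates, ld, cfg = instrument_config()) {
  prov <- attr(candidates, "provenance") %||% c(n_input = nrow(candidates))
  in_panel <- candidates$variant_id %in% rownames(ld)
  if (any(!in_panel)) {
    warn(paste0(sum(!in_panel),
                " candidate(s) absent from the LD panel dropped"))
  }
  x <- candidates[in_panel, , drop = FALSE]
  x <- dplyr::arrange(x, .data$pvalue, .data$pos, .data$variant_id)
  keep <- character(0)
  unclaimed <- x
  while (nrow(unclaimed) > 0) {
    idx <- unclaimed[1, ]
    keep <- c(keep, idx$variant_id)
    r2 <- ld[idx$variant_id, unclaimed$variant_id]^2
    near <- is.na(unclaimed$pos) | is.na(idx$pos) |
      abs(unclaimed$pos - idx$pos) <= cfg$clump_window_bp
    prune <- (r2 >= cfg$clump_r2 & near) |
      unclaimed$variant_id == idx$variant_id
    unclaimed <- unclaimed[!prune, , drop = FALSE]
  }
  out <- x[match(keep, x$variant_id), , drop = FALSE]
  attr(out, "provenance") <- c(prov, absent_in_ld = sum(!in_panel),
                               n_clumped = nrow(out))
  out
}

#' Select independent cis instruments for one protein
#'
#' Convenience wrapper: [select_cis_variants()] then [clump()].
#'
#' @inheritParams select_cis_variants
#' @param ld Signed LD matrix.
#' @return Instrument tibble with stage provenance attribute.
#' @export
select_instruments <- function(exposure, region, outcome, ld,
                               cfg = instrument_config()) {
  clump(select_cis_variants(exposure, region, outcome, cfg), ld, cfg)
}
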