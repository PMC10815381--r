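# Proteome-wide screen orchestration: per-protein instrument selection ->
# harmonization -> MR -> panel-wide FDR -> weighted-median concordance ->
# colocalization gate -> secondary-outcome MR, with auditable provenance.

#' Assemble a screen exposure panel
#'
#' @param protein_id Character vector of protein identifiers.
#' @param exposure List of `csf_sumstats` tibbles, one per protein.
#' @param ld List of signed LD matrices, one per protein region.
#' @param region List of one-row region tibbles (`gene_id`, `chrom`,
#'   `start`, `end`), one per protein.
#' @return A tibble with list-columns, one row per protein.
#' @export
screen_panel <- function(protein_id, exposure, ld, region) {
  stopifnot(!anyDuplicated(protein_id),
            length(exposure) == length(protein_id),
            length(ld) == length(protein_id),
            length(region) == length(protein_id))
  tibble::tibble(protein_id = protein_id, exposure = exposure, ld = ld,
                 region = region)
}

coloc_region_pair <- function(exposure, outcome, region, window_bp) {
  lo <- region$start[1] - window_bp
  hi <- region$end[1] + window_bp
  t1 <- dplyr::filter(exposure, .data$chrom == region$chrom[1],
                      .data$pos >= lo, .data$pos <= hi)
  shared <- intersect(t1$variant_id, outcome$variant_id)
  t1 <- t1[match(shared, t1$variant_id), , drop = FALSE]
  t2 <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  list(trait1 = t1, trait2 = t2)
}

#' Run the proteome-wide MR + colocalization screen
#'
#' For each protein: select cis instruments, harmonize against the primary
#' outcome, estimate the causal effect (Wald for one instrument, IVW for
#' several, weighted median alongside when three or more). BH-FDR is applied
#' across all proteins with at least one harmonized instrument.
#' Colocalization is then computed for FDR-significant proteins whose
#' weighted-median estimate (when available) is concordant -- same sign and
#' p < 0.05 -- with the primary estimate; `coloc_pass` marks a shared-variant
#' posterior at or above `coloc_cutoff`.
#'
#' @param panel A [screen_panel()] tibble.
#' @param outcome Primary-outcome `csf_sumstats`.
#' @param instrument_cfg An [instrument_config()].
#' @param priors [coloc_priors()] for colocalization.
#' @param coloc_window_bp Region half-width around the gene for
#'   colocalization (default the instrument cis window, 1 Mb; 1e5 gives the
#'   narrow +/-100 kb alternative).
#' @param coloc_cutoff H4 posterior cutoff (default 0.70, inclusive).
#' @param coloc_all Compute colocalization for every protein regardless of
#'   FDR status (exploratory; recorded in provenance).
#' @param fdr_alpha FDR level across the protein panel (default 0.05).
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return An object of class `csf_screen`; [tidy()] gives the per-protein
#'   results table, [glance()] the stage counts. Components: `results`,
#'   `estimates` (all methods, long), `coloc` (named list of `coloc_fit`),
#'   `harmonization` (audit tibble), `provenance`.
#' @export
run_screen <- function(panel, outcome, instrument_cfg = instrument_config(),
                       priors = coloc_priors(), coloc_window_bp = 1e6,
                       coloc_cutoff = 0.70, coloc_all = FALSE,
                       fdr_alpha = 0.05, n_boot = 5000, seed = 1) {
  n_prot <- nrow(panel)
  per_protein <- purrr::map(seq_len(n_prot), function(i) {
    prot <- panel$protein_id[i]
    instruments <- select_instruments(panel$exposure[[i]],
                                      panel$region[[i]], outcome,
                                      panel$ld[[i]], instrument_cfg)
    prov <- attr(instruments, "provenance")
    if (nrow(instruments) == 0) {
      return(list(protein_id = prot, reason = "no_instruments",
                  provenance = prov, harmonized = NULL, fit = NULL))
    }
    h <- harmonize_set(instruments, outcome)
    if (nrow(h) == 0) {
      return(list(protein_id = prot, reason = "no_instruments",
                  provenance = prov,
                  harmonized = attr(h, "audit"), fit = NULL))
    }
    fit <- mr_fit(h, n_boot = n_boot, seed = seed + i)
    list(protein_id = prot, reason = NA_character_, provenance = prov,
         harmonized = attr(h, "audit"), pairs = h, fit = fit)
  })

  results <- purrr::map_dfr(per_protein, function(p) {
    if (is.null(p$fit)) {
      return(tibble::tibble(protein_id = p$protein_id, reason = p$reason,
                            nsnp = 0L, instruments = list(character(0)),
                            method = NA_character_, theta = NA_real_,
                            se = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, pvalue = NA_real_,
                            Q = NA_real_, I2 = NA_real_,
                            wm_theta = NA_real_, wm_pvalue = NA_real_))
    }
    est <- p$fit$estimates
    primary <- est[1, ]
    wm <- est[est$method == "weighted_median", ]
    tibble::tibble(protein_id = p$protein_id, reason = NA_character_,
                   nsnp = primary$nsnp,
                   instruments = list(p$pairs$variant_id),
                   method = primary$method, theta = primary$theta,
                   se = primary$se, ci_low = primary$ci_low,
                   ci_high = primary$ci_high, pvalue = primary$pvalue,
                   Q = primary$Q, I2 = primary$I2,
                   wm_theta = if (nrow(wm)) wm$theta else NA_real_,
                   wm_pvalue = if (nrow(wm)) wm$pvalue else NA_real_)
  })

  # FDR family: proteins with >= 1 harmonized instrument
  in_family <- is.na(results$reason)
  results$qvalue <- NA_real_
  results$fdr_significant <- FALSE
  if (any(in_family)) {
    fdr <- bh_fdr(results$pvalue[in_family], alpha = fdr_alpha)
    results$qvalue[in_family] <- fdr$qvalue
    results$fdr_significant[in_family] <- fdr$significant
  }

  # weighted-median concordance: applies only when the method was run
  results$wm_consistent <- is.na(results$wm_theta) |
    (sign(results$wm_theta) == sign(results$theta) &
       results$wm_pvalue < 0.05)

  coloc_eligible <- results$fdr_significant & results$wm_consistent
  do_coloc <- if (coloc_all) in_family else coloc_eligible
  coloc_fits <- list()
  results$pph0 <- NA_real_; results$pph1 <- NA_real_
  results$pph2 <- NA_real_; results$pph3 <- NA_real_
  results$pph4 <- NA_real_
  results$lead_shared_variant <- NA_character_
  results$coloc_pass <- FALSE
  for (i in which(do_coloc)) {
    pair <- coloc_region_pair(panel$exposure[[i]], outcome,
                              panel$region[[i]], coloc_window_bp)
    if (nrow(pair$trait1) == 0) next
    cf <- coloc_abf(pair$trait1, pair$trait2, priors = priors)
    coloc_fits[[panel$protein_id[i]]] <- cf
    results$pph0[i] <- cf$pp[["PPH0"]]; results$pph1[i] <- cf$pp[["PPH1"]]
    results$pph2[i] <- cf$pp[["PPH2"]]; results$pph3[i] <- cf$pp[["PPH3"]]
    results$pph4[i] <- cf$pp[["PPH4"]]
    results$lead_shared_variant[i] <- cf$lead_shared_variant
    results$coloc_pass[i] <- coloc_gate(cf, cutoff = coloc_cutoff) &&
      coloc_eligible[i]
  }

  audit <- purrr::map_dfr(per_protein, function(p) {
    if (is.null(p$harmonized)) return(tibble::tibble())
    dplyr::mutate(p$harmonized, protein_id = p$protein_id, .before = 1)
  })
  multiplicity <- table(factor(results$nsnp[in_family]))
  provenance <- list(
    seed = seed, fdr_alpha = fdr_alpha, coloc_cutoff = coloc_cutoff,
    coloc_window_bp = coloc_window_bp, coloc_all = coloc_all,
    instrument_cfg = unclass(instrument_cfg), priors = unclass(priors),
    n_boot = n_boot,
    n_proteins = n_prot, n_in_fdr_family = sum(in_family),
    n_no_instruments = sum(!in_family),
    n_fdr_significant = sum(results$fdr_significant),
    n_coloc_pass = sum(results$coloc_pass),
    instrument_multiplicity = as.list(multiplicity),
    stage_counts = purrr::map(per_protein,
                              function(p) as.list(p$provenance)) |>
      setNames(panel$protein_id)
  )
  structure(list(results = results, coloc = coloc_fits,
                 harmonization = audit, provenance = provenance,
                 per_protein = per_protein),
            class = "csf_screen")
}

#' @export
tidy.csf_screen <- function(x, ...) x$results

#' @export
glance.csf_screen <- function(x, ...) {
  p <- x$provenance
  tibble::tibble(n_proteins = p$n_proteins,
                 n_in_fdr_family = p$n_in_fdr_family,
                 n_no_instruments = p$n_no_instruments,
                 n_fdr_significant = p$n_fdr_significant,
                 n_coloc_pass = p$n_coloc_pass)
}

#' @export
print.csf_screen <- function(x, ...) {
  cat("CSF proteome MR screen:", x$provenance$n_proteins, "proteins;",
      x$provenance$n_fdr_significant, "FDR-significant;",
      x$provenance$n_coloc_pass, "colocalized\n")
  print(dplyr::select(x$results, "protein_id", "nsnp", "method", "theta",
                      "se", "pvalue", "qvalue", "fdr_significant",
                      "pph4", "coloc_pass"))
  invisible(x)
}

#' Secondary-outcome MR for colocalization-passing proteins
#'
#' Re-harmonizes each passing protein's instrument set against each
#' secondary outcome and re-estimates the causal effect; the unit tag is
#' propagated verbatim to the report (SD, mm3, log-odds, ...).
#'
#' @param screen A `csf_screen` from [run_screen()].
#' @param panel The [screen_panel()] used for the screen.
#' @param outcomes A tibble with columns `outcome_id`, `sumstats` (list of
#'   `csf_sumstats`), `unit` (character tag).
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return A tibble of per-protein, per-outcome MR estimates with a `unit`
#'   column; outcomes missing the instruments yield
#'   `reason = "no_instruments"` rows.
#' @export
run_secondary <- function(screen, panel, outcomes, n_boot = 5000, seed = 1) {
  passing <- screen$results$protein_id[screen$results$coloc_pass]
  grid <- tidyr::expand_grid(protein_id = passing,
                             k = seq_len(nrow(outcomes)))
  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    prot <- grid$protein_id[g]
    k <- grid$k[g]
    i <- match(prot, panel$protein_id)
    ids <- screen$results$instruments[[match(prot,
                                             screen$results$protein_id)]]
    instruments <- dplyr::filter(panel$exposure[[i]],
                                 .data$variant_id %in% ids)
    h <- harmonize_set(instruments, outcomes$sumstats[[k]])
    base <- tibble::tibble(protein_id = prot,
                           outcome_id = outcomes$outcome_id[k],
                           unit = outcomes$unit[k])
    if (nrow(h) == 0) {
      return(dplyr::mutate(base, reason = "no_instruments", nsnp = 0L,
                           method = NA_character_, theta = NA_real_,
                           se = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, pvalue = NA_real_))
    }
    fit <- mr_fit(h, n_boot = n_boot, seed = seed + g)
    primary <- fit$estimates[1, ]
    dplyr::mutate(base, reason = NA_character_, nsnp = primary$nsnp,
                  method = primary$method, theta = primary$theta,
                  se = primary$se, ci_low = primary$ci_low,
                  ci_high = primary$ci_high, pvalue = primary$pvalue)
  })
}

#' Write the consolidated screen report
#'
#' Emits the results table, the harmonization audit, an exploratory table of
#' sub-threshold colocalization results, and a provenance JSON (config echo,
#' seed, stage counts) sufficient to reproduce the run.
#'
#' @param screen A `csf_screen`.
#' @param out_dir Output directory (created if absent).
#' @param outcome_id Label for the primary outcome column.
#' @return Named character vector of the files written, invisibly.
#' @export
make_report <- function(screen, out_dir, outcome_id = "cognitive_performance") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- dplyr::mutate(screen$results, outcome_id = outcome_id)
  files <- c(
    results = file.path(out_dir, "screen_results.tsv"),
    harmonization = file.path(out_dir, "harmonization_audit.tsv"),
    coloc_exploratory = file.path(out_dir, "coloc_exploratory.tsv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_results_table(res, files[["results"]])
  readr::write_tsv(screen$harmonization, files[["harmonization"]],
                   na = "NA", progress = FALSE)
  explor <- dplyr::filter(res, !is.na(.data$pph4), !.data$coloc_pass)
  readr::write_tsv(
    dplyr::select(explor, "protein_id", "outcome_id", "pph0", "pph1",
                  "pph2", "pph3", "pph4", "lead_shared_variant"),
    files[["coloc_exploratory"]], na = "NA", progress = FALSE)
  jsonlite::write_json(screen$provenance, files[["provenance"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
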