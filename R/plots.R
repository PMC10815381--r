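# ggplot2 views of the three result types: per-variant ratio forest for an
# MR fit, regional association + shared-signal posterior for a coloc fit,
# and a panel-wide estimate plot for a screen.

#' @export
autoplot.mr_fit <- function(object, ...) {
  r <- object$ratios
  r$ci_low <- r$ratio - CI_Z * r$ratio_se
  r$ci_high <- r$ratio + CI_Z * r$ratio_se
  overall <- object$estimates[1, ]
  ggplot2::ggplot(r, ggplot2::aes(x = .data$ratio, y = .data$variant_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = overall$theta, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-variant ratio estimate (95% CI)", y = NULL,
                  title = sprintf("%s estimate: %.3f (SE %.3f)",
                                  overall$method, overall$theta,
                                  overall$se)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coloc_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_snp, c("labf1", "labf2"),
                           names_to = "trait", values_to = "labf")
  d$x <- if ("pos" %in% names(object$per_snp)) {
    rep(object$per_snp$pos, each = 2)
  } else {
    rep(seq_len(object$n_snps), each = 2)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$labf,
                                  colour = .data$trait)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "position", y = "log approximate Bayes factor",
                  title = sprintf("PPH4 = %.2f (lead shared variant %s)",
                                  object$pp[["PPH4"]],
                                  object$lead_shared_variant)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.csf_screen <- function(object, ...) {
  d <- dplyr::filter(object$results, is.na(.data$reason))
  d$status <- dplyr::case_when(
    d$coloc_pass ~ "colocalized",
    d$fdr_significant ~ "FDR-significant",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta,
                                  y = stats::reorder(.data$protein_id,
                                                     .data$theta),
                                  colour = .data$status)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SD outcome per 1 log-RFU protein (95% CI)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' PheWAS Manhattan-style plot
#'
#' @param rows Output of [run_phewas()].
#' @param alpha FDR level marker.
#' @return A ggplot object.
#' @export
plot_phewas <- function(rows, alpha = 0.05) {
  d <- dplyr::filter(rows, .data$status == "fitted")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$phenotype_id,
                                                     .data$pvalue),
                                  y = -log10(.data$pvalue),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
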