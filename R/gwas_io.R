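# Reading / writing the tabular artifacts the pipeline touches: GWAS summary
# statistics, LD matrices, gene regions (BED), and the consolidated results
# table. Internal coordinates are 1-based inclusive on GRCh37.

SUMSTATS_COLS <- c(
  variant_id = "variant_id", chrom = "chromosome", pos = "base_pair_location",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
  pvalue = "p_value", n = "n"
)

MANDATORY_COLS <- c("variant_id", "effect_allele", "other_allele",
                    "beta", "se", "pvalue")

#' Construct a validated summary-statistics tibble
#'
#' The central tabular currency of the package: one row per variant holding
#' marginal GWAS association estimates for a single trait. Rows violating the
#' record invariants (non-positive standard error, p outside (0, 1],
#' non-finite beta, identical alleles, allele frequency outside \[0, 1\],
#' duplicated variant id) are dropped and counted in the load report attached
#' as the `"load_report"` attribute.
#'
#' @param x A data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"quantitative"` (beta in trait units per effect-allele
#'   copy) or `"binary"` (beta on the log-odds scale).
#'
#' @return A tibble of class `csf_sumstats`, sorted by (chrom, pos), with
#'   attributes `trait_id`, `trait_type` and `load_report` (a named integer
#'   vector: `n_input`, `n_kept`, `n_dropped`).
#' @export
as_sumstats <- function(x, trait_id, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(MANDATORY_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "csfmr_format_error")
  }
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- dplyr::mutate(x,
    variant_id = as.character(.data$variant_id),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pvalue = as.numeric(.data$pvalue),
    n = as.numeric(.data$n)
  )
  n_input <- nrow(x)
  # p = 0 would break downstream log-domain arithmetic; clamp with a warning
  if (any(!is.na(x$pvalue) & x$pvalue == 0)) {
    warn("p-values equal to 0 replaced by the smallest positive normal double")
    x$pvalue[!is.na(x$pvalue) & x$pvalue == 0] <- .Machine$double.xmin
  }
  valid_allele <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  keep <- valid_allele(x$effect_allele) & valid_allele(x$other_allele) &
    x$effect_allele != x$other_allele &
    is.finite(x$beta) &
    !is.na(x$se) & is.finite(x$se) & x$se > 0 &
    !is.na(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    (is.na(x$pos) | x$pos >= 1) &
    !duplicated(x$variant_id)
  x <- x[keep, , drop = FALSE]
  x <- dplyr::arrange(x, .data$chrom, .data$pos, .data$variant_id)
  x <- x[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pvalue", "n")]
  attr(x, "trait_id") <- trait_id
  attr(x, "trait_type") <- trait_type
  attr(x, "load_report") <- c(n_input = n_input, n_kept = nrow(x),
                              n_dropped = n_input - nrow(x))
  class(x) <- c("csf_sumstats", class(x))
  x
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Accepts GWAS-SSF-like headers via `column_map`; alleles are upper-cased and
#' rows failing validation are dropped and counted (see [as_sumstats()]).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param trait_id Trait name to attach.
#' @param column_map Named character vector mapping internal names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Defaults to
#'   GWAS-SSF conventions (`chromosome`, `base_pair_location`, ...).
#' @param trait_type Passed to [as_sumstats()].
#'
#' @return A `csf_sumstats` tibble.
#' @export
read_sumstats <- function(path, trait_id, column_map = SUMSTATS_COLS,
                          trait_type = "quantitative") {
  column_map <- utils::modifyList(as.list(SUMSTATS_COLS), as.list(column_map))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  out <- tibble::tibble(.rows = nrow(raw))
  for (internal in names(SUMSTATS_COLS)) {
    file_col <- column_map[[internal]]
    if (file_col %in% names(raw)) {
      out[[internal]] <- raw[[file_col]]
    } else if (internal %in% MANDATORY_COLS) {
      abort(paste0("missing mandatory column: ", file_col),
            class = "csfmr_format_error")
    }
  }
  ss <- as_sumstats(out, trait_id = trait_id, trait_type = trait_type)
  if (nrow(ss) == 0) {
    abort(paste0("no parseable rows in ", path), class = "csfmr_empty_input")
  }
  ss
}

#' Write summary statistics to a tab-delimited file
#'
#' Columns use GWAS-SSF-like header names so that [read_sumstats()] with the
#' default `column_map` round-trips all fields (numerics written at 10
#' significant digits).
#'
#' @param x A `csf_sumstats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 10,
                                                    format = "g"))
  out <- tibble::tibble(
    variant_id = x$variant_id,
    chromosome = ifelse(is.na(x$chrom), "NA", x$chrom),
    base_pair_location = ifelse(is.na(x$pos), "NA", as.character(x$pos)),
    effect_allele = x$effect_allele,
    other_allele = x$other_allele,
    effect_allele_frequency = fmt(x$eaf),
    beta = fmt(x$beta),
    standard_error = fmt(x$se),
    p_value = fmt(x$pvalue),
    n = fmt(x$n)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a signed LD correlation matrix
#'
#' The file holds a header row of variant IDs followed by a square numeric
#' matrix of signed correlations r (clumping uses r squared). Symmetry is
#' enforced within 1e-6 by averaging with the transpose.
#'
#' @param path Path to the whitespace/tab-delimited matrix file.
#' @return A numeric matrix with variant IDs as row and column names.
#' @export
read_ld_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1), "[\t ]+")[[1]]
  header <- header[nzchar(header)]
  body <- utils::read.table(path, skip = 1, header = FALSE)
  m <- as.matrix(body)
  validate_ld_matrix(m, header)
}

validate_ld_matrix <- function(m, variant_ids = colnames(m)) {
  if (nrow(m) != ncol(m) || ncol(m) != length(variant_ids)) {
    abort("LD matrix is not square or does not match its variant-ID header",
          class = "csfmr_format_error")
  }
  m <- unname(m)
  if (any(!is.finite(m)) || any(abs(m) > 1 + 1e-6)) {
    abort("LD matrix holds a non-finite entry or |r| > 1",
          class = "csfmr_format_error")
  }
  if (max(abs(m - t(m))) > 1e-6) {
    abort("LD matrix is not symmetric within 1e-6",
          class = "csfmr_format_error")
  }
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  m[m < -1] <- -1
  diag(m) <- 1
  dimnames(m) <- list(variant_ids, variant_ids)
  m
}

#' Write an LD matrix in the format [read_ld_matrix()] accepts
#' @param m Square signed-correlation matrix with variant-ID dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  utils::write.table(formatC(m, digits = 10, format = "g"), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene regions from a BED file
#'
#' BED half-open 0-based intervals are converted to the package's 1-based
#' inclusive convention (`start + 1`, `end`), matching Ensembl GRCh37 gene
#' coordinates. Rows with `start >= end` are rejected with a warning;
#' duplicated gene IDs are an error.
#'
#' @param path Path to a BED file (chrom, start, end, gene_id, \[score\],
#'   \[strand\]).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_regions <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(raw) < 4) {
    abort("BED region file needs at least 4 columns (chrom, start, end, name)",
          class = "csfmr_format_error")
  }
  names(raw)[1:4] <- c("chrom", "start0", "end", "gene_id")
  strand <- if (ncol(raw) >= 6) raw[[6]] else "unknown"
  strand[!strand %in% c("+", "-")] <- "unknown"
  bad <- raw$start0 >= raw$end
  if (any(bad)) {
    warn(paste0(sum(bad), " BED row(s) with start >= end rejected"))
    raw <- raw[!bad, , drop = FALSE]
    strand <- strand[!bad]
  }
  if (anyDuplicated(raw$gene_id)) {
    dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
    abort(paste0("duplicated gene_id in region file: ",
                 paste(dup, collapse = ", ")),
          class = "csfmr_format_error")
  }
  tibble::tibble(
    gene_id = as.character(raw$gene_id),
    chrom = as.character(raw$chrom),
    start = as.integer(raw$start0 + 1L),
    end = as.integer(raw$end),
    strand = strand
  )
}

#' Write the consolidated screen results table
#'
#' Tab-delimited with a deterministic column order; 95% CI bounds are
#' computed as beta +/- 1.959964 * se. Missing colocalization posteriors are
#' printed as "NA".
#'
#' @param rows A data frame with at least `protein_id`, `outcome_id`,
#'   `method`, `nsnp`, `theta`, `se`, `pvalue`; optionally `qvalue` and
#'   coloc posteriors `pph0`..`pph4`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  cols <- c("protein_id", "outcome_id", "method", "nsnp", "theta", "se",
            "ci_low", "ci_high", "pvalue", "qvalue",
            "pph0", "pph1", "pph2", "pph3", "pph4")
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) > 0) {
    rows$ci_low <- rows$theta - CI_Z * rows$se
    rows$ci_high <- rows$theta + CI_Z * rows$se
  }
  for (col in cols) {
    if (!col %in% names(rows)) {
      rows[[col]] <- if (nrow(rows) > 0) NA_real_ else numeric(0)
    }
  }
  out <- rows[, cols]
  num <- vapply(out, is.numeric, logical(1)) & !names(out) %in% "nsnp"
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "NA", formatC(v, digits = 6, format = "g")))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

# two-sided 95% normal quantile used throughout for confidence intervals
CI_Z <- 1.959964
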