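#' Read a transcriptome expression table
#'
#' Reads the per-gene two-library RPKM table used for candidate screening:
#' columns `gene`, `rpkm_a` (sarcocarp library), `rpkm_b` (exocarp library),
#' with optional `target_sequence` (unigene id), `nr_description`
#' (protein annotation) and `fdr`. Rows are returned in file order and the
#' log2 ratio is left to [log2_expression_ratio()] — a precomputed ratio
#' column in the source file is never trusted.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param sep Field separator (default tab).
#' @return A data frame of expression rows with a `log2_ratio` column of
#'   `NA` placeholders.
#' @export
read_expression_table <- function(path, sep = "\t") {
  if (!file.exists(path)) ct_stop(sprintf("file not found: %s", path),
                                  "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  required <- c("gene", "rpkm_a", "rpkm_b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    ct_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")), "schema_error")
  }
  for (col in c("rpkm_a", "rpkm_b")) {
    if (nrow(df) == 0) df[[col]] <- numeric(0)
    if (!is.numeric(df[[col]])) {
      ct_stop(sprintf("column '%s' must be numeric", col), "parse_error")
    }
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      ct_stop(sprintf("negative RPKM in column '%s'", col),
              "validation_error")
    }
  }
  if (!"nr_description" %in% names(df)) {
    df[["nr_description"]] <- rep(NA_character_, nrow(df))
  }
  if (!"fdr" %in% names(df)) df[["fdr"]] <- rep(NA_real_, nrow(df))
  df[["log2_ratio"]] <- rep(NA_real_, nrow(df))
  rownames(df) <- NULL
  df
}

#' Log2 expression ratio between two libraries
#'
#' `log2(rpkm_b / rpkm_a)`: positive when the gene is more abundant in
#' library B (exocarp) than in library A (sarcocarp). Antisymmetric under
#' swapping the libraries. Undefined when either RPKM is zero.
#'
#' @param rpkm_a,rpkm_b Non-negative RPKM values (vectorised).
#' @return Numeric vector of log2 ratios.
#' @export
log2_expression_ratio <- function(rpkm_a, rpkm_b) {
  if (any(rpkm_a <= 0 | rpkm_b <= 0)) {
    ct_stop("log2 ratio undefined for zero or negative RPKM",
            "undefined_ratio")
  }
  log2(rpkm_b / rpkm_a)
}

#' @keywords internal
safe_log2_ratio <- function(rpkm_a, rpkm_b) {
  ifelse(rpkm_a > 0 & rpkm_b > 0, log2(rpkm_b / rpkm_a), NA_real_)
}

#' Classify a gene as differentially expressed
#'
#' A gene counts as differentially expressed between the two libraries when
#' `fdr <= fdr_cutoff` and `|log2_ratio| >= ratio_cutoff` (defaults 0.001
#' and 1, both thresholds inclusive as printed).
#'
#' @param log2_ratio Numeric vector of log2 expression ratios.
#' @param fdr Numeric vector of false discovery rates in `[0, 1]`.
#' @param fdr_cutoff,ratio_cutoff Classification thresholds.
#' @return Logical vector.
#' @export
classify_deg <- function(log2_ratio, fdr, fdr_cutoff = 0.001,
                         ratio_cutoff = 1) {
  if (anyNA(fdr)) {
    ct_stop("fdr missing: differential-expression call unavailable",
            "classification_unavailable")
  }
  fdr <= fdr_cutoff & abs(log2_ratio) >= ratio_cutoff
}

#' Screen candidate reference genes from a transcriptome table
#'
#' Retains genes with (a) a non-empty protein annotation (`nr_description`)
#' and (b) a near-constant expression ratio between the two libraries:
#' `|log2(rpkm_b / rpkm_a)| < ratio_cutoff` (strict inequality; default
#' 0.6). The ratio is always recomputed from the RPKM columns. Rows whose
#' ratio is undefined (a zero RPKM) are excluded. Input order is preserved
#' and the operation is idempotent.
#'
#' @param rows Data frame from [read_expression_table()].
#' @param ratio_cutoff Strict upper bound on `|log2_ratio|`.
#' @return The retained rows, `log2_ratio` column filled.
#' @export
screen_candidates <- function(rows, ratio_cutoff = 0.6) {
  rows$log2_ratio <- safe_log2_ratio(rows$rpkm_a, rows$rpkm_b)
  annotated <- !is.na(rows$nr_description) &
    nzchar(trimws(rows$nr_description))
  keep <- annotated & !is.na(rows$log2_ratio) &
    abs(rows$log2_ratio) < ratio_cutoff
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
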