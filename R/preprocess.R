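#' Average replicate Ct values into a gene-by-sample matrix
#'
#' Arithmetic mean of the replicate Ct values per (gene, sample) cell, the
#' preprocessing step shared by all three stability algorithms.
#'
#' @param x A [ct_table()].
#' @return Numeric matrix, genes in rows (order of first appearance),
#'   samples in columns.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  g <- genes(x)
  s <- samples(x)
  m <- tapply(x$ct, list(factor(x$gene, levels = g),
                         factor(x$sample_id, levels = s)),
              mean)
  if (anyNA(m)) {
    ct_stop("empty replicate set for at least one (gene, sample) cell",
            "missing_cell")
  }
  m <- matrix(m, nrow = length(g), dimnames = list(g, s))
  m
}

#' Relative quantities from mean Ct
#'
#' Transforms a mean-Ct matrix to relative quantities on a linear scale,
#' `Q = 2^-(Ct - Ct_ref)`. Under the default scheme the per-gene reference
#' is that gene's minimum Ct over samples (the geNorm input convention), so
#' the maximum Q per gene is 1 and all Q lie in (0, 1]. A fixed calibrator
#' sample may be named instead. The choice of reference cancels in every
#' downstream stability statistic (per-gene scaling invariance), so the
#' scheme is a reporting convention only.
#'
#' @param mean_ct Gene-by-sample matrix from [average_replicates()].
#' @param scheme `"min_ct_per_gene"` (default) or `"fixed_calibrator"`.
#' @param calibrator Sample (column) name, required for the fixed scheme.
#' @param efficiency Optional per-gene amplification efficiency vector
#'   (fractions, e.g. 0.95). When supplied, quantities use base
#'   `(1 + E)` instead of 2. Off by default: the plain `2^-dCt` transform
#'   is the standard input of the stability algorithms.
#' @return Matrix of the same shape with positive quantities.
#' @export
relative_quantities <- function(mean_ct,
                                scheme = c("min_ct_per_gene",
                                           "fixed_calibrator"),
                                calibrator = NULL, efficiency = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(mean_ct), !anyNA(mean_ct))
  if (scheme == "min_ct_per_gene") {
    ref <- apply(mean_ct, 1, min)
  } else {
    if (is.null(calibrator) || !calibrator %in% colnames(mean_ct)) {
      ct_stop(sprintf("unknown calibrator sample: %s",
                      if (is.null(calibrator)) "<none>" else calibrator),
              "config_error")
    }
    ref <- mean_ct[, calibrator]
  }
  base <- if (is.null(efficiency)) {
    2
  } else {
    stopifnot(length(efficiency) %in% c(1L, nrow(mean_ct)))
    1 + efficiency
  }
  dct <- mean_ct - ref
  base^(-dct)
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Ordinary least squares of mean Ct on log10 template amount. The
#' amplification efficiency follows from the slope as
#' `E = 10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' -1/log10(2) = -3.3219 and E = 1 (100%).
#'
#' @param log10_dilution Numeric vector of log10 template amounts
#'   (e.g. `0, -log10(5), -2*log10(5), ...` for a 5-fold series). Must have
#'   at least 3 distinct values.
#' @param mean_ct Mean Ct at each dilution point.
#' @return List of class `dilution_fit` with elements `slope`, `intercept`,
#'   `r_squared`, `efficiency` and the input points.
#' @export
fit_dilution_series <- function(log10_dilution, mean_ct) {
  stopifnot(length(log10_dilution) == length(mean_ct))
  if (length(log10_dilution) < 3) {
    ct_stop("a dilution series needs at least 3 points", "validation_error")
  }
  if (stats::var(log10_dilution) == 0) {
    ct_stop("zero variance in dilution factors: degenerate fit",
            "degenerate_fit")
  }
  fit <- stats::lm(mean_ct ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  # R^2 computed directly (summary.lm warns on numerically exact fits)
  sst <- sum((mean_ct - mean(mean_ct))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else as.numeric(ssr == 0)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 log10_dilution = log10_dilution,
                 mean_ct = mean_ct),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf(
    "Standard curve: slope %.4f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Primer quality-control gate
#'
#' Passes a fitted standard curve when the amplification efficiency is near
#' 100% (`eff_low <= E <= eff_high`) and the curve is tight
#' (`R^2 > r2_min`). Failures are enumerated in `reasons`.
#'
#' @param fit A [fit_dilution_series()] result.
#' @param eff_low,eff_high Efficiency window (fractions; defaults 0.90 and
#'   1.10).
#' @param r2_min Strict lower bound on R-squared (default 0.99).
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
primer_qc_gate <- function(fit, eff_low = 0.90, eff_high = 1.10,
                           r2_min = 0.99) {
  reasons <- character(0)
  if (fit$efficiency < eff_low || fit$efficiency > eff_high) {
    reasons <- c(reasons, sprintf(
      "efficiency %.3f outside [%.2f, %.2f]", fit$efficiency,
      eff_low, eff_high))
  }
  if (!(fit$r_squared > r2_min)) {
    reasons <- c(reasons, sprintf("R^2 %.4f not > %.2f", fit$r_squared,
                                  r2_min))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' RNA purity gate
#'
#' Absorbance-ratio check on extracted RNA: `1.8 <= A260/A280 <= 2.0`
#' (inclusive) and `A260/A230` within `tol` of 2.0.
#'
#' @param a260_280,a260_230 Non-negative absorbance ratios.
#' @param tol Tolerance on the A260/A230 distance from 2.0 (default 0.2).
#' @return Logical.
#' @export
rna_qc_gate <- function(a260_280, a260_230, tol = 0.2) {
  a260_280 >= 1.8 & a260_280 <= 2.0 &
    a260_230 >= 2.0 - tol & a260_230 <= 2.0 + tol
}

#' Per-gene Ct distribution summaries
#'
#' Five-number summary of mean Ct per gene across samples plus the range in
#' cycles, the descriptive view that flags weakly expressed genes (high
#' mean Ct) and genes with high expression variation. Quartiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param mean_ct Gene-by-sample matrix from [average_replicates()].
#' @param high_variation_cycles Range threshold above which a gene is
#'   flagged as highly variable (default 6 cycles, strict).
#' @return Data frame with one row per gene: `gene`, `min_ct`, `q25`,
#'   `median_ct`, `q75`, `max_ct`, `mean_ct`, `range_cycles`,
#'   `high_variation`; attributes `global_min` and `global_max`.
#' @export
ct_summary <- function(mean_ct, high_variation_cycles = 6) {
  stopifnot(is.matrix(mean_ct))
  qs <- t(apply(mean_ct, 1, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), type = 7))
  out <- data.frame(
    gene = rownames(mean_ct),
    min_ct = qs[, 1], q25 = qs[, 2], median_ct = qs[, 3],
    q75 = qs[, 4], max_ct = qs[, 5],
    mean_ct = rowMeans(mean_ct),
    range_cycles = qs[, 5] - qs[, 1],
    stringsAsFactors = FALSE)
  out$high_variation <- out$range_cycles > high_variation_cycles
  rownames(out) <- NULL
  attr(out, "global_min") <- min(mean_ct)
  attr(out, "global_max") <- max(mean_ct)
  out
}
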