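#' Relative expression of a target gene by the delta-delta-Ct method
#'
#' Per sample: `dCt = Ct_target - mean(Ct_refs)` (the arithmetic mean of
#' the reference genes' Ct, equivalent to normalizing by the geometric mean
#' of their linear quantities), `ddCt = dCt - dCt_calibrator`, relative
#' expression `2^-ddCt`. The calibrator point has relative expression 1 by
#' construction. Replicate-level dCt values propagate to a per-point
#' standard deviation of `2^-ddCt`; replicates are paired by replicate
#' index within each sample, the usual layout of a qPCR plate.
#'
#' @param ct A [ct_table()] containing the target and reference genes.
#' @param target Target gene symbol.
#' @param refs Character vector of one or more reference genes.
#' @param calibrator Sample id used as the ddCt baseline (e.g. the 0 h
#'   sample of a time course, or the first organ).
#' @return Object of class `ddct_profile`: data frame `sample_id`,
#'   `label`, `rel_expr`, `sd`, plus a list column `replicates` of
#'   replicate-level relative expressions; attributes `target`, `refs`,
#'   `calibrator`.
#' @examples
#' set.seed(3)
#' sim <- simulate_ct_panel(panel_spec("organ", n_genes = 4, seed = 3))
#' ct <- sim$ct
#' ddct_profile(ct, target = genes(ct)[1], refs = genes(ct)[2:3],
#'              calibrator = samples(ct)[1])
#' @export
ddct_profile <- function(ct, target, refs, calibrator) {
  stopifnot(inherits(ct, "ct_table"))
  if (!length(refs)) ct_stop("reference gene set is empty", "config_error")
  missing_genes <- setdiff(c(target, refs), genes(ct))
  if (length(missing_genes)) {
    ct_stop(sprintf("gene(s) not in table: %s",
                    paste(missing_genes, collapse = ", ")), "config_error")
  }
  if (!calibrator %in% samples(ct)) {
    ct_stop(sprintf("calibrator sample not in table: %s", calibrator),
            "config_error")
  }
  mean_ct <- average_replicates(ct)
  s <- samples(ct)
  dct <- mean_ct[target, s] - colMeans(mean_ct[refs, s, drop = FALSE])
  ddct <- dct - dct[calibrator]
  rel <- 2^(-ddct)

  # replicate-level propagation: pair replicates by index within sample
  rep_rel <- lapply(s, function(smp) {
    sub <- ct[ct$sample_id == smp, , drop = FALSE]
    reps <- sort(unique(sub$replicate[sub$gene == target]))
    vals <- vapply(reps, function(rr) {
      tgt <- sub$ct[sub$gene == target & sub$replicate == rr]
      rf <- vapply(refs, function(g) {
        v <- sub$ct[sub$gene == g & sub$replicate == rr]
        if (length(v)) v[1] else NA_real_
      }, numeric(1))
      if (!length(tgt) || anyNA(rf)) return(NA_real_)
      2^(-((tgt[1] - mean(rf)) - dct[calibrator]))
    }, numeric(1))
    vals[!is.na(vals)]
  })
  sds <- vapply(rep_rel, function(v) {
    if (length(v) >= 2) stats::sd(v) else NA_real_
  }, numeric(1))

  label <- vapply(s, function(smp) {
    row <- ct[match(smp, ct$sample_id), , drop = FALSE]
    if ("time_h" %in% names(ct) && is.finite(row$time_h)) {
      sprintf("%g h", row$time_h)
    } else smp
  }, character(1))

  out <- data.frame(sample_id = s, label = unname(label),
                    rel_expr = unname(rel), sd = unname(sds),
                    stringsAsFactors = FALSE)
  out$replicates <- rep_rel
  structure(out, target = target, refs = refs, calibrator = calibrator,
            class = c("ddct_profile", "data.frame"))
}

#' @export
print.ddct_profile <- function(x, digits = 3, ...) {
  cat(sprintf("ddCt profile of %s vs %s (calibrator %s)\n",
              attr(x, "target"), paste(attr(x, "refs"), collapse = " + "),
              attr(x, "calibrator")))
  df <- data.frame(label = x$label,
                   rel_expr = round(x$rel_expr, digits),
                   sd = round(x$sd, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare two expression profiles obtained with different references
#'
#' The validation step of reference-gene selection: the same target
#' quantified against two reference choices should give concordant
#' profiles if both references are stable. Emits each profile's
#' descending-order string (points within `tol` relative difference are
#' joined by an approximately-equal sign), the Spearman rank correlation
#' between the two profiles, and the per-point fold ratio
#' `p1 / p2`.
#'
#' @param p1,p2 [ddct_profile()] objects over the same point labels.
#' @param tol Relative tolerance for calling two adjacent points
#'   approximately equal in the order string (default 0.10).
#' @return List with `order1`, `order2` (character), `rank_correlation`
#'   (Spearman), `fold_ratio` (named numeric, p1/p2 per point).
#' @export
compare_profiles <- function(p1, p2, tol = 0.10) {
  if (!identical(p1$label, p2$label)) {
    ct_stop("profiles have different point labels", "integrity_error")
  }
  order_string <- function(p) {
    ord <- order(-p$rel_expr)
    lab <- p$label[ord]
    val <- p$rel_expr[ord]
    sep <- vapply(seq_len(length(val) - 1), function(i) {
      denom <- max(val[i], val[i + 1])
      if (denom == 0 || (val[i] - val[i + 1]) / denom <= tol) {
        " ≈ "
      } else " > "
    }, character(1))
    paste0(lab, c(sep, ""), collapse = "")
  }
  rho <- stats::cor(p1$rel_expr, p2$rel_expr, method = "spearman")
  ratio <- p1$rel_expr / p2$rel_expr
  names(ratio) <- p1$label
  list(order1 = order_string(p1), order2 = order_string(p2),
       rank_correlation = rho, fold_ratio = ratio)
}

#' Two-sample t-test on replicate relative expressions
#'
#' Annotates profile points with significance (two-sided Welch t-test);
#' the degenerate case of two identical zero-variance groups returns
#' p = 1, and separated zero-variance groups return p = 0.
#'
#' @param point_a,point_b Numeric vectors of replicate-level values
#'   (>= 2 each).
#' @return Two-sided p-value.
#' @export
replicate_t_test <- function(point_a, point_b) {
  stopifnot(length(point_a) >= 2, length(point_b) >= 2)
  if (stats::sd(point_a) == 0 && stats::sd(point_b) == 0) {
    return(if (mean(point_a) == mean(point_b)) 1 else 0)
  }
  stats::t.test(point_a, point_b)$p.value
}
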