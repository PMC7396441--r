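#' BestKeeper-style descriptive statistics of raw Ct
#'
#' Per-gene dispersion summary on raw mean Ct: geometric mean, arithmetic
#' mean, min, max, dispersion and CV%. The default dispersion is the sample
#' standard deviation (n-1 denominator) about the arithmetic mean; the
#' original applet's mean absolute deviation about the geometric mean is
#' available via `sd_mode = "mad_geomean"` for compatibility studies. A
#' gene whose dispersion exceeds 1 cycle is flagged as unstable and
#' excluded from the index.
#'
#' @param mean_ct Gene-by-sample matrix from [average_replicates()].
#' @param sd_mode `"sd"` (default) or `"mad_geomean"`.
#' @param sd_cutoff Exclusion threshold in cycles (default 1, strict `>`).
#' @return Data frame: `gene`, `geo_mean_ct`, `arith_mean_ct`, `min_ct`,
#'   `max_ct`, `sd_ct`, `cv_pct`, `excluded`, `reason`.
#' @export
bestkeeper_descriptives <- function(mean_ct,
                                    sd_mode = c("sd", "mad_geomean"),
                                    sd_cutoff = 1) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(is.matrix(mean_ct), all(mean_ct > 0))
  geo <- exp(rowMeans(log(mean_ct)))
  ari <- rowMeans(mean_ct)
  disp <- if (sd_mode == "sd") {
    apply(mean_ct, 1, stats::sd)
  } else {
    rowMeans(abs(mean_ct - geo))
  }
  excluded <- disp > sd_cutoff
  out <- data.frame(
    gene = rownames(mean_ct),
    geo_mean_ct = unname(geo),
    arith_mean_ct = unname(ari),
    min_ct = apply(mean_ct, 1, min),
    max_ct = apply(mean_ct, 1, max),
    sd_ct = unname(disp),
    cv_pct = unname(100 * disp / ari),
    excluded = unname(excluded),
    reason = ifelse(excluded, sprintf("SD > %g", sd_cutoff), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reduce the gene panel to the BestKeeper input limit
#'
#' BestKeeper analyzes at most `limit` genes at a time; when the panel is
#' larger, the genes with the worst combined geNorm-rank + NormFinder-rank
#' sum are removed first (ties broken by the worse geNorm rank, then later
#' input order).
#'
#' @param genorm_fit A [genorm()] fit.
#' @param normfinder_fit A [normfinder()] fit over the same genes.
#' @param limit Maximum panel size (default 10).
#' @return Character vector of retained genes, in original input order.
#' @export
select_input_genes <- function(genorm_fit, normfinder_fit, limit = 10) {
  g_rank <- stats::setNames(genorm_fit$stability$rank,
                            genorm_fit$stability$gene)
  n_rank <- stats::setNames(normfinder_fit$stability$rank,
                            normfinder_fit$stability$gene)
  universe <- names(g_rank)
  if (!setequal(universe, names(n_rank))) {
    ct_stop("geNorm and NormFinder rankings cover different gene sets",
            "integrity_error")
  }
  if (length(universe) <= limit) return(universe)
  score <- g_rank[universe] + n_rank[universe]
  ord <- order(-score, -g_rank[universe], -seq_along(universe))
  drop <- universe[ord][seq_len(length(universe) - limit)]
  setdiff(universe, drop)
}

#' BestKeeper index and per-gene correlations
#'
#' Excludes genes whose Ct dispersion exceeds `sd_cutoff` (default 1
#' cycle), forms the BestKeeper index as the per-sample geometric mean of
#' the retained genes' Ct, then correlates every input gene's Ct with the
#' index (Pearson r, two-sided p-value from the exact t-transform with n-2
#' degrees of freedom). Genes excluded by the SD filter, or with p > 0.05,
#' are flagged invalid but still reported with their r. Valid genes are
#' ranked by descending r.
#'
#' @param mean_ct Gene-by-sample matrix; rows restricted to `genes`.
#' @param genes Genes to analyze (default all rows), e.g. from
#'   [select_input_genes()].
#' @param sd_mode,sd_cutoff Passed to [bestkeeper_descriptives()].
#' @param p_cutoff Significance threshold on the correlation (default
#'   0.05).
#' @return Object of class `bestkeeper_fit`: \describe{
#'   \item{descriptives}{per-gene dispersion table.}
#'   \item{index}{per-sample geometric-mean Ct of retained genes.}
#'   \item{stability}{data frame `gene`, `r`, `p_value`, `sd_ct`, `valid`,
#'     `reason`, `rank` (rank NA for invalid genes; valid genes ranked 1..n
#'     by descending r, ties sharing order of appearance).}
#' }
#' @export
bestkeeper <- function(mean_ct, genes = rownames(mean_ct),
                       sd_mode = c("sd", "mad_geomean"), sd_cutoff = 1,
                       p_cutoff = 0.05) {
  if (inherits(mean_ct, "ct_table")) mean_ct <- average_replicates(mean_ct)
  sd_mode <- match.arg(sd_mode)
  m <- mean_ct[genes, , drop = FALSE]
  desc <- bestkeeper_descriptives(m, sd_mode = sd_mode,
                                  sd_cutoff = sd_cutoff)
  retained <- desc$gene[!desc$excluded]
  if (length(retained) < 2) {
    ct_stop("fewer than 2 genes retained after the SD filter: index degenerate",
            "degenerate_index")
  }
  index <- exp(colMeans(log(m[retained, , drop = FALSE])))

  r <- p <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (stats::sd(m[i, ]) == 0 || stats::sd(index) == 0) {
      r[i] <- if (stats::sd(m[i, ]) == 0 && stats::sd(index) == 0) 1 else NA
      p[i] <- if (is.na(r[i])) NA else 0
    } else {
      ht <- stats::cor.test(m[i, ], index, method = "pearson")
      r[i] <- unname(ht$estimate)
      p[i] <- ht$p.value
    }
  }
  excluded <- desc$excluded
  nonsig <- !excluded & !is.na(p) & p > p_cutoff
  valid <- !excluded & !nonsig & !is.na(r)
  reason <- character(nrow(m))
  reason[excluded] <- sprintf("SD > %g", sd_cutoff)
  reason[nonsig] <- sprintf("P > %g", p_cutoff)

  # valid genes rank 1..n_valid by descending r; invalid genes continue
  # the ordering below them (parenthesized in reports)
  rank_col <- rep(NA_integer_, nrow(m))
  rank_col[valid] <- rank(-r[valid], ties.method = "min")
  if (any(!valid)) {
    r_inv <- r[!valid]
    r_inv[is.na(r_inv)] <- -Inf
    rank_col[!valid] <- sum(valid) + rank(-r_inv, ties.method = "min")
  }
  stability <- data.frame(gene = desc$gene, r = r, p_value = p,
                          sd_ct = desc$sd_ct, valid = valid,
                          reason = reason, rank = rank_col,
                          stringsAsFactors = FALSE)
  structure(list(descriptives = desc, index = index,
                 stability = stability,
                 retained = retained),
            class = "bestkeeper_fit")
}

#' @export
print.bestkeeper_fit <- function(x, ...) {
  cat("BestKeeper-style stability analysis\n")
  v <- x$stability[x$stability$valid, ]
  if (nrow(v)) {
    top <- v$gene[which.min(v$rank)]
    cat(sprintf("  most stable: %s (r = %.3f)\n", top,
                v$r[which.min(v$rank)]))
  }
  nexcl <- sum(!x$stability$valid)
  if (nexcl) {
    cat(sprintf("  %d gene(s) flagged invalid (SD or P criterion)\n",
                nexcl))
  }
  invisible(x)
}

#' Consensus ranking across stability methods
#'
#' Aggregates per-method gene ranks by their geometric mean. Ranks (not raw
#' M/S/r values) are aggregated because the three statistics live on
#' incomparable scales, with r inverted. A gene invalid in a method (e.g.
#' a parenthesized BestKeeper entry) contributes nothing for that method;
#' a gene valid in no method is placed last and flagged. Final ranks ascend
#' in the geometric-mean rank, ties broken by geNorm rank, then input
#' order.
#'
#' @param rankings Named list of per-method rank vectors (named numeric
#'   vectors, gene -> rank, `NA` = invalid in that method). Typically
#'   `list(genorm = ..., normfinder = ..., bestkeeper = ...)`. At least 2
#'   methods over one gene universe.
#' @return Data frame of class `consensus_ranking`: `gene`, one
#'   `rank_<method>` column per method, `geo_mean_rank`, `final_rank`,
#'   `n_methods`, `flagged`.
#' @export
consensus_ranking <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 2)
  universe <- names(rankings[[1]])
  for (rk in rankings) {
    if (!setequal(names(rk), universe)) {
      ct_stop("method rankings cover different gene universes",
              "integrity_error")
    }
  }
  rank_mat <- vapply(rankings, function(rk) unname(rk[universe]),
                     numeric(length(universe)))
  rank_mat <- matrix(rank_mat, nrow = length(universe),
                     dimnames = list(universe, names(rankings)))
  geo <- apply(rank_mat, 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) NA_real_ else exp(mean(log(z)))
  })
  n_methods <- rowSums(!is.na(rank_mat))
  flagged <- n_methods == 0
  genorm_rank <- if ("genorm" %in% colnames(rank_mat)) {
    rank_mat[, "genorm"]
  } else {
    rank_mat[, 1]
  }
  ord_key <- ifelse(is.na(geo), Inf, geo)
  tie1 <- ifelse(is.na(genorm_rank), Inf, genorm_rank)
  final <- integer(length(universe))
  final[order(ord_key, tie1, seq_along(universe))] <-
    seq_along(universe)
  out <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (m in colnames(rank_mat)) out[[paste0("rank_", m)]] <- rank_mat[, m]
  out$geo_mean_rank <- geo
  out$final_rank <- final
  out$n_methods <- n_methods
  out$flagged <- flagged
  rownames(out) <- NULL
  class(out) <- c("consensus_ranking", "data.frame")
  out
}

#' Write a combined stability report
#'
#' One CSV over the shared gene universe with, per method, a value column
#' and a rank column, plus the consensus geometric-mean rank and final
#' rank. Invalid entries are rendered with a parenthesized rank and the
#' reason that fired (SD or P criterion), so the report is explicit about
#' why a gene was set aside.
#'
#' @param stability_tables Named list of data frames with columns `gene`,
#'   a value column (`m`, `s` or `r`), optional `valid`/`reason`, and
#'   `rank`.
#' @param consensus A [consensus_ranking()] data frame.
#' @param path Output CSV path.
#' @return Invisibly, the assembled report data frame.
#' @export
write_stability_report <- function(stability_tables, consensus, path) {
  universe <- consensus$gene
  report <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (method in names(stability_tables)) {
    tab <- stability_tables[[method]]
    if (!setequal(tab$gene, universe)) {
      ct_stop(sprintf("method '%s' covers a different gene set", method),
              "integrity_error")
    }
    idx <- match(universe, tab$gene)
    value_col <- intersect(c("m", "s", "r", "value"), names(tab))[1]
    report[[paste0(method, "_value")]] <- round(tab[[value_col]][idx], 4)
    valid <- if ("valid" %in% names(tab)) tab$valid[idx] else
      rep(TRUE, length(idx))
    rk <- tab$rank[idx]
    reason <- if ("reason" %in% names(tab)) tab$reason[idx] else ""
    shown <- ifelse(valid, as.character(rk),
                    trimws(sprintf("(%s) %s",
                                   ifelse(is.na(rk), "-",
                                          as.character(rk)),
                                   reason)))
    report[[paste0(method, "_rank")]] <- shown
  }
  report$geo_mean_rank <- round(consensus$geo_mean_rank, 4)
  report$final_rank <- consensus$final_rank
  utils::write.csv(report, path, row.names = FALSE, quote = TRUE)
  invisible(report)
}
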