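#' Fit a reference-gene stability analysis
#'
#' The package's main entry point: runs the three stability algorithms
#' (geNorm, model-based variance decomposition, BestKeeper-style index
#' correlation) on one replicate-level Ct table and aggregates their
#' rankings into a geometric-mean consensus. The BestKeeper step receives
#' at most `bestkeeper_limit` genes, discarding the jointly worst genes
#' under geNorm + NormFinder when the panel is larger (the applet's
#' historical 10-gene limit); discarded genes stay in the consensus
#' through their other two ranks.
#'
#' @param ct A [ct_table()].
#' @param groups Sample grouping for the model-based method: `"tissue"`,
#'   `"group"`, `"time"` (uses the corresponding metadata column),
#'   `"none"`, or an explicit vector mapping samples to groups. Default
#'   `"auto"`: tissue when that column has 2+ levels, otherwise ungrouped.
#' @param v_threshold geNorm pairwise-variation cutoff (default 0.15).
#' @param bestkeeper_limit BestKeeper panel limit (default 10).
#' @param sd_mode,sd_cutoff,p_cutoff Passed to [bestkeeper()].
#' @return Object of class `ref_stability` with components `genorm`,
#'   `normfinder`, `bestkeeper` (the three fits), `consensus`
#'   (a [consensus_ranking()] data frame), `mean_ct`, `genes`, `samples`,
#'   `groups`.
#' @seealso [genorm()], [normfinder()], [bestkeeper()],
#'   [consensus_ranking()], [run_stability_pipeline()]
#' @examples
#' sim <- simulate_ct_panel(panel_spec("stress", n_genes = 8, seed = 11))
#' fit <- ref_stability(sim$ct)
#' fit
#' head(summary(fit))
#' @export
ref_stability <- function(ct, groups = "auto", v_threshold = 0.15,
                          bestkeeper_limit = 10,
                          sd_mode = c("sd", "mad_geomean"), sd_cutoff = 1,
                          p_cutoff = 0.05) {
  stopifnot(inherits(ct, "ct_table"))
  sd_mode <- match.arg(sd_mode)
  if (length(genes(ct)) < 3) {
    ct_stop("stability analysis needs at least 3 genes",
            "insufficient_data")
  }
  if (length(samples(ct)) < 2) {
    ct_stop("stability analysis needs at least 2 samples",
            "insufficient_data")
  }
  mean_ct <- average_replicates(ct)
  q <- relative_quantities(mean_ct)

  grp <- resolve_groups(ct, groups)
  g_fit <- genorm(q, v_threshold = v_threshold)
  n_fit <- normfinder(-mean_ct, groups = grp)
  bk_genes <- select_input_genes(g_fit, n_fit, limit = bestkeeper_limit)
  b_fit <- bestkeeper(mean_ct, genes = bk_genes, sd_mode = sd_mode,
                      sd_cutoff = sd_cutoff, p_cutoff = p_cutoff)

  universe <- genes(ct)
  g_rank <- stats::setNames(g_fit$stability$rank, g_fit$stability$gene)
  n_rank <- stats::setNames(n_fit$stability$rank, n_fit$stability$gene)
  b_rank <- stats::setNames(rep(NA_real_, length(universe)), universe)
  bs <- b_fit$stability
  b_rank[bs$gene[bs$valid]] <- bs$rank[bs$valid]
  cons <- consensus_ranking(list(genorm = g_rank[universe],
                                 normfinder = n_rank[universe],
                                 bestkeeper = b_rank[universe]))

  structure(list(genorm = g_fit, normfinder = n_fit, bestkeeper = b_fit,
                 consensus = cons, mean_ct = mean_ct, q = q,
                 genes = universe, samples = samples(ct), groups = grp),
            class = "ref_stability")
}

#' @keywords internal
resolve_groups <- function(ct, groups) {
  s <- samples(ct)
  meta <- function(col) {
    vapply(s, function(x) as.character(ct[[col]][match(x, ct$sample_id)]),
           character(1))
  }
  if (is.character(groups) && length(groups) == 1) {
    if (groups == "none") return(NULL)
    if (groups == "auto") {
      if ("tissue" %in% names(ct) &&
          length(unique(ct$tissue)) >= 2) return(meta("tissue"))
      return(NULL)
    }
    col <- switch(groups, tissue = "tissue", group = "group",
                  time = "time_h",
                  ct_stop(sprintf("unknown grouping: %s", groups),
                          "config_error"))
    if (!col %in% names(ct)) {
      ct_stop(sprintf("metadata column '%s' absent", col), "config_error")
    }
    return(meta(col))
  }
  if (!is.null(names(groups))) return(as.character(groups[s]))
  stopifnot(length(groups) == length(s))
  as.character(groups)
}

#' @export
print.ref_stability <- function(x, ...) {
  cat(sprintf(
    "Reference-gene stability analysis: %d genes, %d samples%s\n",
    length(x$genes), length(x$samples),
    if (is.null(x$groups)) "" else
      sprintf(" (%d groups)", length(unique(x$groups)))))
  cons <- x$consensus[order(x$consensus$final_rank), ]
  cat(sprintf("  consensus top 3: %s\n",
              paste(utils::head(cons$gene, 3), collapse = ", ")))
  cat(sprintf("  geNorm pair: %s (M = %.3f); optimal n = %d\n",
              paste(x$genorm$final_pair, collapse = "/"),
              x$genorm$stability$m[
                match(x$genorm$final_pair[1], x$genorm$stability$gene)],
              x$genorm$optimal_n))
  cat(sprintf("  NormFinder best: %s (S = %.3f)\n",
              x$normfinder$best_gene, min(x$normfinder$stability$s)))
  bv <- x$bestkeeper$stability
  top_b <- bv$gene[bv$valid][which.min(bv$rank[bv$valid])]
  if (length(top_b)) {
    cat(sprintf("  BestKeeper best: %s (r = %.3f)\n", top_b,
                bv$r[match(top_b, bv$gene)]))
  }
  invisible(x)
}

#' @export
summary.ref_stability <- function(object, ...) {
  cons <- object$consensus
  g <- object$genorm$stability
  n <- object$normfinder$stability
  b <- object$bestkeeper$stability
  out <- data.frame(gene = cons$gene, stringsAsFactors = FALSE)
  out$genorm_m <- g$m[match(cons$gene, g$gene)]
  out$genorm_rank <- cons$rank_genorm
  out$normfinder_s <- n$s[match(cons$gene, n$gene)]
  out$normfinder_rank <- cons$rank_normfinder
  out$bestkeeper_r <- b$r[match(cons$gene, b$gene)]
  out$bestkeeper_rank <- cons$rank_bestkeeper
  out$geo_mean_rank <- cons$geo_mean_rank
  out$final_rank <- cons$final_rank
  out[order(out$final_rank), ]
}

#' @export
coef.ref_stability <- function(object, ...) {
  stats::setNames(object$consensus$geo_mean_rank, object$consensus$gene)
}

#' @export
plot.ref_stability <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  plot(x$genorm, which = "m")
  plot(x$genorm, which = "v")
  invisible(x)
}

#' Recommended reference genes from a fit
#'
#' The `optimal_n` top consensus genes (n from the geNorm V criterion).
#'
#' @param fit A [ref_stability()] fit.
#' @return Character vector of gene symbols, best first.
#' @export
recommended_genes <- function(fit) {
  stopifnot(inherits(fit, "ref_stability"))
  cons <- fit$consensus[order(fit$consensus$final_rank), ]
  utils::head(cons$gene, fit$genorm$optimal_n)
}

#' Run the stability workflow over declared sample subsets
#'
#' Reruns [ref_stability()] on each declarative subset of a Ct table
#' (filters over tissue / condition group / time metadata), the way a
#' reference-gene study analyses "all stresses", each stress alone, and
#' the organ panel. Subsets selecting fewer than 3 genes or 2 samples, or
#' failing outright, are skipped with a warning rather than aborting the
#' whole run.
#'
#' @param ct A [ct_table()].
#' @param subsets Named list; each element a list of filter arguments for
#'   [ct_subset()] (`tissue`, `group`, `time_h`, `samples`), or `NULL` for
#'   no filtering.
#' @param ... Passed to [ref_stability()].
#' @return Named list of `ref_stability` fits (skipped subsets are absent).
#' @examples
#' sim <- simulate_ct_panel(panel_spec("stress", n_genes = 6, seed = 5))
#' fits <- run_stability_pipeline(sim$ct,
#'   subsets = list(all = NULL, NaCl = list(group = "NaCl")))
#' names(fits)
#' @export
run_stability_pipeline <- function(ct, subsets, ...) {
  stopifnot(inherits(ct, "ct_table"), is.list(subsets),
            !is.null(names(subsets)))
  fits <- list()
  for (label in names(subsets)) {
    flt <- subsets[[label]]
    res <- tryCatch({
      sub <- if (is.null(flt)) ct else do.call(ct_subset, c(list(ct), flt))
      if (length(genes(sub)) < 3 || length(samples(sub)) < 2) {
        ct_stop("subset too small (need >= 3 genes and >= 2 samples)",
                "subset_error")
      }
      ref_stability(sub, ...)
    }, ctstab_error = function(e) {
      ct_warn(sprintf("subset '%s' skipped: %s", label,
                      conditionMessage(e)), "subset_skipped")
      NULL
    })
    if (!is.null(res)) fits[[label]] <- res
  }
  fits
}
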