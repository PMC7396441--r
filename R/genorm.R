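#' Pairwise variation between two genes
#'
#' The geNorm building block: the standard deviation (n-1 denominator)
#' across samples of `log2(Q_j / Q_k)`. Zero when two genes have
#' proportional quantity profiles; symmetric in its two arguments.
#'
#' @param q Quantity matrix (genes x samples, all positive), e.g. from
#'   [relative_quantities()].
#' @param gene_j,gene_k Row names of the two genes.
#' @return Non-negative scalar.
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  if (ncol(q) < 2) {
    ct_stop("pairwise variation needs at least 2 samples",
            "insufficient_data")
  }
  stats::sd(log2(q[gene_j, ] / q[gene_k, ]))
}

#' geNorm M-value of one gene within a subset
#'
#' The mean of the pairwise variations of `gene_j` against every other gene
#' in `subset`. Lower M means more stable expression.
#'
#' @param q Quantity matrix (genes x samples, positive).
#' @param gene_j Gene to score; must belong to `subset`.
#' @param subset Character vector of at least two gene names.
#' @return Non-negative scalar M.
#' @export
m_value <- function(q, gene_j, subset = rownames(q)) {
  if (length(subset) < 2) {
    ct_stop("M-value needs a subset of at least 2 genes",
            "insufficient_data")
  }
  stopifnot(gene_j %in% subset)
  others <- setdiff(subset, gene_j)
  lr <- log2(sweep(q[others, , drop = FALSE], 2, q[gene_j, ], "/"))
  mean(apply(lr, 1, stats::sd))
}

#' @keywords internal
m_values_all <- function(q, subset) {
  vapply(subset, function(g) m_value(q, g, subset), numeric(1))
}

#' geNorm stability analysis
#'
#' Full geNorm procedure on a quantity matrix: M-values for the complete
#' gene set, stepwise exclusion of the least stable gene (highest M, ties
#' broken by removing the gene later in input order) until two genes remain,
#' per-sample normalization factors `NF_n` (geometric mean of the top-n
#' genes' quantities), and the pairwise-variation curve `V_n/n+1`
#' (standard deviation over samples of `log2(NF_n / NF_n+1)`) that
#' determines the optimal number of reference genes: the smallest `n` with
#' `V_n/n+1 <= v_threshold`.
#'
#' @param q Quantity matrix (genes x samples, positive), at least 3 genes,
#'   or a [ct_table()] (converted via [average_replicates()] and
#'   [relative_quantities()]).
#' @param v_threshold Pairwise-variation cutoff (default 0.15): `n` genes
#'   suffice when `V_n/n+1` is no more than this.
#' @return Object of class `genorm_fit` with components:
#'   \describe{
#'     \item{stability}{data frame `gene`, `m`, `rank`: each gene's M at
#'       the exclusion round of its removal (the two final genes share the
#'       final-round M and joint rank 1).}
#'     \item{full_set_m}{named vector of M over the complete gene set.}
#'     \item{exclusion_order}{genes in order of removal, least stable
#'       first.}
#'     \item{ranking}{genes from most to least stable.}
#'     \item{final_pair}{the two most stable genes.}
#'     \item{nf}{matrix of normalization factors, one row per n = 2..k.}
#'     \item{v}{named vector `V2/3, V3/4, ...`.}
#'     \item{optimal_n}{smallest adequate reference-gene count.}
#'     \item{v_warning}{TRUE when no V met the threshold and `optimal_n`
#'       fell back to the full gene count.}
#'   }
#' @examples
#' set.seed(1)
#' ct <- simulate_ct_panel(panel_spec("organ", n_genes = 6, seed = 1))$ct
#' fit <- genorm(relative_quantities(average_replicates(ct)))
#' fit$final_pair
#' @export
genorm <- function(q, v_threshold = 0.15) {
  if (inherits(q, "ct_table")) {
    q <- relative_quantities(average_replicates(q))
  }
  stopifnot(is.matrix(q), all(q > 0))
  k <- nrow(q)
  if (k < 3) ct_stop("geNorm needs at least 3 genes", "insufficient_data")
  all_genes <- rownames(q)

  full_m <- m_values_all(q, all_genes)

  remaining <- all_genes
  exclusion_order <- character(0)
  reported_m <- stats::setNames(numeric(k), all_genes)
  round_m <- list()
  while (length(remaining) > 2) {
    m <- m_values_all(q, remaining)
    round_m[[length(round_m) + 1L]] <- m
    # ties on the maximum broken toward the gene later in input order
    worst_idx <- max(which(m == max(m)))
    worst <- remaining[worst_idx]
    reported_m[worst] <- m[worst_idx]
    exclusion_order <- c(exclusion_order, worst)
    remaining <- remaining[-worst_idx]
  }
  # in a 2-gene subset each gene's M is the single pairwise variation:
  # compute it once so the pair shares one value bit-for-bit
  pair_m <- pairwise_variation(q, remaining[1], remaining[2])
  final_m <- stats::setNames(rep(pair_m, 2), remaining)
  round_m[[length(round_m) + 1L]] <- final_m
  reported_m[remaining] <- pair_m

  ranking <- c(remaining, rev(exclusion_order))
  rank_vec <- stats::setNames(c(1L, 1L, seq(3L, k)), ranking)

  stability <- data.frame(gene = all_genes,
                          m = unname(reported_m[all_genes]),
                          rank = unname(rank_vec[all_genes]),
                          stringsAsFactors = FALSE)

  # normalization factors for n = 2..k over the stability ranking
  nf <- t(vapply(2:k, function(n) {
    normalization_factor(q, ranking, n)
  }, numeric(ncol(q))))
  rownames(nf) <- paste0("NF", 2:k)

  vres <- v_criterion(q, ranking, v_threshold = v_threshold, nf = nf)

  structure(list(stability = stability,
                 full_set_m = full_m,
                 exclusion_order = exclusion_order,
                 ranking = ranking,
                 final_pair = remaining,
                 round_m = round_m,
                 nf = nf,
                 v = vres$v,
                 optimal_n = vres$optimal_n,
                 v_warning = vres$warning,
                 v_threshold = v_threshold),
            class = "genorm_fit")
}

#' Per-sample normalization factor
#'
#' Geometric mean, per sample, of the quantities of the `n` top-ranked
#' genes. Requires `n >= 2`: a single-gene "factor" defeats the purpose of
#' multi-gene normalization.
#'
#' @param q Quantity matrix (genes x samples, positive).
#' @param ranking Character vector of genes, most stable first.
#' @param n Number of top genes to combine (2..number of genes).
#' @return Named numeric vector over samples.
#' @export
normalization_factor <- function(q, ranking, n) {
  if (n < 2 || n > length(ranking)) {
    ct_stop(sprintf("n = %d out of range [2, %d]", n, length(ranking)),
            "validation_error")
  }
  top <- ranking[seq_len(n)]
  exp(colMeans(log(q[top, , drop = FALSE])))
}

#' Pairwise-variation criterion for the number of reference genes
#'
#' `V_n/n+1 = sd_samples(log2(NF_n / NF_n+1))` for n = 2..k-1; the optimal
#' reference-gene count is the smallest n with `V_n/n+1 <= v_threshold`.
#' When no V meets the threshold the full gene count is returned with a
#' warning flag.
#'
#' @param q Quantity matrix.
#' @param ranking Genes, most stable first (e.g. `genorm(q)$ranking`).
#' @param v_threshold Cutoff, default 0.15.
#' @param nf Optional precomputed NF matrix (rows `NF2..NFk`).
#' @return List with `v` (named vector), `optimal_n`, `warning`.
#' @export
v_criterion <- function(q, ranking, v_threshold = 0.15, nf = NULL) {
  k <- length(ranking)
  if (k < 3) ct_stop("V criterion needs at least 3 ranked genes",
                     "insufficient_data")
  if (is.null(nf)) {
    nf <- t(vapply(2:k, function(n) normalization_factor(q, ranking, n),
                   numeric(ncol(q))))
    rownames(nf) <- paste0("NF", 2:k)
  }
  v <- vapply(seq_len(k - 2), function(i) {
    stats::sd(log2(nf[i, ] / nf[i + 1, ]))
  }, numeric(1))
  names(v) <- paste0("V", 2:(k - 1), "/", 3:k)
  ok <- which(v <= v_threshold)
  if (length(ok)) {
    list(v = v, optimal_n = unname(ok[1]) + 1L, warning = FALSE)
  } else {
    list(v = v, optimal_n = k, warning = TRUE)
  }
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability analysis\n")
  cat(sprintf("  most stable pair: %s (M = %.3f)\n",
              paste(x$final_pair, collapse = " / "),
              x$stability$m[match(x$final_pair[1], x$stability$gene)]))
  worst <- x$stability$gene[which.max(x$stability$rank)]
  cat(sprintf("  least stable: %s (M = %.3f)\n", worst,
              max(x$stability$m)))
  cat(sprintf("  optimal number of reference genes: %d%s\n", x$optimal_n,
              if (x$v_warning) " (no V below threshold; using all genes)"
              else ""))
  invisible(x)
}

#' @export
plot.genorm_fit <- function(x, which = c("m", "v"), ...) {
  which <- match.arg(which)
  if (which == "m") {
    ord <- order(-x$stability$rank)
    graphics::plot(seq_along(ord), x$stability$m[ord], type = "b",
                   xaxt = "n", xlab = "", ylab = "M-value",
                   main = "geNorm average expression stability", ...)
    graphics::axis(1, at = seq_along(ord), labels = x$stability$gene[ord],
                   las = 2, cex.axis = 0.8)
  } else {
    graphics::barplot(x$v, ylab = "Pairwise variation V",
                      main = "Optimal number of reference genes", ...)
    graphics::abline(h = x$v_threshold, lty = 2)
  }
  invisible(x)
}
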