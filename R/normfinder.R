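#' Model-based expression stability (NormFinder-style)
#'
#' Variance-decomposition estimate of per-gene stability on log-scale
#' expression. Within each sample group the gene-by-sample log-expression
#' matrix is double-centred; the residual variance per gene is
#' bias-corrected for the shared-reference artefact of using the gene panel
#' itself as the normalizer. With two or more groups a per-gene, per-group
#' intergroup deviation is estimated and shrunk towards zero, and the
#' stability value combines the (shrunk) systematic between-group deviation
#' with the random intragroup variation. The most stable gene has the
#' smallest S.
#'
#' @details Per group \eqn{g} with \eqn{n_g} samples and \eqn{k} genes:
#' residuals \eqn{r_{igj} = y_{igj} - \bar y_{ig.} - \bar y_{.gj} + \bar
#' y_{.g.}}; raw variance \eqn{s^2_{ig} = \sum_j r^2_{igj} / (n_g - 1)};
#' bias-corrected \eqn{\hat\sigma^2_{ig} = \max\{0, k/(k-2) (s^2_{ig} -
#' \sum_i s^2_{ig} / (k(k-1)))\}}. Intergroup deviation
#' \eqn{d_{ig} = (\bar y_{ig.} - \bar y_{i..}) - (\bar y_{.g.} - \bar
#' y_{...})} (group means averaged unweighted over groups), shrunk by
#' \eqn{\tilde d_{ig} = d_{ig}\,\hat\gamma / (\hat\gamma +
#' \hat\sigma^2_{ig}/n_g)} with the method-of-moments
#' \eqn{\hat\gamma = \max\{0, \mathrm{var}(d) -
#' \mathrm{mean}(\hat\sigma^2/n_g)\}}. Per-gene, per-group stability
#' \eqn{\rho_{ig} = |\tilde d_{ig}| +
#' \sqrt{(\hat\sigma^2_{ig}/n_g)\,\hat\gamma/(\hat\gamma +
#' \hat\sigma^2_{ig}/n_g)}} and \eqn{S_i = \mathrm{mean}_g \rho_{ig}}.
#' With a single group (or `groups = NULL`) there is no intergroup term and
#' \eqn{S_i = \hat\sigma_i}. All statistics are invariant to per-gene and
#' per-sample additive shifts of `y`, so any log-scale expression measure
#' (`-Ct`, `log2 Q`) gives identical results.
#'
#' @param y Log2-scale expression matrix (genes x samples); a
#'   [ct_table()] is accepted and converted as `-average_replicates(x)`.
#'   At least 3 genes (the bias correction requires k >= 3).
#' @param groups Mapping of samples to groups: a character/factor vector,
#'   either named by sample or in column order. `NULL` for ungrouped mode.
#'   Every group needs at least 2 samples.
#' @return Object of class `normfinder_fit`: \describe{
#'   \item{stability}{data frame `gene`, `s`, `rank` (rank 1 = smallest S).}
#'   \item{sigma2}{genes x groups matrix of bias-corrected intragroup
#'     variances.}
#'   \item{d, d_shrunk}{genes x groups intergroup deviations (grouped mode
#'     only).}
#'   \item{gamma_hat}{intergroup variance estimate (grouped mode).}
#'   \item{best_gene}{gene with smallest S.}
#'   \item{best_pair, best_pair_s}{best two-gene combination (grouped mode
#'     with >= 2 groups; see [best_pair()]).}
#'   \item{groups}{group labels used, or NULL.}
#' }
#' @examples
#' set.seed(2)
#' y <- matrix(rnorm(5 * 8, 25), 5, 8,
#'             dimnames = list(paste0("G", 1:5), paste0("S", 1:8)))
#' normfinder(y, groups = rep(c("leaf", "root"), each = 4))
#' @export
normfinder <- function(y, groups = NULL) {
  if (inherits(y, "ct_table")) {
    ctab <- y
    y <- -average_replicates(ctab)
    if (is.null(groups) && "tissue" %in% names(ctab)) {
      groups <- vapply(samples(ctab), function(s) {
        ctab$tissue[match(s, ctab$sample_id)]
      }, character(1))
    }
  }
  stopifnot(is.matrix(y))
  k <- nrow(y)
  if (k < 3) {
    ct_stop("NormFinder bias correction requires at least 3 genes",
            "insufficient_genes")
  }
  gene_names <- rownames(y)
  if (is.null(groups)) groups <- rep("all", ncol(y))
  if (!is.null(names(groups))) {
    groups <- groups[colnames(y)]
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(y))
  glev <- unique(groups)
  n_g <- table(factor(groups, levels = glev))
  if (any(n_g < 2)) {
    ct_stop("every group needs at least 2 samples", "insufficient_samples")
  }

  sigma2 <- matrix(NA_real_, k, length(glev),
                   dimnames = list(gene_names, glev))
  gene_group_mean <- sigma2  # ybar_ig.
  for (g in glev) {
    yg <- y[, groups == g, drop = FALSE]
    ng <- ncol(yg)
    gi <- rowMeans(yg)                 # ybar_ig.
    sj <- colMeans(yg)                 # ybar_.gj
    gg <- mean(yg)                     # ybar_.g.
    r <- yg - outer(gi, rep(1, ng)) - outer(rep(1, k), sj) + gg
    s2 <- rowSums(r^2) / (ng - 1)
    sigma2[, g] <- pmax(0, (k / (k - 2)) * (s2 - sum(s2) / (k * (k - 1))))
    gene_group_mean[, g] <- gi
  }

  grouped <- length(glev) >= 2
  if (grouped) {
    # d_ig: gene-by-group interaction of the group means
    gene_mean <- rowMeans(gene_group_mean)          # ybar_i.. (over groups)
    group_mean <- colMeans(gene_group_mean)         # ybar_.g.
    grand <- mean(gene_group_mean)                  # ybar_...
    d <- gene_group_mean - outer(gene_mean, rep(1, length(glev))) -
      outer(rep(1, k), group_mean) + grand
    sig_over_n <- sweep(sigma2, 2, as.numeric(n_g), "/")
    gamma_hat <- max(0, stats::var(as.vector(d)) - mean(sig_over_n))
    # gamma_hat = 0 means no detectable intergroup variance: full
    # shrinkage (0/0 guarded to 0)
    denom <- gamma_hat + sig_over_n
    shrink <- ifelse(denom > 0, gamma_hat / denom, 0)
    d_shrunk <- d * shrink
    rho <- abs(d_shrunk) + sqrt(sig_over_n * shrink)
    s_val <- rowMeans(rho)
  } else {
    d <- d_shrunk <- NULL
    gamma_hat <- NA_real_
    s_val <- sqrt(sigma2[, 1])
  }

  rank_vec <- rank(s_val, ties.method = "first")
  stability <- data.frame(gene = gene_names, s = unname(s_val),
                          rank = unname(rank_vec),
                          stringsAsFactors = FALSE)

  fit <- structure(list(stability = stability,
                        sigma2 = sigma2,
                        d = d, d_shrunk = d_shrunk,
                        gamma_hat = gamma_hat,
                        n_g = as.numeric(n_g),
                        best_gene = gene_names[which.min(s_val)],
                        best_pair = NULL, best_pair_s = NA_real_,
                        groups = if (grouped) groups else NULL,
                        group_levels = if (grouped) glev else NULL),
                   class = "normfinder_fit")
  if (grouped) {
    bp <- best_pair(fit)
    fit$best_pair <- bp$pair
    fit$best_pair_s <- bp$s
  }
  fit
}

#' Best two-gene combination under the NormFinder model
#'
#' Exhaustive search over gene pairs. Averaging two genes averages their
#' (shrunk) intergroup deviations — genes that deviate in opposite
#' directions cancel — and quarters the summed intragroup variance:
#' \eqn{\tilde d_{Ag} = (\tilde d_{ig} + \tilde d_{i'g})/2},
#' \eqn{\sigma^2_{Ag} = (\hat\sigma^2_{ig} + \hat\sigma^2_{i'g})/4}. The
#' pair stability recombines these exactly like the single-gene S and the
#' minimizing pair is returned.
#'
#' @param fit A grouped [normfinder()] fit (>= 2 groups).
#' @return List with `pair` (two gene names) and `s` (pair stability).
#' @export
best_pair <- function(fit) {
  stopifnot(inherits(fit, "normfinder_fit"))
  if (is.null(fit$d_shrunk)) {
    ct_stop("best pair requires grouped mode with >= 2 groups",
            "unsupported_mode")
  }
  genes <- fit$stability$gene
  gamma_hat <- fit$gamma_hat
  n_g <- fit$n_g
  best <- NULL
  best_s <- Inf
  for (a in seq_len(length(genes) - 1)) {
    for (b in seq(a + 1, length(genes))) {
      d_pair <- (fit$d_shrunk[a, ] + fit$d_shrunk[b, ]) / 2
      s2_pair <- (fit$sigma2[a, ] + fit$sigma2[b, ]) / 4
      v <- s2_pair / n_g
      shrink <- ifelse(gamma_hat + v > 0, gamma_hat / (gamma_hat + v), 0)
      s_pair <- mean(abs(d_pair) + sqrt(v * shrink))
      if (s_pair < best_s) {
        best_s <- s_pair
        best <- c(genes[a], genes[b])
      }
    }
  }
  list(pair = best, s = best_s)
}

#' @export
print.normfinder_fit <- function(x, ...) {
  cat("NormFinder-style stability analysis\n")
  cat(sprintf("  best gene: %s (S = %.3f)\n", x$best_gene,
              min(x$stability$s)))
  if (!is.null(x$best_pair)) {
    cat(sprintf("  best pair: %s (S = %.3f)\n",
                paste(x$best_pair, collapse = " + "), x$best_pair_s))
  }
  worst <- x$stability$gene[which.max(x$stability$s)]
  cat(sprintf("  worst gene: %s (S = %.3f)\n", worst, max(x$stability$s)))
  invisible(x)
}
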