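#' Specify a synthetic Ct panel
#'
#' Describes a replicate-level Ct dataset with known ground truth,
#' emulating the two experimental designs of a typical reference-gene
#' study: an organ/fruit-stage panel of 13 samples, or a stress panel of
#' 2 tissues x 5 stress conditions x 5 time points (0/2/6/12/24 h), both
#' with 3 replicates per sample. Gene baselines sit in the observed qPCR
#' working range (~19-33 cycles before noise). Stable genes carry only a
#' small per-sample residual; genes named in `unstable` additionally drift
#' with the experimental condition (organ identity, stress group, or time),
#' which is what every stability algorithm is supposed to detect.
#'
#' @param panel `"organ"` (13 organ samples) or `"stress"` (50 samples:
#'   leaf/root x 5 stresses x 0/2/6/12/24 h).
#' @param n_genes Panel size (default 14).
#' @param n_replicates Technical replicates per (sample, gene), default 3.
#' @param baseline_range Range the per-gene baseline Ct is drawn from
#'   (default `c(19, 33)` cycles).
#' @param sd_loading SD of the per-sample loading offset tau_j (cycles,
#'   default 0.4): common to all genes, so it cancels under normalization.
#' @param stable_sd Per-gene residual SD sigma_i for stable genes (cycles,
#'   default 0.15).
#' @param unstable Names (e.g. `"G13"`) or count of unstable genes
#'   (default 2: the last two genes).
#' @param drift_amplitude Condition-linked drift amplitude delta_i for
#'   unstable genes (cycles, default 2).
#' @param drift_pattern `"group"` (drift follows the condition group /
#'   organ) or `"time"` (follows the time course; stress panel only).
#' @param unstable_sd Residual SD of unstable genes (default 0.3).
#' @param replicate_sd SD of the replicate-level noise eta_r (default 0.1).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return List of class `panel_spec` with all parameters resolved
#'   (gene names, sample design, per-gene sigma and delta).
#' @export
panel_spec <- function(panel = c("organ", "stress"), n_genes = 14,
                       n_replicates = 3, baseline_range = c(19, 33),
                       sd_loading = 0.4, stable_sd = 0.15, unstable = 2,
                       drift_amplitude = 2,
                       drift_pattern = c("group", "time"),
                       unstable_sd = 0.3, replicate_sd = 0.1, seed = 1) {
  panel <- match.arg(panel)
  drift_pattern <- match.arg(drift_pattern)
  stopifnot(n_genes >= 3, n_replicates >= 1, stable_sd >= 0,
            unstable_sd >= 0, replicate_sd >= 0, drift_amplitude >= 0,
            length(baseline_range) == 2,
            baseline_range[1] < baseline_range[2])
  gene_names <- sprintf("G%02d", seq_len(n_genes))
  if (is.numeric(unstable) && length(unstable) == 1) {
    stopifnot(unstable <= n_genes)
    unstable <- if (unstable > 0) utils::tail(gene_names, unstable)
                else character(0)
  }
  if (!all(unstable %in% gene_names)) {
    ct_stop("unstable set is not a subset of the gene panel",
            "validation_error")
  }
  if (panel == "organ") {
    design <- data.frame(
      sample_id = c("root", "stem", "leaf", "leaf_bud", "flower_bud",
                    "flower", "green_fruit", "pink_fruit", "blue_fruit",
                    "seed", "exocarp", "sarcocarp", "whole_fruit"),
      tissue = "organ", group = "control", time_h = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    design <- expand.grid(
      time_h = c(0, 2, 6, 12, 24),
      group = c("NaCl", "NaHCO3", "saline_alkaline", "PEG", "AlCl3"),
      tissue = c("leaf", "root"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%s_%gh", design$tissue, design$group,
                                design$time_h)
    design <- design[, c("sample_id", "tissue", "group", "time_h")]
  }
  structure(list(panel = panel, genes = gene_names, design = design,
                 n_replicates = n_replicates,
                 baseline_range = baseline_range,
                 sd_loading = sd_loading, stable_sd = stable_sd,
                 unstable = unstable, drift_amplitude = drift_amplitude,
                 drift_pattern = drift_pattern, unstable_sd = unstable_sd,
                 replicate_sd = replicate_sd, seed = as.integer(seed)),
            class = "panel_spec")
}

#' @keywords internal
drift_values <- function(spec) {
  design <- spec$design
  if (spec$panel == "organ" || spec$drift_pattern == "group") {
    # one drift level per condition unit (organ sample, or stress group
    # within tissue), spread symmetrically over [-1, 1]
    unit <- if (spec$panel == "organ") design$sample_id
            else paste(design$tissue, design$group)
    lev <- unique(unit)
    val <- if (length(lev) > 1) seq(-1, 1, length.out = length(lev)) else 0
    stats::setNames(val, lev)[unit]
  } else {
    # time-linked: centred, scaled time course
    t <- design$time_h
    (t - mean(unique(t))) / max(abs(unique(t) - mean(unique(t))))
  }
}

#' Generate a synthetic replicate-level Ct table
#'
#' Draws `Ct = mu_i + tau_j + delta_i * pattern(condition) + eps_ij +
#' eta_r`: a per-gene baseline, a per-sample loading offset shared by all
#' genes, a condition-correlated drift for the planted unstable genes, a
#' per-(gene, sample) residual and replicate-level noise, all Gaussian on
#' the Ct (log) scale. Deterministic given the spec (including its seed).
#' Unstable genes drift with alternating sign, so a pair of them deviates
#' in opposite directions — the situation in which a two-gene combination
#' can beat any single gene.
#'
#' @param spec A [panel_spec()].
#' @return List with `ct` (a [ct_table()]) and `truth`, a list recording
#'   every drawn parameter: `mu`, `tau`, `sigma`, `delta` (named vectors),
#'   `pattern` (per-sample drift multiplier), `eps` (gene x sample residual
#'   matrix) and `expected_ct` (gene x sample mean surface without
#'   replicate noise).
#' @examples
#' sim <- simulate_ct_panel(panel_spec("stress", seed = 7))
#' sim$ct
#' sim$truth$delta
#' @export
simulate_ct_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  design <- spec$design
  k <- length(spec$genes)
  n <- nrow(design)

  mu <- stats::setNames(
    stats::runif(k, spec$baseline_range[1], spec$baseline_range[2]),
    spec$genes)
  tau <- stats::setNames(stats::rnorm(n, 0, spec$sd_loading),
                         design$sample_id)
  sigma <- stats::setNames(
    ifelse(spec$genes %in% spec$unstable, spec$unstable_sd,
           spec$stable_sd), spec$genes)
  delta <- stats::setNames(rep(0, k), spec$genes)
  if (length(spec$unstable)) {
    signs <- rep(c(1, -1), length.out = length(spec$unstable))
    delta[spec$unstable] <- signs * spec$drift_amplitude
  }
  pattern <- drift_values(spec)

  eps <- matrix(stats::rnorm(k * n, 0, sigma), nrow = k,
                dimnames = list(spec$genes, design$sample_id))
  expected_ct <- outer(mu, rep(1, n)) + outer(rep(1, k), tau) +
    outer(delta, pattern) + eps
  colnames(expected_ct) <- design$sample_id

  rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                      gene = spec$genes, sample_id = design$sample_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_ct <- expected_ct[cbind(rows$gene, rows$sample_id)]
  rows$ct <- base_ct + stats::rnorm(nrow(rows), 0, spec$replicate_sd)
  meta_idx <- match(rows$sample_id, design$sample_id)
  rows$tissue <- design$tissue[meta_idx]
  rows$group <- design$group[meta_idx]
  rows$time_h <- design$time_h[meta_idx]
  rows <- rows[, c("sample_id", "tissue", "group", "time_h", "gene",
                   "replicate", "ct")]

  list(ct = ct_table(rows),
       truth = list(mu = mu, tau = tau, sigma = sigma, delta = delta,
                    pattern = stats::setNames(pattern, design$sample_id),
                    eps = eps, expected_ct = expected_ct, spec = spec))
}

#' Generate a synthetic dilution series
#'
#' A standard curve with known amplification efficiency: log10 template
#' amounts descend in `dilution_fold`-fold steps from 0, and
#' `Ct = intercept + slope * x + noise` with
#' `slope = -1 / log10(1 + efficiency)` (so efficiency 1 gives the classic
#' -3.3219 cycles per decade).
#'
#' @param efficiency True amplification efficiency as a fraction in
#'   (0.5, 1.5).
#' @param intercept Ct at the undiluted point (default 22 cycles).
#' @param n_points Number of dilution points (default 5).
#' @param dilution_fold Fold change per step (default 5).
#' @param noise_sd SD of Gaussian Ct noise (default 0).
#' @param seed Optional integer seed.
#' @return List with `log10_dilution`, `mean_ct`, `true_slope`,
#'   `true_efficiency`; feed the first two to [fit_dilution_series()].
#' @export
simulate_dilution_series <- function(efficiency, intercept = 22,
                                     n_points = 5, dilution_fold = 5,
                                     noise_sd = 0, seed = NULL) {
  if (efficiency <= 0.5 || efficiency >= 1.5) {
    ct_stop("true efficiency must lie in (0.5, 1.5)", "validation_error")
  }
  stopifnot(n_points >= 3)
  if (!is.null(seed)) set.seed(seed)
  x <- -(seq_len(n_points) - 1) * log10(dilution_fold)
  slope <- -1 / log10(1 + efficiency)
  ct <- intercept + slope * x + stats::rnorm(n_points, 0, noise_sd)
  list(log10_dilution = x, mean_ct = ct, true_slope = slope,
       true_efficiency = efficiency)
}
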