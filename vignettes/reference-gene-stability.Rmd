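---
title: "Reference-gene stability from Ct tables: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability from Ct tables: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstab)
```

# The problem

RT-qPCR reports a cycle threshold Ct, the cycle at which amplification
fluorescence crosses a detection line; each missing cycle is roughly a
doubling of starting template. Expression of a target gene is only
interpretable relative to reference genes measured in the same sample,
because template input, extraction yield and reverse-transcription
efficiency differ between samples. The whole workflow in this package
exists to answer one question: *which candidate genes vary so little
across the experimental conditions that they can serve as that
reference?* — and to quantify what goes wrong when an unstable gene is
used instead.

All statistics operate on the log scale that Ct already lives on: a
per-sample loading offset adds a constant to every gene's Ct in that
sample, and a gene's abundance scale adds a constant to that gene's Ct
everywhere. Every stability statistic here is invariant to both kinds of
shift (this is property-tested), which is what makes raw Ct usable
without absolute calibration.

# Data model

The canonical container is a long-format replicate-level Ct table: one
row per (sample, gene, replicate) with optional tissue, condition-group
and time metadata. Validation is strict by default — finite positive Ct,
unique replicate keys, and a complete gene-by-sample grid, because the
stability algorithms implicitly assume complete matrices. A permissive
mode downgrades missing cells to listwise deletion of the affected
samples with a warning; silently analysing an incomplete matrix would
bias the pairwise statistics toward the genes observed together.
Decimal-comma exports (common from qPCR instruments) are normalized on
read via a dialect flag.

Replicates are averaged arithmetically per cell. Relative quantities use
`Q = 2^-(Ct - Ct_ref)` with the per-gene minimum Ct as reference, the
conventional geNorm input: Q then lies in (0, 1] with the best-expressed
sample at 1. The choice of reference is cosmetic — per-gene rescaling
cancels in every downstream statistic — but it must be fixed for
reproducible intermediate output. An efficiency-corrected variant
`(1 + E)^-ΔCt` is available but off by default, since the standard
formulation of all three algorithms is exponent-base 2.

# The three stability algorithms

## geNorm

The pairwise variation of genes *j*, *k* is the standard deviation
(n − 1 denominator, the original convention) over samples of
`log2(Q_j / Q_k)`; the M-value of *j* is its mean pairwise variation
against all other genes in the current set. The least stable gene
(highest M) is removed and M recomputed until two genes remain; those
share a single M (their mutual pairwise variation, computed once so the
tie is exact) and joint rank 1. Each gene's *reported* M is its M in the
round of its removal — that stepwise convention is what produces a
distinct M per gene and matches the familiar stability charts; the
full-set M is retained alongside. Ties in "highest M" are broken by
removing the gene later in input order, a documented, deterministic
choice.

The normalization factor NF_n is the per-sample geometric mean of the
top-n genes' quantities (n ≥ 2 — a one-gene "factor" defeats the
method's purpose and is rejected). `V_n/n+1 = sd(log2(NF_n / NF_n+1))`
measures how much adding the (n+1)-th gene changes the factor; the
optimal reference count is the smallest n with V ≤ 0.15, the method's
canonical threshold ("no more than" — the comparison is inclusive). If
no V meets the threshold the full gene count is returned with an
explicit warning flag rather than a silent answer.

## Model-based estimation (NormFinder style)

Within each sample group the log-expression matrix is double-centred;
residual variances are bias-corrected by
`σ̂² = max(0, k/(k−2) · (s² − Σ_i s²_i / (k(k−1))))`. The correction
follows from `E[s²_i] = (1 − 2/k)σ²_i + Σ_l σ²_l / k²` for two-way
centred residuals: centring by the panel mean leaks every gene's noise
into every residual, and the correction inverts that leakage exactly
(plug the expectation in and σ²_i comes back). It requires k ≥ 3 and is
validated by parameter recovery on generated truth rather than by
matching any particular historical implementation bit-for-bit. With two
or more groups, gene-by-group interactions of the group means give
intergroup deviations d; a method-of-moments intergroup variance
`γ̂ = max(0, var(d) − mean(σ̂²/n_g))` shrinks them
(`d̃ = d·γ̂/(γ̂ + σ̂²/n_g)`), degrading gracefully to full shrinkage when
no intergroup signal is detectable, and the stability value combines
systematic and random parts:
`S_i = mean_g(|d̃_ig| + sqrt(σ̂²_ig/n_g · γ̂/(γ̂ + σ̂²_ig/n_g)))`.
Ungrouped mode reduces to `S_i = σ̂_i`. The best two-gene combination is
found by exhaustive search with the pair's deviation averaged
(opposite-signed deviations cancel) and variance quartered.

Published S-values from the original applet are **not** numerically
reproduced — they depend on that implementation's exact constants, which
the available description underdetermines. What is reproducible, and
what the tests assert, is rank-level behaviour: planted unstable genes
rank last, variance parameters are recovered within sampling error, and
the ungrouped ordering equals the residual-SD ordering.

## BestKeeper style

Descriptive statistics are computed on raw mean Ct: geometric and
arithmetic means, extremes, SD and CV%. The default dispersion is the
sample standard deviation about the arithmetic mean; the original
applet's mean absolute deviation about the geometric mean is available
by flag for compatibility studies. Genes with SD > 1 cycle are excluded
from the index — a gene swinging more than a cycle is disqualified
regardless of correlation. The index is the per-sample geometric mean of
retained genes' Ct; every input gene (including excluded ones, for
reporting) gets a Pearson correlation with the index and an exact
t-transform p-value (n − 2 df). Genes excluded by SD, or with p > 0.05,
are flagged invalid with the *firing criterion recorded* — published
tables often collapse both cases into a dash, which loses information
the report should keep. Because the historical tool accepts at most 10
genes, larger panels are reduced first by dropping the genes with the
worst geNorm-rank + model-based-rank sum (ties toward the worse geNorm
rank); dropped genes keep their other two ranks in the consensus.

## Consensus

Per-method *ranks* are aggregated by geometric mean; aggregating the raw
M, S, r values would average incomparable scales (r is even inverted).
Invalid entries contribute nothing; a gene valid nowhere is placed last
and flagged. Final ranks break ties by geNorm rank, then input order.
The aggregation is order-invariant in the method list and
Pareto-consistent (a gene beating another in every method precedes it) —
both property-tested. The combined "comprehensive ranking" columns of
published studies are not reproduced numerically: no single aggregation
rule regenerates them, so rank-level and property-based checks stand in.

# ΔΔCt validation

`ddct_profile()` computes `ΔCt = Ct_target − mean(Ct_refs)` per sample
(the arithmetic mean of reference Ct equals normalizing by the geometric
mean of reference quantities — the only scale-coherent reading of a
multi-gene reference), anchors at a calibrator sample, and reports
`2^-ΔΔCt` with replicate-level propagation to per-point SDs. The
calibrator defaults to nothing silently: it is a required argument; time
courses conventionally use the 0 h sample and organ panels the first
organ. Profile comparisons emit descending-order strings (points within
10% relative difference joined by "≈" — published order strings use the
symbol without defining closeness, so the tolerance is configurable),
Spearman correlation, and per-point fold ratios. Note that the ratio of
two profiles of the same target under different references is
calibrator-invariant, which is why single-point fold-discrepancy numbers
are meaningful across laboratories.

Welch two-sample t-tests annotate replicate-level differences; the
degenerate zero-variance case returns p = 1 (identical means) or 0
(separated), so significance stars never crash on idealized data.

# The synthetic generator

`simulate_ct_panel()` draws
`Ct = μ_i + τ_j + δ_i·pattern(condition) + ε_ij + η_r`:
per-gene baselines uniform in 19–33 cycles (the working range observed
in real panels), per-sample loading offsets (SD 0.4 cycles), per-gene
residuals (stable genes SD 0.15, unstable 0.3 cycles), replicate noise
(SD 0.1 cycles), and a condition-linked drift of amplitude δ (default 2
cycles) for the planted unstable genes, with alternating sign so that a
pair of unstable genes deviates in opposite directions. Drift follows
either the condition group (one level per organ or per tissue × stress
unit, spread evenly over [−1, 1]) or the centred time course. The two
built-in designs mirror the standard study layouts: 13 organ samples,
and 2 tissues × 5 stresses × 5 time points (0/2/6/12/24 h), 3
replicates each.

Everything is Gaussian on the Ct scale, which matches the log-linear
nature of qPCR and makes parameter recovery well-posed. What the
generator does **not** emulate: amplification-efficiency differences
between genes, non-Gaussian outliers (pipetting failures), missing
cells, plate/batch effects, and correlated residuals between genes
sharing a pathway. Passing tests therefore demonstrate algorithmic
correctness under the stated noise model, not robustness to every
pathology of real plates — the strict table validation is the package's
first line of defence for the latter.

`simulate_dilution_series()` produces standard curves with
`slope = −1/log10(1 + E)`, so a perfect doubling gives the classic
−3.32 cycles per decade.

# Numerical choices and degenerate inputs

- Screening cutoffs are applied exactly as printed: `|log2 ratio| < 0.6`
  strict, differential-expression thresholds `fdr ≤ 0.001` and
  `|ratio| ≥ 1` inclusive. How a ratio landing exactly on 0.6 should be
  treated is genuinely undocumented in the source material; strictness
  here is this package's documented choice, and the boundary is tested.
  Ratios are always recomputed from the RPKM columns — precomputed ratio
  columns in supplied tables are never trusted, because printed tables
  are not always internally consistent.
- Quartiles in Ct summaries use linear interpolation between order
  statistics (`quantile()` type 7). Any convention satisfying the
  min ≤ q25 ≤ median ≤ q75 ≤ max ordering would do; one had to be fixed.
- All standard deviations use the n − 1 denominator.
- R² for standard curves is computed directly from residual and total
  sums of squares (the `summary.lm` shortcut warns on numerically exact
  fits, which the noise-free tests exercise deliberately).
- γ̂ = 0 (no detectable intergroup variance) shrinks deviations fully to
  zero with a guarded 0/0.
- Stability analysis refuses panels of fewer than 3 genes and groups of
  fewer than 2 samples; the BestKeeper index refuses to form from fewer
  than 2 retained genes.

# Problem sizes in the tests

The suite runs entirely on generated data at desk scale: brute-force
agreement of the M-value on 200 random 5 × 8 matrices, variance-recovery
at 200 samples per group (averaged over 10 independent panels, so the
check measures estimator accuracy rather than single-draw noise), and
planted-gene ranking recovery over 100 simulated stress panels of 5
genes — sizes chosen so the whole suite completes in seconds while the
Monte-Carlo rates are still sharp (a ≥ 95% recovery criterion at 100
draws).

# Known limitations

- Stability is only estimable *relative to the panel*: if every
  candidate drifted identically, all methods would report perfect
  stability. The screening step's transcriptome-wide ratio filter is the
  guard against assembling such a panel.
- The model-based method assumes roughly balanced groups; strongly
  unbalanced designs will weight the unweighted group means differently
  from sample-weighted ones.
- Efficiency correction is available for quantities but the stability
  statistics themselves assume a common exponential base across genes.
- No instrument-native file formats; CSV/TSV only.
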