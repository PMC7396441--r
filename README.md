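# ctstab

Reference-gene stability analysis for RT-qPCR.

Relative quantification by RT-qPCR stands or falls with the reference
(housekeeping) genes used to normalize the target: a reference that itself
responds to the experimental conditions silently distorts every fold
change computed against it. `ctstab` implements the complete candidate
selection and validation workflow a reference-gene study runs:

1. **Screening** — candidate genes are taken from a two-library
   transcriptome RPKM table, keeping annotated genes whose expression
   ratio is near-constant, `|log2(RPKM_b / RPKM_a)| < 0.6`.
2. **QC** — dilution-series standard curves (`E = 10^(-1/slope) - 1`,
   gate on efficiency near 100% and `R² > 0.99`), RNA absorbance-ratio
   gates, and per-gene Ct distribution summaries (genes spanning more
   than 6 cycles are flagged as highly variable).
3. **Stability** — three complementary algorithms on replicate-averaged
   Ct:
   - *geNorm*: the M-value of gene *j* is the mean over partners *k* of
     `sd_samples(log2(Q_j / Q_k))`; the least stable gene is excluded
     stepwise until a tied best pair remains, and the pairwise variation
     `V_n/n+1 = sd(log2(NF_n / NF_{n+1}))` of normalization factors
     (geometric means of the top-*n* quantities) decides how many
     reference genes suffice (`V ≤ 0.15`).
   - *NormFinder-style model-based estimation*: per-group two-way
     centering of log expression gives bias-corrected intragroup
     variances σ̂²; with ≥ 2 groups, shrunken intergroup deviations d̃
     combine with σ̂² into a stability value
     `S = mean_g(|d̃| + sqrt(σ̂²/n_g · γ̂/(γ̂ + σ̂²/n_g)))`, and an
     exhaustive search finds the best two-gene combination.
   - *BestKeeper-style index analysis*: raw-Ct descriptives, exclusion of
     genes with SD > 1 cycle, the index as per-sample geometric-mean Ct,
     and per-gene Pearson correlation with the index (genes with
     P > 0.05 flagged invalid; the historical 10-gene input limit is
     honoured by dropping the jointly worst genes first).
4. **Consensus** — the geometric mean of the per-method ranks (ranks, not
   raw values: M, S and r live on incomparable scales), with invalid
   entries masked.
5. **Validation** — ΔΔCt profiles of a target gene
   (`2^-(ΔCt - ΔCt_calibrator)`, multi-gene references entering through
   their mean Ct) compared across reference choices: order strings,
   Spearman rank correlation and per-point fold ratios.

A synthetic Ct generator with known ground truth (per-gene baselines,
per-sample loading offsets, planted condition-correlated drift, replicate
noise — all Gaussian on the Ct scale) emulates the two standard designs,
a 13-sample organ panel and a 2 tissue × 5 stress × 5 time-point panel,
so every stage is testable without instrument data.

## Worked example

```r
library(ctstab)

sim <- simulate_ct_panel(panel_spec("stress", seed = 42))
fit <- ref_stability(sim$ct)        # genorm + normfinder + bestkeeper
fit
#> Reference-gene stability analysis: 14 genes, 50 samples (2 groups)
#>   consensus top 3: G09, G03, G12
#>   geNorm pair: G03/G09 (M = 0.165); optimal n = 2
#>   NormFinder best: G09 (S = 0.020)
#>   BestKeeper best: G09 (r = 0.972)

head(summary(fit), 3)
#>    gene genorm_m normfinder_s bestkeeper_r geo_mean_rank final_rank
#> 9   G09    0.165       0.0199        0.972          1.00          1
#> 3   G03    0.165       0.0465        0.971          2.29          2
#> 12  G12    0.202       0.0263        0.956          3.63          3

recommended_genes(fit)
#> [1] "G09" "G03"
```

The two genes the generator planted as condition-dependent (`G13`, `G14`,
drifting by ±2 cycles with the stress condition) fall to the bottom of
the consensus (final ranks 13 and 14, geNorm M 1.29 and 1.44 versus
0.165 for the best pair) — the situation the workflow exists to detect.
`run_stability_pipeline()` reruns the same analysis over declarative
condition subsets, and `ddct_profile()` / `compare_profiles()` quantify
how much a poor reference choice distorts a target's expression profile.

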