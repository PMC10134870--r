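# coldflux

Metabolic robustness analysis for two-temperature bacterial growth
experiments.

Cold-adapted marine bacteria such as *Pseudoalteromonas haloplanktis*
experience seasonal temperature swings of 10–15 °C, yet their central
metabolome can stay remarkably stable while the transcriptome reprograms
deeply. `coldflux` packages the quantitative workflow for studying this
"transcriptomic buffering" from bioreactor growth curves, NMR metabolite
time series, RNA-Seq differential-expression tables and a genome-scale
metabolic model, for two growth conditions (here 0 °C vs 15 °C):

- **Growth and uptake kinetics** — specific growth rate
  μ = (ln OD(T3) − ln OD(T1)) / (T3 − T1), biomass yield
  λ = ΔX (g/L) / ΔS (mol/L) with per-condition OD→biomass factors
  (0.74 at 15 °C, 0.66 at 0 °C), and substrate uptake
  q = 1000·μ/λ in mmol/gDW/h.
- **Metabolome robustness statistics** — baseline-normalized trajectories,
  cross-condition Pearson trend correlations with exact permutation
  Spearman support (n = 5 time points), all-against-all correlation
  matrices, Welch tests comparing the two conditions' matrices,
  Bonferroni-corrected per-metabolite mean tests, and log2 fold-change
  contrasts at the first exponential sampling point.
- **DEG summarization** — TPM, |log2FC| ≥ 1 and adjusted p < 0.05
  thresholding, Fisher-exact COG category enrichment (BH-corrected), and
  per-pathway DEG fractions.
- **Constraint-based modeling** — models in the community JSON schema,
  flux balance analysis (FBA: maximize biomass c·v s.t. S·v = 0,
  lb ≤ v ≤ ub) on a simplex solver written for this package, and
  per-metabolite production/consumption flux splits.
- **Relative omics integration** — the top/bottom 3% of gene and
  metabolite fold changes (2-fold cutoff) become candidate constraints
  ("flux 2× higher in the warm condition") on a paired two-condition flux
  model; the **maximum consistency score** (MCS) is the largest subset of
  candidates a feasible flux pair can satisfy simultaneously, against the
  theoretical maximum (TMCS). Representative fluxes are chosen
  parsimoniously and compared downstream: predicted metabolite log2FC
  from production fluxes, simple matching coefficient (SMC) against
  measured changes, and pathway-level Kolmogorov–Smirnov flux contrasts.
- **A synthetic study generator** — a 38-reaction toy central-carbon
  network (glutamate + gluconate medium, PPP, TCA, the
  PEP–pyruvate–oxaloacetate node, lumped fatty-acid and amino-acid
  branches) plus growth, metabolome and expression tables with planted
  ground truth, used by the test suite for end-to-end recovery checks.

## Worked example

```r
library(coldflux)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> <pipeline_report> seed 1
#>   mu: 0C 0.0265 h-1, 15C 0.2691 h-1
#>   metabolome: 76% below |log2FC| 1, 100% positive trends
#>   DEGs: 14 up, 5 down (metabolic 100.00%)
#>   consistency: MCS 18 / TMCS 19
#>   SMC 0.21
```

The simulated cold and warm cultures were planted with exponential rates
0.027 and 0.27 h⁻¹; the kinetics stage recovers 0.0265 and 0.2691 h⁻¹
from the noisy OD curves. Most simulated metabolites change less than
2-fold between conditions (76% below the |log2FC| = 1 threshold) and all
non-contrast metabolites share their temporal trends across temperatures
(100% positive correlation) — the robustness signature. Of 19 candidate
fold-change constraints, 18 can be embedded simultaneously in a feasible
pair of flux distributions (MCS/TMCS = 0.95). The pathway comparison on
those fluxes recovers the planted contrast: pentose-phosphate flux higher
in the warm condition (KS p = 0.0079), fatty-acid flux higher in the cold
(KS p = 0.029).

Individual stages are exported directly, e.g.

```r
model <- make_toy_model()
cold <- fba(apply_condition_bounds(model, c(EX_glu_e = 0.10, EX_glcn_e = 0.08)))
cold$objective_value          # predicted growth rate, h^-1
flux_splits(model, cold, "pep_c")$production_fractions
```

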