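---
title: "Methods: metabolic robustness analysis across growth temperatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic robustness analysis across growth temperatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A cold-adapted marine bacterium grown at two widely separated
temperatures (0 °C and 15 °C) can show nearly identical central
metabolomes while hundreds of metabolic genes change expression. To ask
*how* the regulatory layer buffers metabolism, three data layers are
combined: growth/uptake kinetics, NMR metabolite time series, and
RNA-Seq fold changes, integrated on a constraint-based metabolic model
to produce one flux distribution per condition. The differences between
the two flux distributions are then the mechanistic readout: which
pathways re-route so that metabolite pools stay put.

`coldflux` implements that workflow end to end, exercised on a synthetic
toy system whose ground truth is known, so every stage has recovery
tests.

## Kinetics

The specific growth rate over a sampling window is the two-point
log-ratio `mu = (ln OD(t2) - ln OD(t1)) / (t2 - t1)` in h⁻¹. The
"log" is natural: only ln-based rates have the dimensional meaning of an
exponential rate constant. Replicates are averaged (arithmetic mean OD)
before the ratio; per-replicate rates and their s.d. are reported
alongside.

Biomass is OD600 times a per-condition dry-weight factor (defaults
0.74 g/L/OD at 15 °C, 0.66 at 0 °C; overridable). The yield on a
substrate is `lambda = delta biomass (g/L) / delta substrate (mol/L)`,
and the specific uptake rate is `q = 1000 mu / lambda` in mmol/gDW/h —
the factor 1000 converts mol to mmol and is asserted as an invariant.

**Sampling-point labels.** Both growth curves are sampled five times at
matched physiological stages, not matched clock times (the cold culture
grows ten-fold slower). We label the points T0–T4: the uptake window runs
from T1 (second point, early exponential) to T3 (fourth point), and the
substrates run out at T3's sampling — so the window captures essentially
the whole drawdown. Functions that need "the same point in both
conditions" (the metabolite contrast, the expression sampling) therefore
select by index, not by absolute time.

## Metabolome robustness statistics

Trajectories are normalized to the condition-specific mean at the first
sampling point ("fold over baseline"). This choice is invisible to every
correlation statistic (scale invariance, verified numerically) but makes
trajectories comparable across metabolites measured in arbitrary NMR
units.

Cross-condition trend agreement per metabolite is the Pearson
product-moment correlation between the two conditions' per-time mean
trajectories; statistical support is a Spearman test whose two-sided
p-value comes from the exact permutation null for n ≤ 9 (all n!
rank permutations; at the study's n = 5 the p-value can only take values
k/120) and a Student-t approximation above. The t-approximation is
unreliable at n = 5, which is why the exact null is the default.
Constant trajectories make the correlation undefined: the result carries
an explicit `defined = FALSE` flag rather than NaN.

Structure conservation is assessed by all-against-all correlation
matrices per condition, compared by a Welch two-sample t-test on their
upper-triangle entries. Quantitative conservation is a per-metabolite
Welch test on values pooled over times and replicates, Bonferroni
corrected over the metabolites tested (`p_adj = min(1, m p)`). Welch
(unequal-variance) tests are used throughout; with n = 3 replicates the
equal-variance assumption buys nothing.

The condition contrast at T1 is `log2(mean_warm / mean_cold)` on
replicate values, flagging metabolites at |log2FC| ≥ 1 and summarizing
the fraction below threshold (integer-rounded percentage).

## Expression summarization

TPM follows the standard definition (counts per kilobase, scaled to one
million per sample). Differentially expressed genes (DEGs) are called by
thresholds — adjusted p < 0.05 (exclusive) and |log2FC| ≥ 1 (inclusive)
— on a table that arrives with log2FC and adjusted p already computed;
the differential testing engine itself is upstream and out of scope.

COG category enrichment uses a two-sided Fisher exact test per category
on the 2×2 table (in-category × in-DEG-set) over the background of genes
*with* a COG annotation, Benjamini–Hochberg corrected across categories
within a direction. The enrichment test is a documented choice (the
upstream analysis this emulates does not state one); a one-sided
alternative is exposed as an argument. Pathway-level summaries report the
percentage of each pathway's genes that are DEGs, split by direction,
plus the metabolic-gene share of all DEGs.

## Constraint-based core

Models use the community constraint-based JSON schema (metabolites,
reactions with stoichiometry/bounds/GPR/subsystem, genes, objective);
read/write round-trips are lossless and validated (ids unique, bounds
ordered, stoichiometry closed, GPR genes declared, exchanges touching
exactly one metabolite). Exchange fluxes follow the community sign
convention: negative = uptake. `apply_condition_bounds()` sets each
measured exchange's lower bound to minus the uptake magnitude and closes
uptake on every other exchange except a configurable free set (water,
protons, O2, CO2, phosphate, ammonium, sulfate by default — the medium's
inorganic components; the exact composition of the study medium is not
enumerated anywhere, hence configurable).

FBA maximizes the biomass flux subject to `S v = 0` and bounds. The LP
solver is a dense two-phase simplex written for this package (no LP
library exists in the target environment): Dantzig pricing with an
automatic switch to Bland's rule after a stall (anti-cycling), a
periodic reduced-cost refresh to cancel accumulated round-off, pivot
tolerance 1e-9, optimality tolerance 1e-7. Steady-state and bound
tolerances are 1e-6 throughout. The test suite checks the solver against
brute-force vertex enumeration on small networks and a linearity
property (scaling all uptakes by k scales the optimum by exactly k).
Objective values are the contract; flux vectors are representative only,
with parsimonious selection used wherever a specific vector is reported.

Flux splits decompose a metabolite's steady-state turnover:
the production contribution of reaction r is `max(0, s_mr v_r)`,
fractions are contributions over total production, and production equals
consumption by steady state (asserted within 1e-6). Zero-turnover
metabolites yield empty fraction maps, not errors.

## Consistency-score integration

Relative omics data enter as candidate constraints on a paired flux
model. Every reversible reaction is split into nonnegative forward and
backward components; the split network is duplicated into condition A
(cold) and B (warm) copies with their own uptake bounds; each condition
keeps a biomass floor (default 10% of its unconstrained FBA optimum — a
weak "the model must still grow" requirement, configurable).

Candidates come from `select_regulated()`: the top and bottom 3% of
linear fold changes (ties broken lexicographically for determinism),
further filtered by a 2-fold cutoff. Gene fold changes map to reactions
through GPRs with AND → min (a complex is limited by its scarcest
subunit) and OR → max (isozymes add capacity); reactions with no
measured gene are omitted, and regulated entries that map to nothing are
dropped from the theoretical maximum with a log. An "up" candidate with
capped ratio `rho_hat = min(rho, rho_max)` demands
`flux_B(target) >= rho_hat * flux_A(target)` and
`flux_A(target) >= epsilon`, where a reaction's flux is its
forward+backward component sum and a metabolite's is its total
production; "down" is symmetric. `rho_max = 10` keeps constraint
coefficients small; `epsilon = 1e-3` mmol/gDW/h is the smallest
reference flux for which a ratio is meaningful.

The maximum consistency score (MCS) is the size of the largest
simultaneously satisfiable candidate set; the theoretical maximum (TMCS)
counts all mappable candidates, so MCS ≤ TMCS always. Because
deactivating a candidate simply removes its two rows, infeasibility is
*monotone* in the active set. The search exploits this directly:
depth-first branch-and-bound over candidate subsets with hard-row LP
feasibility checks, include-first ordering (large sets early), a
remaining-candidate cardinality bound, pruning of every superset of an
infeasible set, and up-front exclusion of candidates infeasible alone.
An earlier formulation with big-M indicator rows was abandoned: the
big-M magnitudes (~1e4) amplified tableau round-off enough to leave
relaxation indicators fractional at the 1e-5 level, which a
branch-and-bound on indicator variables then chased pointlessly. The
subset search reaches the same optimum with well-scaled LPs only, and
the suite cross-checks it against full 2^TMCS enumeration.

With the optimal active set fixed, representative fluxes maximize the
summed biomass, then minimize total absolute flux at that optimum
(parsimonious tie-break), and are mapped back to net values on the
unsplit network. Every active constraint is re-checked post hoc against
the returned solution at 1e-6.

## Downstream flux analysis

The "predicted internal concentration" of a metabolite is proxied by its
total production flux — a modeling proxy, not a concentration; predicted
log2FC is the production-flux log-ratio, 0 when both productions vanish,
and ±10 (capped, flagged) when exactly one does. The simple matching
coefficient (SMC) is the fraction of metabolites whose predicted
up/down/unchanged category matches the measured one; the zero band
`delta` defaults to 0 on both sides, which makes any nonzero measured
noise a directional call — the SMC on noisy synthetic data is therefore
conservative, and a wider band is exposed as configuration. A Spearman
correlation is reported on the strongly changing subset
(|measured log2FC| ≥ 1).

Pathway activity contrasts drop reactions inactive in both conditions
and reactions that change direction, then compare the two conditions'
|flux| samples by two-sample two-sided Kolmogorov–Smirnov test (exact
for ≤ 10 used reactions, asymptotic above). The node report lists all
reactions around a metabolite with per-condition fluxes, deltas and
producer/consumer roles, sorted by |delta|.

## The synthetic study

The generator plants a complete ground truth and emits every input the
pipeline consumes.

- **Toy network** (38 reactions, 28 metabolites): glutamate and
  gluconate uptake, gluconate → 6-phosphogluconate → a five-reaction
  pentose-phosphate chain with a ribose-5-P biomass draw, lower
  glycolysis, a TCA loop, the full PEP–pyruvate–oxaloacetate node
  (malate dehydrogenase, PEP carboxykinase, PEP synthetase, pyruvate
  kinase, PEP carboxylase, citrate synthase), acetate overflow, a
  five-reaction lumped fatty-acid chain, a lumped amino-acid branch, and
  a biomass reaction drawing acetyl-CoA, oxaloacetate, 2-oxoglutarate,
  ribose-5-P, PEP and ATP. Pathway chains carry five reactions each so
  that pathway-level two-sample tests have enough support to reach
  p < 0.05 at all (the minimal exact KS p at three-vs-three is 0.1).
  On glutamate alone, PEP carboxykinase is the only PEP source — a
  testable structural fact used by the node-analysis checks.
- **Conditions**: cold ("0C") μ = 0.027 h⁻¹ with uptakes 0.10/0.08
  mmol/gDW/h (glutamate/gluconate), warm ("15C") μ = 0.27 h⁻¹ with
  0.47/0.62 — the measured scales of the system this emulates.
- **Planted flux pair**: per-condition FBA with forcing bounds — the
  fatty-acid sink fixed 2.5-fold higher in the cold condition and PEP
  carboxykinase forced on in the cold / nearly off in the warm (the
  cold-condition TCA→PEP rerouting); the warm condition's five-fold
  larger gluconate uptake gives it the higher pentose-phosphate flux.
  The pair is verified against steady state and bounds before any data
  are emitted; generation aborts otherwise. The regulated truth keeps
  reactions at least 2-fold apart that are active in *both* conditions,
  so the planted pair itself satisfies every derivable candidate
  constraint — making "noise-free data are fully consistent
  (MCS = TMCS)" exact by construction.
- **Metabolome**: 34 metabolites in two blocks sharing latent
  trajectories — an amino-acid-like rising block (16) and a central
  intermediate falling block (18) — indexed by sampling stage, so
  noise-free cross-condition trend correlation is exactly 1. An
  8-metabolite contrast set receives a ±1.5 log2 shift at T1 in the warm
  condition (2 up, 6 down). Replicate noise is lognormal, CV 15%.
- **Expression**: genes of reactions whose planted flux magnitudes
  differ ≥ 2-fold get log2FC = log2(ratio) + N(0, 0.25) with small
  adjusted p; ~400 background genes get null fold changes and uniform p;
  counts are negative binomial around a lognormal baseline; COG letters
  and pathway tags derive from the reactions a gene catalyzes.
- **Noise defaults**: OD CV 5%, metabolite CV 15%, expression σ = 0.25
  log2 units — chosen so planted effects are detectable at the study's
  sample sizes (3 replicates, 5 time points). At these conditions the
  per-seed uptake estimate scatters ~4% (1σ), which the study's own
  replicate s.d. on μ corroborates; accuracy claims about the estimator
  are therefore made on seed-averaged estimates, while exactness claims
  use noiseless data.

What the generator does **not** emulate: NMR spectral artifacts or
peak-assignment ambiguity, sequencing depth effects and dispersion
estimation, lag/stationary growth phases (growth is exponential until
substrate exhaustion), thermodynamic constraints, and any real kinetic
regulation. Passing recovery tests therefore demonstrate the
*statistical machinery and the integration logic*, not that the toy
model represents the real organism's network.

## Problem sizes and runtime choices

The default pipeline (34 metabolites × 2 conditions × 5 times × 3
replicates, ~430 genes, 38-reaction model, ~19 integration candidates)
runs in seconds. Test-suite simulations use 10 fixed seeds for
recovery claims, 20 seeds where a mean is asserted, and 24 seed pairs
for the null-size check of the matrix comparison; the brute-force MCS
cross-check uses instances with TMCS ≤ 10. These sizes make the full
suite complete in about a minute while keeping every probabilistic claim
at the margins the tests state.

## Known limitations

- The consistency search is exponential in the candidate count in the
  worst case; it is meant for the tens-of-candidates scale of the
  top-3% selection on models of this size, not for genome-scale
  candidate sets.
- The dense simplex is appropriate for toy-to-medium models; a
  genome-scale reconstruction (thousands of reactions) needs a sparse
  industrial LP solver, and the package will be slow there.
- Alternative optima: MCS-optimal active sets need not be unique; one
  deterministic representative is returned (candidate ordering is
  lexicographic), and no enumeration of equivalent sets is attempted.
- Predicted "concentrations" are production fluxes; agreement with
  measured fold changes is a directional, not quantitative, claim.
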