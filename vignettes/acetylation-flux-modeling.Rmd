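---
title: "Modeling protein acetylation as overflow metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein acetylation as overflow metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylflux)
```

## The model

Protein and histone acetylation consumes acetyl-CoA, a metabolite at the
crossroads of central carbon metabolism. `acetylflux` treats bulk
acetylation as a *flux* readable from a genome-scale metabolic
reconstruction: the network is augmented with a nuclear protein-acetylation
reaction

```
protein[n] + acetyl-CoA[n] -> acetyl-protein[n] + CoA[n]
```

fed by a nuclear copy of ATP-citrate lyase and reversible nucleus-cytosol
transport of citrate and oxaloacetate. The protein substrate is supplied by
an unlimited source/sink pair, a deliberate modeling choice: it makes the
acetylation flux a pure readout of nuclear acetyl-CoA supply rather than of
protein turnover, which the model does not describe.

Flux states are computed by flux balance analysis (FBA): maximize an
objective over flux vectors $v$ subject to steady state $S v = 0$ and
bounds $lb \le v \le ub$ (all fluxes in mmol/gDW/h). Acetylation enters as
a *secondary* objective,

$$\max \; v_{biomass} + \varepsilon \, v_{acetylation},$$

with a small $\varepsilon > 0$. The reported acetylation flux is then the
carbon the optimal state can divert to acetylation *without compromising
growth* — overflow metabolism. Because the two objectives are resolved by
magnitude separation, the acetylation value is insensitive to
$\varepsilon$; the package verifies this over
$\varepsilon \in [10^{-6}, 10^{-2}]$ and uses $10^{-4}$ (the midpoint of
the validated range, on a log scale) as the default. A lexicographic
two-stage mode is available (`lexicographic = TRUE`) but the single
weighted LP is the default formulation. Since LP optima need not be unique,
`flux_variability_at_optimum()` can bound the acetylation flux over the
optimal face; on the bundled network the value is unique to numerical
tolerance. When pinning the *weighted* objective, note that the slack on the
fixed objective is amplified by $1/\varepsilon$ along the acetylation axis;
use a tight `optimality_tol` for uniqueness checks.

This is a secondary-objective assumption, not merely a numerical trick: a
back-of-envelope capacity calculation supports it. A measured cytosolic
acetyl-CoA synthesis flux of 2 nmol/h per µl of packed cells at ~10^6
cells/µl (about 1 pL per cell — the one free parameter of the calculation,
exposed as `cells_per_ul`) is ~1.2 × 10^9, i.e. 10^9 molecules per hour
per cell to one significant figure. Saturating ~10^9 acetylation sites
within 24 h then requires 1/24 ≈ 4.2% of that flux — under 5%, so
acetylation is a metabolically cheap secondary demand
(`molecules_per_hour_per_cell()`, `required_flux_fraction()`).

## The LP backend

Every computation reduces to linear programs of the form
max $c^T x$ s.t. $A_{eq} x = b_{eq}$, $A_{ge} x \ge b_{ge}$,
$lb \le x \le ub$. The package implements its own dense two-phase tableau
simplex (`lp_solve()`, internal): a Dantzig pivot rule with a fallback to
Bland's rule guarantees termination on the degenerate bases that
steady-state constraints produce, and infeasible/unbounded programs are
detected and reported as solver status. Dense tableaus are appropriate for
the core-carbon scale this package targets (tens to a few hundred
reactions); a genome-scale reconstruction such as a human
metabolic network can be *parsed* with `load_model()` but solving it is
beyond the intended scale of this backend. The test suite cross-checks the
solver against brute-force vertex enumeration of the flux polytope on all
bundled small networks (agreement to $10^{-6}$ or better) and against an
independent simplex implementation on random LPs.

## The toy network and its designed truths

`make_toy_network()` builds a deterministic ~30-reaction core-carbon model:
exchanges for glucose, acetate, glutamine, a lumped amino-acid pool, fatty
acids and oxygen; lumped glycolysis (2 ATP + 2 pyruvate per glucose),
pyruvate oxidation, citrate synthesis, a lumped oxidative branch (9 ATP per
acetyl unit burned), the citrate shuttle, cytosolic ATP-citrate lyase,
fatty-acid synthesis and β-oxidation, and a biomass reaction consuming
amino acids, ATP and lipid. Formulas use a carbon-only convention
(glucose = C4, acetyl = C2, lipid = C8) so that carbon bookkeeping in
"acetyl units" (1 unit = 2 carbons) is exact with integer-valued optima:
`acetyl_unit_balance()` verifies
`uptake = acetylation + biomass + secretion + sinks` at every optimum.

The stoichiometry was chosen so that five qualitative truths hold by
construction under the baseline medium (`toy_baseline_medium()`: glucose
10, acetate 2, glutamine 2, amino acids 4, fatty acids 2, oxygen 40):

1. glucose excess raises acetylation (more surplus carbon);
2. amino-acid removal raises acetylation (biomass, capped by nitrogen,
   releases its carbon demand);
3. removing every carbon source drives acetylation to zero;
4. deleting the ATP-citrate-lyase gene (`ACLY_t`) abolishes acetylation —
   an "impacting" deletion under the 1% rule;
5. deleting fatty-acid synthase (`FASN_t`) raises acetylation — an
   "enhancing" deletion (it is the big acetyl-CoA consumer).

Getting truth 2 *and* a nonzero acetylation flux in glucose-free media
required care: with a biomass-first objective, the last unit of carbon is
always spent on growth unless a non-carbon constraint binds first. The toy
network therefore makes amino acids the binding biomass cap at baseline,
with a realistic oxidative ATP yield so that energy demands do not consume
the acetate/fatty-acid carbon that sustains acetylation when glucose is
withdrawn.

Screen conventions (where the underlying rule is qualitative, the package
fixes a quantitative default and reports it): "excess" multiplies an
allowance by 2; trace nutrients get 1% of a standard allowance; a condition
"supports" acetylation iff its flux reaches 5% of baseline (boundary
inclusive); a deletion is "impacting" iff its acetylation ratio is
≤ 0.99 (with a 10^-6 numeric-zero guard), "enhancing" iff > 1; the
preferential ranking keeps deletions with ≥ 50% of wild-type biomass and
sorts by `biomass_ratio - acetylation_ratio`, breaking ties toward higher
biomass. The nutrient screen uses one shared baseline for all conditions
and records it in the result's attributes.

## Transcriptome integration

`discretize()` maps an expression profile to gene states (low / moderate /
high) by quantile thresholds (default: bottom and top quartile) and
propagates them through gene-protein-reaction rules with AND = min,
OR = max. When integrating a cohort, thresholds are computed against the
pooled cohort distribution rather than per sample (`reference` argument,
used automatically by `integrate_cohort()`): per-sample quantiles force a
fixed fraction of each sample's genes into the low state regardless of
biology, which on a small network randomly severs entire carbon routes;
panel-relative thresholds make a call mean "low *for this panel*", which is
the appropriate reading for cell-line cohorts.

`integrate_imat_linear()` solves a single LP in split fluxes
($v = p - q$, $p, q \ge 0$, so $p + q$ linearizes $|v|$): low-state
reactions pay a penalty per unit of absolute flux, high-state reactions
carry a soft activation reward (a penalized shortfall slack against an
activation level of 0.001 mmol/gDW/h), and the biomass + ε·acetylation
objective is retained. Constraints stay soft, so conflicting expression
evidence is traded off rather than causing infeasibility. One subtlety of
the split-variable relaxation: a reversible high-state reaction can satisfy
its activation by circulating $p$ and $q$ simultaneously; the bundled
networks keep their acetylation-relevant reactions irreversible, and the
enumeration oracle in the tests uses the same $|v|$ convention, so the
check is exact. Penalty and reward weights default to 1.0; the tests probe
other values.

`integrate_gimme()` is the robustness check: minimize
$\sum_r \max(0, t - e_r)\,|v_r|$ (reaction expression $e_r$ via the same
rule folding, threshold $t$ at the 25th percentile) subject to biomass at
least 90% of its optimum, then — within that penalty optimum — re-maximize
the weighted biomass + ε·acetylation objective and read the flux state.
Re-maximizing the *weighted* objective in the final stage (rather than
acetylation alone) makes a penalty-free profile reduce exactly to plain
weighted FBA, which keeps the two integrators comparable; maximizing
acetylation alone would instead report the acetylation ceiling at the 90%
biomass floor even for uninformative profiles.

Drug effects enter as up/down gene signatures (`drug_signature()`,
`apply_drug_signature()`): signature genes are forced high/low on top of a
sample's basal states, reaction states are recomputed, and
`acetylation_delta()` reports the flux reduction the drug's transcriptional
footprint causes.

## Synthetic cohorts and drug response

`make_expression_cohort()` plants a dichotomy in acetyl-CoA-synthesis
capacity: a minority (default 25%) of samples shifts the six
acetyl-CoA-route genes up by half the effect size, the rest down by the
other half; all genes carry lognormal noise (σ = 0.5 log2 units). The
defaults (effect = 4 log2 units, fraction 0.25) were chosen at design time
so the planted signal behaves as an on/off capacity difference under
quartile discretization: with the high fraction at 0.25, the planted-low
expression mass just exceeds the bottom-quartile threshold, so the
threshold falls *inside* the planted cluster and false low-calls on
housekeeping genes become rare by construction. The generator emulates the
bimodal flux landscape of a real cell-line panel; it does not emulate
dropout, batch effects, correlated co-expression, or the thousands-of-genes
scale of real transcriptomes — passing tests show the inference machinery
recovers a planted signal, not that it is robust to those real-data
features.

`make_drug_response()` draws AUC values (area under the growth curve;
lower = more inhibition) as
`intercept - slope * flux - strength * delta + noise` with defaults
intercept 12, slope 0.26 AUC units per flux unit (spacing the two flux
modes of the default cohort by a few AUC units), Gaussian noise σ = 1.5,
and an optional per-(line, drug) flux-reduction term. Both generators are
pure functions of their spec (seed included).

The statistics layer mirrors standard practice: Welch t-tests for group
comparisons (the unequal-variance form is the robust default), Pearson
correlation with two-sided p, per-line median normalization of multi-drug
AUC panels, a two-sided deviation rule (|delta − per-line median| >
threshold, default 10% of the cohort's median nonzero flux) for calling
differential drug pairs, an upper-tail hypergeometric test for gene-list
overlap, and a compound-level selectivity screen (per-compound high-vs-low
group AUC difference, compared between KDAC inhibitors and the rest of a
library). Cell lines with fewer than two drug values are dropped from
normalization; compounds without enough data in both flux groups are
dropped from the selectivity screen, with counts reported. A flux exactly
at the 0.05 bimodal cutoff goes to the high group (the low group is
defined by strict `< 0.05`). No multiple-testing correction is applied to
these screen-level statistics.

## Problem sizes and reproducibility

The default test and acceptance runs use the ~30-reaction network, cohorts
of 60 samples, 100 seeded replicates for the recovery and null-calibration
experiments, and brute-force oracles on networks of at most 8 reactions —
sizes at which every LP is exactly checkable and a full run completes in
minutes on one core. `integrate_cohort()` deduplicates identical
discretized states across samples, so a bimodal cohort costs a handful of
LP solves rather than one per sample. `scripts/acceptance.R` re-derives
the headline quantities from scratch under a caller-supplied seed.

## Known limitations

- The LP backend is dense; genome-scale solving is out of scope.
- Acetylation is bulk-level: no site resolution, no deacetylation
  kinetics, no distinction between individual histone marks.
- The augmentation assumes a single cytosolic ACLY reaction to mirror
  into the nucleus and maps species by an explicit table; reconstructions
  with different naming need a custom `species_map`.
- Signatures are consumed as given gene lists; deriving them from raw
  differential expression is out of scope.
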