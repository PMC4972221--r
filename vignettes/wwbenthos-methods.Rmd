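---
title: "Methods: trait-based detection of wastewater impacts in streams"
author: "wwbenthos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based detection of wastewater impacts in streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wwbenthos)
```

## The design and its logic

wwbenthos analyses a replicated upstream/downstream survey of benthic
macroinvertebrates around wastewater treatment plant outfalls. Each stream
contributes three sampling locations: two upstream references (U2 furthest
upstream, U1 just above the outfall) and one downstream impacted reach (D).
The second reference is the crucial design element: the U2 to U1 contrast
measures how much two unimpacted reaches of the same stream differ
naturally, so every downstream contrast can be corrected for that natural
longitudinal drift. All change statistics in the package are built on this
BACI-style logic, space-for-time with internal controls.

Two competing explanations of downstream community change are
distinguished:

* **environmental context** — communities already shaped by catchment
  agriculture are dominated by pollution-tolerant taxa and should resist an
  organic-enrichment disturbance;
* **magnitude of disturbance** — the response should scale with how much
  wastewater the stream receives, both in quantity (dilution) and in
  composition (effluent chemistry).

## Descriptors

`descriptorMatrix()` computes, per location: taxa richness, Hurlbert
rarefied richness (exact hypergeometric expectation, standardized by
default to the smallest location total — no resampling), Pielou's evenness
(Shannon entropy with natural logs over `ln S`, so a perfectly even
community scores exactly 1), Fisher's log-series alpha (the root of
`S = alpha ln(1 + N/alpha)`, solved to a residual below 1e-10), the
Saprobic Index, the SPEAR pesticides index, and six supplementary
descriptors (total abundance, EPT richness, %EPT, the oligochaete-excluded
variants, Berger-Parker dominance).

The two trait-based indices carry the ecological signal:

* **Saprobic Index**: `SI = sum(s_i g_i a_i) / sum(g_i a_i)` with taxon
  saprobic values `s` in [1, 4], indicator weights `g` in 1..5 and the raw
  count as abundance term `a`. Using raw counts rather than a categorical
  abundance-class coding keeps the operation self-contained; an
  `abundance_class` hook accepts any class transform. Unscored taxa are
  excluded from numerator and denominator, never imputed.
* **SPEAR**: `100 * sum(w(x_i) [i in SPEAR]) / sum(w(x_i))` with the
  log-damped weight `w(x) = log10(4x + 1)`, the canonical form for this
  index. Membership is an input flag in the trait table, not derived from
  a trait database. The log damping makes the index sensitive to
  presence/absence of rarer taxa — a property that matters for the noise
  model below.

## Change statistics

For each descriptor `d`, the null-corrected change per stream is
`(d_D - d_U1) - (d_U1 - d_U2)`: zero whenever the downstream change equals
the natural drift. For whole-community change, all 36 locations enter one
joint NMDS (two axes, Hellinger-transformed counts, Euclidean distances);
Total Community Change is the Euclidean displacement U1 to D minus the
displacement U2 to U1 in that ordination. TCC may legitimately be
negative (downstream shift smaller than natural drift) and is passed
through unfloored. TCC is invariant under rotation and translation of the
NMDS configuration, which the tests assert.

Whether the joint ordination should span all locations or a subset is not
fixed by the design; the package ordains all locations at once so that the
three scores per stream are directly comparable.

## Predictors

Six predictors enter every multiple-regression model:

1-3. **RD1-3_invert** — U1 site scores on the first three constrained axes
  of a partial RDA of the upstream communities on land use plus reach-scale
  chemistry, conditioned on forward-selected PCNM spatial eigenvectors.
  These axes summarize the upstream community composition, i.e. the
  environmental context.
4. **DF_ww** — the dilution factor `Q347 / Q_ww` (low-flow discharge over
  mean wastewater discharge); small values mean strong disturbance.
5. **PC1_ww** — first component of a correlation-scaled PCA of the 20
  downstream water-chemistry variables, summarizing effluent composition.
  PCA signs are arbitrary, so the component is oriented to correlate
  positively with total nitrogen.
6. **PC_habitat** — a two-stage habitat-change score: stage 1 is a PCA of
  the habitat block over the U1 and D rows; stage 2 collapses the
  per-stream D-minus-U1 differences of the first three component scores to
  one score by an *uncentred* PCA, so a stream with identical upstream and
  downstream habitat scores exactly zero. The sign follows the
  fine-sediment (mud) change. The two stages are exposed separately so
  either can be swapped.

Predictor sets for constrained ordination pass a collinearity pre-filter
(greedy in input-column order, dropping any column with `|r| >= 0.6`
against a retained one; the published description "r < 0.6" is read as
the retention condition) and a forward selection.

## Inference

**Hierarchical partitioning** (`hierPart`, `hierPartZ`) fits all `2^k` OLS
subsets and averages each predictor's R-squared increments over hierarchy
levels, splitting explained variance into independent (I) and joint (J)
effects. Two identities are asserted on every call: `sum(I)` equals the
full-model R-squared and `I + J` equals the univariate R-squared, both to
1e-10. Significance uses randomization: the response is permuted (the
published description says only "randomizations of the data matrix";
permuting the response preserves the predictor correlation structure,
which is the relevant null), and `Z = (I_obs - mean(I_rand))/sd(I_rand)`
is flagged at the upper 95% confidence limit Z > 1.65. Because I is a
non-negative R-squared-like quantity its randomization distribution is
right-skewed and the Z > 1.65 rule is mildly liberal (about 0.07 observed
rejection under a simulated null instead of 0.05); this is a property of
the published procedure, reproduced rather than corrected.

**Forward selection** is greedy on the adjusted-R-squared gain
(Ezekiel's formula `1 - (1 - R2)(n - 1)/(n - p - 1)`), with an optional
double stop at the full-model adjusted R-squared. The per-step permutation
test compares the observed best gain against the permutation distribution
of the *maximum* gain over all remaining candidates. Testing the maximum,
rather than the selected candidate in isolation, accounts for the
selection step and keeps the procedure calibrated under a global null (the
tests show an empty-selection rate of about 1 - alpha on pure noise);
testing the selected candidate alone would be anti-conservative.

**Blocked ANOVA** (`blockedAnova`) tests the location effect with stream
as a block — under the balanced design this is exactly the mixed model
with a random stream intercept, and the tests verify F and denominator df
against an REML fit. The stream variance share is the method-of-moments
component `(MS_stream - MS_err)/(MS_stream + (k - 1) MS_err)`, floored at
zero (negative method-of-moments components are a known artifact). Tukey
HSD contrasts use the studentized range on the error df. Cohen's d (D vs
pooled upstream) uses the group-pooled, n-weighted SD; other poolings
exist and give different values on the same means, so d is reported as
descriptive output only.

**PERMANOVA** permutes freely across all rows by default; a `strata`
option restricts permutations within streams but is off by default, since
the location test is meant to see between-stream exchangeability.
Permutation p-values throughout use `(1 + count)/(1 + n_perm)`, which can
never report zero.

## The synthetic-data generator

`simulateStreams()` emulates the study conditions: 12 streams x 3
locations, about 60 taxa in four ecological roles (oligochaetes, SPEAR+EPT
insects, tolerant chironomid/gammarid-like taxa, background taxa),
catchment agriculture spanning 5-80% cover and downstream wastewater
fractions spanning 23-133% of the low-flow discharge (both spans exact,
order randomized). It is parameterized on the *descriptor scale*: upstream
Saprobic Index rises linearly with agriculture, upstream SPEAR falls with
arable cover, the downstream oligochaete share follows
`0.35 - 1.40 (SI_up - 1.94)` against `0.10 + 0.468 (SI_up - 1.94)`
upstream (slopes on the share scale matching the reported per-percent
values), and the downstream SPEAR target drops by `gamma_spear_df` index
points per unit wastewater fraction. A numerical solver then finds taxon
compositions whose *realized* index values — through the actual index
formulas, including the log-damped SPEAR weights — hit those targets, so
ground truth and pipeline agree by construction on noise-free data
(`dispersion = Inf`, all sigmas zero). Counts are negative-binomial
(ecological counts are overdispersed); chemistry and habitat covariates
are phenomenological log-linear responses, with a stream-specific
effluent-quality factor carried by 13 of the 20 chemistry variables.

Noise defaults were fixed once against the reported strength of the key
relationships: upstream SPEAR~arable R2 about 0.75, SI~agriculture about
0.5, SPEAR change~dilution factor about 0.6, mean downstream Saprobic
increase about +0.5, mean location richness about 26. One compromise is
documented: because SPEAR's log-damped weights give rare-taxon presence
flicker a noise floor of about 1.6 index points per location at
realistic count totals, matching the reported change-regression strength
requires a mean downstream SPEAR drop (about 13 points) larger than the
field value (about 4 points). The generator reproduces the reported
signal-to-noise ratio at the cost of the absolute effect size; analyses
of absolute SPEAR changes on synthetic data should keep that in mind.

What the generator does *not* emulate: temporal (seasonal) turnover,
taxonomic aggregation error, spatially autocorrelated community structure
beyond the stream blocks, hydrological or chemical process dynamics, and
zero-inflation beyond what the negative binomial produces. Passing
recovery tests therefore show that the estimators detect the planted
structure at realistic noise, not that they are robust to every field
artifact.

## Numerical choices and degenerate inputs

* Rarefaction uses `lchoose` differences, stable up to very large totals;
  `n` above the location total is an error naming the largest admissible
  standardization.
* `fisherAlpha` brackets the root in `[1e-8, 2^m]` and refines with
  `uniroot` at machine tolerance; `S == N` (all singletons) is an explicit
  divergence error.
* NMDS runs `vegan::monoMDS` (Kruskal stress-1, monotone regression) from
  a metric (PCoA) start plus `n_starts - 1` random starts, keeping the
  lowest stress; configurations are centred and principal-axis rotated.
  Convergence tolerances are tightened (`smin = 1e-12`) so perfectly
  embeddable configurations report stress below 1e-6. Defaults: k = 2,
  20 starts, ratio tolerance 1e-7.
* Variation partitioning reports negative shared fractions as computed
  (the inclusion-exclusion identity then holds to 1e-10) plus a
  zero-floored view for display.
* All randomized stages take a seed; the pipeline derives per-stage seeds
  from one root seed, giving byte-identical reports across reruns.
* Degenerate PERMANOVA input (all distances zero) yields a flagged
  `NA` p-value, never a silent number; an all-equal descriptor in the
  blocked ANOVA reports F = 0 with all Tukey p-values 1.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline on 12-stream surveys
(36 locations x 60 taxa, about half a second per run), uses 100 replicate
surveys for parameter recovery, 500 simulated nulls for PERMANOVA
calibration and 200 for forward selection and the randomization Z, with
permutation counts of 99-199 inside simulations and the defaults
(999 permutations, 1000 randomizations, 20 NMDS starts) for single
analyses. These sizes keep a full check under a few minutes on one core
while leaving the Monte-Carlo bounds comfortably away from their binomial
noise.

## A worked run

```{r example, eval = FALSE}
cfg <- pipelineConfig(params = simParams(seed = 1), seed = 1)
bundle <- runPipeline(cfg)
bundle$anova_table          # location means, F, Tukey, variance shares
hierpartTable(bundle)       # I, J, %I, Z per response and predictor
renderReports(bundle, "reports/")
```

## Known limitations

* The Swiss IBCH biotic index is not computed; a precomputed column can be
  carried through from the input tables.
* The mixed model is implemented as its balanced-design ANOVA equivalent;
  heavily unbalanced data are handled by listwise exclusion of incomplete
  streams, not by REML.
* The randomization-Z procedure inherits the mild anti-conservatism noted
  above.
* With twelve streams, six predictors in an all-subsets decomposition is
  near the practical ceiling (n must exceed k + 1); interpret joint
  effects with caution at this n.
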