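# wwbenthos

Trait-based analysis of stream macroinvertebrate responses to wastewater
point sources.

## The problem

Treated wastewater enters a stream as a press disturbance whose footprint
depends both on how much effluent arrives relative to baseflow and on what
the receiving community already looks like. Communities in agricultural
catchments are pre-filtered toward pollution-tolerant taxa and may barely
respond to additional organic enrichment, while the same input depresses
pesticide-sensitive taxa wherever dilution is poor. Disentangling this
*environmental context* from the *magnitude of disturbance* requires a
replicated design with internal controls: per stream, two upstream
reference reaches (U2, U1) and one reach (D) below the outfall, replicated
across streams spanning a land-use gradient.

wwbenthos implements that analysis end to end for benthic invertebrate
count data, and ships a calibrated synthetic-data generator that emulates a
twelve-stream survey with known ground truth, so every estimator can be
checked for parameter recovery.

## The statistics at its core

* **Trait indices.** Saprobic Index
  `SI = Σ s_i g_i a_i / Σ g_i a_i` (taxon saprobic values `s ∈ [1,4]`,
  indicator weights `g ∈ 1..5`, counts `a`), and the SPEAR pesticides
  index `100 · Σ_{i∈SPEAR} w(x_i) / Σ_i w(x_i)` with log-damped weights
  `w(x) = log10(4x + 1)`; plus richness, Hurlbert rarefied richness,
  Pielou's J, Fisher's α, and EPT/dominance metrics.
* **Null-corrected change.** Per descriptor and stream,
  `Δ = (D − U1) − (U1 − U2)`; for whole communities, Total Community
  Change `TCC = ‖NMDS_D − NMDS_U1‖ − ‖NMDS_U1 − NMDS_U2‖` from one joint
  two-axis NMDS (Hellinger-transformed counts, Euclidean distances).
* **Disturbance predictors.** Dilution factor `DF_ww = Q347 / Q_ww`;
  wastewater composition `PC1_ww` (PCA of 20 chemistry variables);
  habitat change `PC_habitat` (two-stage PCA); and upstream community
  composition axes `RD1–3_invert` from a partial RDA conditioned on
  forward-selected PCNM spatial eigenvectors.
* **Inference.** Hierarchical partitioning over all 2^k regression
  subsets (independent effects `I`, joint effects `J`, with
  `ΣI = R²_full` and `I + J = R²_univariate` as asserted identities),
  randomization Z-scores (significant at Z > 1.65), partial correlations,
  stream-blocked ANOVA with Tukey HSD and stream variance components,
  Cohen's d, and PERMANOVA of location groups.

## Worked example

```r
library(wwbenthos)

se <- simulateStreams(simParams(seed = 1))
se
#> StreamExperiment: 60 taxa x 36 sampling locations
#>   streams: 12  positions: U2/U1/D
#>   SPEAR taxa: 21  EPT taxa: 23  oligochaetes: 3

d <- descriptorMatrix(se)
round(head(d[, c("taxa_richness", "evenness", "saprobic", "spear")], 4), 3)
#>        taxa_richness evenness saprobic  spear
#> s01_U2            31    0.674    1.998 40.181
#> s01_U1            26    0.688    2.011 40.474
#> s01_D             25    0.658    2.595 34.541
#> s02_U2            25    0.648    1.944 51.488

bundle <- runPipeline(pipelineConfig(params = simParams(seed = 1), seed = 1))
bundle
#> ReportBundle: 12 streams, 36 locations
#>   NMDS stress 0.0730 | PERMANOVA F = 7.43, R2 = 0.31, p = 0.001
#>   responses modelled: d_taxa, d_rarefied, d_evenness, d_fisher,
#>   d_community, d_spear, d_saprobic
```

Stream s01 illustrates the planted structure: downstream of the outfall
the Saprobic Index rises (2.01 → 2.60, organic enrichment) and SPEAR falls
(40.5 → 34.5, toxicant stress). Across streams, the hierarchical
partitioning attributes the SPEAR change to the dilution factor:

```r
ht <- hierpartTable(bundle)
head(ht[ht$response == "d_spear",
        c("predictor", "I", "J", "total", "pct_I", "Z", "significant")], 3)
#>  predictor      I       J  total pct_I      Z significant
#>      DF_ww 0.4226 -0.0493 0.3733  54.4  3.205        TRUE
#> PC_habitat 0.1626 -0.1080 0.0546  21.0  0.755       FALSE
#> RD1_invert 0.0802  0.0261 0.1063  10.3 -0.144       FALSE
```

`DF_ww` carries 54% of the explained variance with Z = 3.2 — the
dilution factor, not the upstream context, drives the SPEAR response. The
blocked ANOVA shows both trait indices shifting downstream, with the
Saprobic Index response shared across all streams (stream variance 0%)
while SPEAR levels are strongly stream-specific (75%):

```r
bundle$anova_table[5:6, c("mean_U1", "mean_D", "F", "p",
                          "stream_var_pct", "cohens_d")]
#>   mean_U1 mean_D      F p stream_var_pct cohens_d
#> 5   2.037  2.472 28.460 0          0.000    2.825
#> 6  42.148 28.250 76.586 0         75.442   -2.186

renderReports(bundle, "reports/")   # CSV tables + run log
```

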