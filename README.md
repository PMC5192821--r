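# phet

Soil nutrient heterogeneity, tree species diversity, and community
phylogenetic structure — an analysis pipeline for plot-based forest
studies, plus a scenario-based synthetic-data generator for calibrating
and power-checking every stage of the analysis.

## The scientific problem

Does within-plot heterogeneity of a limiting soil nutrient (phosphorus,
in most tropical forests) promote tree species diversity? Niche theory
says yes (more niches can be partitioned), neutral theory says no
(composition is drift- and dispersal-driven), and a unimodal variant
predicts a hump (extreme heterogeneity shrinks per-species effective
area). Community phylogenetics adds a diagnostic: if heterogeneity lets
closely related species coexist, plots should shift from phylogenetic
overdispersion at low heterogeneity to clustering at high heterogeneity.

`phet` computes, per 20 × 20 m plot:

* soil nutrient availability *M* and heterogeneity CV = SD/*M* from
  replicated samples (plus natural-log versions used for correlation);
* richness, Shannon's *H′* = −∑ fᵢ ln fᵢ, the effective number of
  species e^*H′*, and individual-based rarefied richness
  E[S_n] = ∑ᵢ (1 − C(N−Nᵢ, n)/C(N, n));
* MPD (unweighted mean pairwise cophenetic distance), its standardized
  effect size under the taxa-labels permutation null,
  SES = (MPD_obs − mean of randomized values)/SD, and the net
  relatedness index NRI = −SES (positive = clustering, negative =
  overdispersion);
* rooted Faith's phylogenetic diversity with analytic individual-based
  rarefaction E[PD_n] = ∑_b L_b (1 − C(N−N_b, n)/C(N, n)), and the
  Hill-number phylogenetic diversity of order q = 1;
* Shapiro–Wilk normality screening and the Pearson correlation grid
  (r, two-sided p at α = .05) relating nutrient availability and CV to
  the diversity and structure metrics.

The generator (`simulate_dataset()`) emulates the study design — 39
plots, four soil samples per plot, a 156-species pool on an ultrametric
tree, 84–300 stems (DBH > 1 cm) per plot — under three assembly regimes
(`niche_coupled`, `unimodal`, `neutral`). See the vignette
(`vignettes/soil-heterogeneity-phylodiversity.Rmd`) for the models,
conventions, and calibration rationale.

## A worked example

```r
library(phet)

sim <- simulate_dataset(sim_config(scenario = "niche_coupled", seed = 1))
run <- run_pipeline(sim$tree, sim$community, sim$soil,
                    n_rand = 999, seed = 1)
print(run)
```

```
phet pipeline run: 39 plots, 156 species, rarefied to n = 85, 999 randomizations (seed 1)
significant correlations at alpha = 0.05: 5 of 19
  EP_log_cv ~ R_TR: r = 0.669, p = 3.25e-06 (n = 39)
  EP_log_cv ~ e_H: r = 0.643, p = 1e-05 (n = 39)
  EP_log_cv ~ nri: r = 0.489, p = 0.00159 (n = 39)
  EP_log_cv ~ pd_rarefied: r = 0.491, p = 0.00152 (n = 39)
  EP_log_cv ~ hill_pd_q1: r = 0.352, p = 0.0281 (n = 39)
```

Under niche-coupled assembly, only the phosphorus-heterogeneity (log
CV of EP) correlations come out significant: heterogeneous plots hold
more (rarefied) species, higher effective species numbers and higher
phylogenetic diversity, and their NRI rises — exactly the
niche-partitioning signature. Nutrient *availability* shows no effect,
and a neutral-scenario run leaves the grid empty of significant
heterogeneity correlations. The per-plot table carries the underlying
values:

```r
head(run$metrics[, c("plot_id", "richness", "R_TR", "e_H", "nri",
                     "pd_rarefied", "hill_pd_q1", "EP_cv")])
```

```
 plot_id richness R_TR   e_H    nri pd_rarefied hill_pd_q1  EP_cv
     P01       29 20.7 14.98  2.106        8.33       4.50 0.3691
     P02       54 32.3 30.76  0.453       11.03       5.73 0.5628
     P03       20 19.7 10.72 -1.329       10.14       4.85 0.0967
     P04       21 15.5  9.89 -1.201        8.52       4.83 0.1953
     P05       20 15.5 10.26 -1.076        8.56       5.21 0.1904
     P06       25 24.6 17.60 -1.200       11.21       6.46 0.4142
```

`write_pipeline_outputs(run, dir)` writes `metrics.csv`,
`correlations.csv`, `normality.csv` and a `manifest.json` recording the
seed, version and input checksums. The same pipeline runs from files
(Newick tree, community CSV, soil CSV — `write_dataset()` emits all
three plus the simulation truth), and `validate_inputs()` reports any
inconsistencies first.

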