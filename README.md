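# cricketnets

Social-network analysis of pre- and post-copulatory male competition in
burrow-dwelling crickets (and similar burrow-structured mating
systems).

In field crickets, males compete for fertilizations before mating — by
fighting rivals at burrows — and after mating, when the ejaculates of
males that inseminated the same female compete inside her.  Both arenas
can be represented as social networks over the same males, which makes
three questions answerable from one season of observations:

1. **Within pairs** — are males that fight each other more also in
   stronger sperm competition, controlling for spatial and temporal
   overlap?
2. **Within individuals** — do males with many fighting opponents also
   have many sperm-competition rivals?
3. **Across the mating network** — do promiscuous males mate with
   promiscuous females (positive degree correlation), beyond what
   spatial and temporal structure alone would produce?

The package is aimed at behavioural ecologists with tabular observation
records: a roster (id, sex, emergence day, death day), burrow occupancy
(total time observed per individual per burrow), fight events and
mating events.

## The models at the core

* **Networks.**  Fighting: `w[i,j]` = number of times male `i` arrived
  at a burrow and fought resident `j` (directed).  Sperm competition:
  the one-mode projection of the male x female matrix `M` of
  spermatophore transfers, `w[i,j] = Σ_f 1[M[j,f] > 0] · M[i,f]`.
  Spatial overlap: own time at shared burrows, symmetrized by the
  geometric mean `√(w[i,j]·w[j,i])`.  Temporal overlap: shared days of
  adult life (inclusive).  Males that never shared a burrow with
  another male are removed before analysis.

* **MRQAP** (prediction 1): OLS over unordered dyads,

  `y_ij = β0 + β_F·Fighting_ij + β_S·Space_ij + β_T·Time_ij + ε_ij`,

  predictors centered and scaled, with permutation p-values from
  Dekker double-semipartialling: each predictor's residual matrix is
  node-permuted and the t-value of the permuted term compared with the
  observed one, `p = (b + 1)/(n_perm + 1)`.

* **Node statistics** (prediction 2): degree (unique partners) and
  strength (total instigated weight) compared by an exact-under-ties
  Wilcoxon signed-rank test and correlated by Spearman's r_s.

* **Constrained degree-correlation null** (prediction 3): observed
  endpoint-degree correlation over mating edges, against networks drawn
  by including each pair of the space x time possibility set
  independently at the observed density.

A mechanistic season simulator (burrow clusters, sedentary territorial
males, roving phonotactic females, arrival fights, mate
monopolization) generates complete observation sets with optional
planted effects for calibration and power studies.

## Worked example

```r
library(cricketnets)

cfg <- synthetic_preset("cohort", beta_fight_sperm = 1.5,
                        assortativity_strength = 2, seed = 2026)
obs <- generate_observations(cfg)
obs
#> <observation_set: 80 individuals (40 male, 40 female), 433 occupancy
#>  records, 183 fights, 203 matings>

report <- run_full_analysis(obs, n_perm = 999, n_sim = 999, seed = 1)
report
#> == Competition-network analysis report ==
#> 40 males (39 retained after isolate filtering), 741 dyads
#>
#> -- Mantel covariate checks --
#>   fighting_space: r = 0.442, p = 0.001
#>   fighting_time: r = 0.209, p = 0.001
#>   space_time: r = 0.074, p = 0.077
#>
#> -- Within-pair: MRQAP (sperm competition ~ fighting + space + time) --
#> MRQAP network regression (dsp permutations, t statistic)
#>          coefficient     p
#> Fighting      0.4947 0.001
#> Space        -0.2093 0.001
#> Time          0.3255 0.001
#> R^2 = 0.223, residual SE = 1.124, df = 737, dyads = 741, 999 permutations, seed = 201
#>
#> -- Within-individual --
#>   degree comparison: medians 4 (fighting) vs 6 (sperm), W = 118.5, N = 37, p = 0.0004411
#>   degree correlation: r_s = 0.695, p = 9.257e-07
#>   strength correlation: r_s = 0.560, p = 0.0002114
#>
#> -- Mating-network degree correlation --
#> Degree-correlation null model: observed r_s = 0.1466, p = 0.021 (upper tail)
#>   999 simulated networks (edge rate 0.172 over 705 possible pairs, 0 redraws)
```

Reading the output: fighting predicts sperm competition within pairs
even with spatial and temporal overlap in the model (the seeded data
plant exactly this coupling); males with many fighting opponents have
many sperm-competition rivals (r_s = 0.70); and the mating network is
more assortative by promiscuity (r_s = 0.147) than 97.9% of
density-matched networks drawn from the pairs that could have mated.
Note `df = 741 − 4 = 737`: the regression uses each unordered male
pair once, with an intercept, which you can audit from the reported
degrees of freedom.

`write_analysis_report(report, "out/")` emits `report.json`, a
regression table CSV and the simulated null draws;
`write_observation_set(obs, "data/")` round-trips the records as four
CSVs.  A thin command-line front end with `simulate` / `analyze` /
`report` verbs is installed at
`system.file("cli", "cricketnets.R", package = "cricketnets")`.

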