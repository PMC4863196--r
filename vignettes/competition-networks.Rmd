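---
title: "Competition networks from burrow-structured observation records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition networks from burrow-structured observation records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cricketnets)
```

## The question and the data

In burrow-dwelling field crickets, males compete for fertilizations
twice: before mating, by fighting other males at burrows, and after
mating, when the ejaculates of males that inseminated the same female
compete inside her.  Whether the same pairs and the same individuals are
involved in both arenas determines whether pre-copulatory success can
shield a male from post-copulatory competition, and ultimately whether
"specialist" male strategies can evolve.

`cricketnets` takes a season of observation records — a roster of adults
with emergence and death days, total time observed per individual per
burrow, fight events, and mating events with a spermatophore-transfer
flag — and answers three questions:

1. **Within pairs**: do males that fight each other more also compete
   more in sperm competition, after accounting for how much the pair
   overlapped in space and time?
2. **Within individuals**: is a male's number of fighting opponents
   correlated with his number of sperm-competition rivals?
3. **Across the mating network**: do promiscuous males tend to mate
   with promiscuous females (positive degree correlation), relative to
   what spatial and temporal structure alone would produce?

## Networks

Four male-by-male matrices and one male-by-female matrix are built:

* **Fighting** (directed): `w[i, j]` counts the fights in which male
  `i` arrived at a burrow and fought resident `j`.
* **Mating** (bipartite): `M[m, f]` counts matings between `m` and `f`
  in which a spermatophore was transferred; unsuccessful mounts are
  excluded at this step and nowhere else.
* **Sperm competition** (directed): the one-mode projection
  `w[i, j] = sum over females f mated by j of M[i, f]`.  Each
  spermatophore is one unit of investment competing for a share of a
  shared female's eggs, so mating once with each of two shared females
  and mating twice with one shared female yield the same strength.
* **Temporal overlap** (symmetric): shared days of adult life, counted
  inclusively — two individuals alive on the same single day overlap by
  one day, not zero.
* **Spatial overlap** (symmetric): the directed intermediate
  `w[i, j]` sums `i`'s observed time at burrows both males used;
  reciprocal values are then combined by their geometric mean.

Directed matrices entering pairwise analyses are symmetrized by the
**geometric mean** of the two reciprocal weights,
`sqrt(w[i, j] * w[j, i])`.  Unlike the arithmetic mean this rewards
balanced interaction: reciprocal weights (5, 5) give 5 while (1, 9)
give 3, although both average 5; a one-sided interaction gives 0.  A
consequence worth knowing: a directed network with *no* reciprocal
dyads symmetrizes to an all-zero matrix, and the pipeline then stops
with a stage-labelled degeneracy error rather than silently regressing
on a constant.

**Isolate filtering.**  Males that never shared a burrow with another
male cannot fight and are unlikely to enter sperm competition; they are
removed once per season, before network construction, and all male-male
matrices are built over the retained set.  Males retained but inactive
in one network keep zero rows rather than being dropped.

## Within-pair inference: MRQAP with Dekker semipartialling

The sperm-competition network is regressed on the fighting network with
spatial and temporal overlap as covariates, over the **unordered dyad
set** (each pair once, diagonal excluded) with an intercept:

$$y_{ij} = \beta_0 + \beta_F F_{ij} + \beta_S S_{ij} + \beta_T T_{ij} + \varepsilon_{ij}$$

Each predictor is centered and scaled over its dyads (population SD),
so coefficients are per-SD effects.  Degrees of freedom are
`n_dyads - 4`; with 39 retained males that is `C(39,2) - 4 = 737` and
with 96 males `4560 - 4 = 4556`, so the unordered-dyad convention is
auditable directly from the reported df.

Dyadic observations are not independent — dyads sharing a node are
correlated — so p-values come from the quadratic assignment procedure:
node labels are permuted (rows and columns together), which preserves
the network's dependence structure.  Because the covariates are
themselves correlated with the predictor of interest (the Mantel
pre-check in every report quantifies this), the package uses **Dekker
double-semipartialling**: each predictor is residualized on the others,
the residual matrix is node-permuted, the response is refit on the
other predictors plus the permuted residual, and the pivotal statistic
— the t-value of the permuted term, by default — is compared to its
observed value.  Two-sided p-values use the add-one convention
`(b + 1) / (n_perm + 1)` so zero is impossible and the resolution floor
is `1/(n_perm + 1)`.  With `exact = TRUE` all `n!` permutations are
enumerated (up to 8 nodes); the identity permutation reproduces the
observed t exactly, by the Frisch–Waugh identity.  A naive
response-permutation variant (`mrqap_y_permute()`) is included as a
cross-check; it agrees with semipartialling when predictors are
uncorrelated and is known to misbehave when they are not.

## Within-individual and mating-network analyses

**Degree** is the number of unique partners (weights affect only edge
existence); **strength** is the total weight a male instigates, defined
on the original directed networks.  Each male's fighting and
sperm-competition degrees are compared by a paired Wilcoxon signed-rank
test, and correlated by Spearman's rank correlation (repeated with
strength as a robustness check).  The signed-rank test enumerates the
exact null distribution over all `2^n` sign assignments for up to 14
non-zero differences — exact even under tied magnitudes, which the
usual implementations approximate — and uses the tie-corrected normal
approximation with continuity correction beyond that.

**Degree correlation.**  Over the edges of the mating network, the
degrees of the two endpoints are collected and their Spearman
correlation computed; positive values mean promiscuous individuals pair
with promiscuous partners.  Significance cannot come from a free null:
crickets can only mate if they overlapped in space and time, and that
structure alone induces nonzero degree correlations.  The constrained
null therefore multiplies the spatial and temporal overlap matrices
(over mixed-sex pairs) to obtain the **possibility set** — pairs that
were both alive at some point and used at least one common burrow — and
draws each possible edge independently with probability
`E_obs / E_poss`, matching the observed density on average.  Degenerate
draws (fewer than 3 edges, or no degree variance) are redrawn, up to
`50 * n_sim` attempts, and the redraw count is reported.  The default
tail is upper (promiscuity assortment is the directional hypothesis); a
two-sided option doubles the smaller tail.

## The simulator

`generate_observations()` produces complete observation sets from a
daily process: adults emerge on staggered days (uniform over
`emergence_spread`), live a negative-binomial number of days
(`lifespan_dispersion = 1` gives the geometric lifespans typical of
wild insect adults, standard deviation near the mean), and occupy one
burrow per day.  Males are sedentary territorial residents drawing
burrows from a home cluster; females rove, and with probability
`female_attraction` a move targets a singing male's burrow
(phonotaxis).  Fights happen on arrival — a male landing on an occupied
burrow fights the resident with probability
`fight_prob_on_male_encounter`, with a same-day return bout
(`refight_prob`) giving the directed network its reciprocal weights —
while settled cohabitants do not re-fight daily.  A female mates at
most one male per burrow visit (mate monopolization; her phonotaxis
target when present), with probability
`1 - exp(-mating_rate_scale * multiplier)` per day, and a spermatophore
transfers with probability `spermatophore_success_prob`.
`cluster_popularity` concentrates the population in a few good habitat
patches, which simultaneously produces frequent fighting among the
concentrated males and many spatial isolates — the low-density field
regime.

Three presets document the regimes used throughout:
`"y2006-like"` (74 males among 151 adults, ~12 observed days, roughly a
third of males isolated), `"y2013-like"` (119 males among 239 adults,
~14 observed days, under a tenth isolated), and `"cohort"` (below).

### Planted effects

Both planted effects are built from multipliers that equal 1 at
strength 0, so null configurations are exactly null.

* `beta_fight_sperm` couples fighting and sperm competition within
  pairs in both causal directions: females are preferentially attracted
  to males that fought their previous mates (consistent preferences —
  matched males attract the same females) and convert those visits more
  readily; and males occasionally seek out a sperm-competition rival
  for a brief skirmish that is recorded as a fight without displacing
  either resident.  The occupancy-neutral skirmish matters: if
  challenges relocated males, the planted signal would leak into the
  spatial covariate and be absorbed by it.
* `assortativity_strength` plants promiscuity assortment.  Promiscuity
  propensity is individual quality expressed as adult longevity
  (rank-scaled to (-1, 1)); at strength `a` promiscuous females move
  more, seek males whose current partner count matches their own and
  whose quality is similar, and pairs convert encounters in proportion
  to their joint partner counts.  This matched, reinforcing structure
  is necessary: planting via independent activity multipliers provably
  *lowers* edge-level degree correlation (hubs acquire low-degree
  partners), and pure similarity without activity leaves degrees
  unmoved.

The documented magnitudes used by the package's power studies are
`planted_effect_defaults()`: `beta_fight_sperm = 1.5`,
`assortativity_strength = 2`.

### What passing the calibration studies does and does not show

The acceptance suite verifies, under null configurations, that the
MRQAP fighting coefficient, the Mantel test, the signed-rank comparison
and the degree-correlation null all reject at the nominal 5% rate
(within the 99% binomial envelope over 500 replicate seasons), and that
both planted effects are recovered in at least 90% of replicates at the
documented defaults.

These studies run under the `"cohort"` preset — a synchronized cohort
(`emergence_spread = 10`) with homogeneous survival
(`lifespan_dispersion = 20`) — because that is the regime in which the
permutation tests' exchangeability assumption actually holds.  Under
field phenology (long emergence window, geometric lifespans), *any* two
event networks observed over the same season share per-individual
exposure: a long-lived male accumulates more fights *and* more matings,
so the fighting and sperm-competition networks are genuinely dependent
even with no behavioural coupling, in a way the linear space and time
covariates only partly absorb.  In our experiments this inflates the
MRQAP type-I error several-fold.  This is a property of the method on
window-observed data, not of this implementation (the same permutation
machinery is exactly calibrated on matrices with independent exposure
structure), and it is worth bearing in mind when interpreting
field-data results from this family of analyses: part of an observed
fighting–sperm-competition association can reflect shared exposure
rather than behaviour.  The signed-rank calibration compares
per-individual observed days between two independent seasons;
per-node network degrees are not a valid calibration target because
degrees within one network are mutually dependent, which the
signed-rank test's independence assumption does not tolerate.

The simulator deliberately omits: predation and weather, singing-effort
dynamics, mate guarding beyond within-visit monopolization, sperm
precedence and paternity, migration, and nymph behaviour.  Passing
tests on synthetic data shows the estimators and their null
distributions behave as designed under a mechanistic burrow-structured
mating system; it does not validate the behavioural assumptions against
real crickets.

## Numerical and design choices

* Dyad set: unordered pairs for symmetric matrices, all ordered
  off-diagonal cells for directed ones; zero is a value, never
  missingness; matrices are complete.
* Standardization uses the population (divide-by-n) SD over the dyad
  set; symmetric duplicates carry no information and are not counted
  twice.  Constant matrices raise degeneracy errors rather than NaNs.
* Permutation comparisons use a `1e-12` tolerance when counting
  `|stat*| >= |stat_obs|` so floating-point ties count as exceedances
  (the conservative direction).
* All permutation and simulation p-values are bit-reproducible given
  `(seed, n_perm)`; the pipeline derives per-stage seeds from one
  top-level seed by fixed offsets, so each sub-analysis can be
  reproduced in isolation.
* Rank-deficient designs report the most correlated predictor pair by
  name.  Mantel and correlation functions reject constant inputs.
* Problem sizes in the test suite: calibration uses 500 seasons of 40
  males + 40 females (cohort regime, 99 permutations/simulations per
  test); recovery uses 100 seasons at 40+40 for the pair-coupling
  effect and 100 seasons at 119+120 (the high-density population size)
  for the degree-correlation effect, which is a population-level
  statistic and is studied at the population scale the field regimes
  describe.
* Exact permutation enumeration is capped at 8 nodes (8! = 40320
  refits); the exhaustive cross-checks in the test suite use 5 nodes.

## Limitations

* Geometric-mean symmetrization erases one-sided interactions; very
  sparse seasons can yield an all-zero symmetrized fighting network, in
  which case the pipeline aborts with a stage-labelled error instead of
  producing a meaningless fit.
* The spatial-overlap projection (own time at shared burrows, gated by
  the partner's positive use) is one of several defensible readings of
  "males connected through the burrows both used"; alternatives such as
  weighting by the partner's time would change the directed
  intermediate but not the qualitative pipeline.
* Under field phenology the MRQAP calibration caveat above applies to
  any analysis of this design, ours included.
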