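---
title: "From flower traits to multi-species parasitism: the models behind nectarmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From flower traits to multi-species parasitism: the models behind nectarmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nectarmatch` links the functional structure of sown wildflower communities
to the biological control of a multi-species crop-pest community by
hymenopteran parasitoids.  This vignette is the package's own account of the
science: the models, their assumptions, the tunable parameters and the
numerical choices, and what the synthetic-data tests do and do not
demonstrate about real field data.

## 1. The nectar-accessibility model

Adult parasitoids need sugar, and floral nectar is their main source; a
plant only subsidizes a parasitoid if its nectar is *available* (produced
while the adult flies) and *accessible* (reachable by its head and
mouthparts).  `nectar_accessible()` implements a geometric decision tree
over seven measurements, all in millimetres:

* insect: head radius $r$ (half the maximum dorsal head width including the
  eyes), proboscis length $x$, proboscis width $z$ at mid-length;
* flower: opening width $w$, corolla height $h$, nectar depth $p$, nectar
  tube diameter $d$ (absent for open nectaries).

Three constraints are combined:

1. **Penetration** — the head enters the corolla iff $w \ge 2r$.
2. **Reach** — with the head inside, the proboscis must span the nectar
   tube, $x \ge p$; with the head excluded it must span corolla plus tube
   from the opening, $x \ge h + p$.
3. **Tube width** — where a narrow tube holds the nectar, $z \le d$.

Extrafloral nectar, secreted on bracts or stipules outside the perianth,
short-circuits the tree: it is accessible to every visitor.  Species with
no nectar are never accessible.

Two geometric conventions in this tree were genuinely open and are package
design choices.  First, $h$ and $p$ are treated as *disjoint* segments, so
the total depth from the opening is $h + p$ and head entry "spends" the
corolla height.  Second, head entry is all-or-nothing: partial insertion is
not modelled.  Both choices honor the three named constraints while keeping
the tree monotone: lengthening or narrowing the proboscis can never lose
access, and deepening the flower can never grant it.  The test suite pins
the tree to an independently coded nested-conditional oracle over a full
$5^7$ parameter grid, plus these monotonicity properties.

Missing morphology is handled conservatively: the verdict is *inaccessible*
with reason `fail_missing_trait`, and cover aggregation warns rather than
silently counting such species as resources.

**Availability** (`nectar_available()`) has two modes.  In `window` mode the
flowering window (onset, onset + duration, both in days of year) must
overlap the parasitoid's activity window by at least one day; extrafloral
producers are taken to secrete throughout the season.  In `survey` mode a
species counts as flowering when its phenological stage on the 11-point
(0–10) scale lies in a configurable flowering range, 5–8 by default, and
the survey date falls inside the activity window.  The pipeline uses
`window` mode because the synthetic surveys derive their stages from the
same windows; with real survey data the `survey` mode is the faithful
choice.

**The nectar covariate.** `accessible_cover()` sums, per plot, the percent
ground cover of species that pass both filters for a focal parasitoid.
This is a mass-ratio covariate: it weights dominant resource species,
deliberately ignoring how the resource is partitioned.

## 2. Functional diversity

Plant communities are described by a mixed-type trait matrix (floral
dimensions, nectar type and quantity, phenology, colour, height, leaf
distribution).  `gower_dissimilarity()` combines range-scaled quantitative
traits with 0/1-mismatch categorical and binary traits under equal trait
weights, deleting missing values pairwise and renormalizing; a species pair
sharing no observed trait is an error naming the pair.  Equal weights are
used because no weighting scheme is implied by the study design; the
observed range of the supplied matrix defines the scaling.

`fdis()` is functional dispersion: species are embedded by principal
-coordinates analysis of the Gower matrix and FDis is the abundance-weighted
mean Euclidean distance to the abundance-weighted centroid.  Gower matrices
are generally non-Euclidean, so when negative eigenvalues exceed $10^{-8}$
of the leading eigenvalue the Cailliez correction is applied (via
`ape::pcoa`); this correction is one of the two standard options and the
choice is immaterial at the precision the analyses use.  A single-species
community has FDis 0, not an error.  `rao_q()` is Rao quadratic entropy
$Q = \sum_{ij} w_i w_j d_{ij}$, computed on $d$ (not $d^2$).  Both metrics
are reported — they are typically strongly correlated, and the pipeline's
regressions use FDis with Rao alongside as a consistency check.

## 3. Mixed models, multimodel inference, and the neutral check

Parasitism of each herbivore is a binomial outcome (hosts parasitized of
hosts examined) per plot and distance.  `fit_glmm()` fits binomial-logit
and Poisson-log mixed models with a single random intercept by maximum
likelihood (adaptive Gauss–Hermite quadrature, 15 nodes by default; 1 node
is the Laplace approximation, which the simulation-heavy pipeline stages
use).  The AIC always counts $k = (\text{fixed effects}) + 1$ parameters so
candidate models remain comparable, including the degenerate single-group
case where the model collapses to a GLM with $\sigma_u = 0$.  The random
grouping (plot, strip or block) is chosen once per analysis by AIC
(`select_random_effect()`).  Per-term type II Wald chi-square tests come
from `car::Anova`; variance explained is the variance-partition pseudo-R²
with distribution-specific variance $\pi^2/3$ (binomial-logit) or
$\log(1 + 1/e^{\beta_0})$ (Poisson-log).

`build_term_sets()` enumerates all additive combinations of the nine
community predictors — nectar cover, species richness and FDis, each with a
quadratic term, plus pairwise linear interactions — under marginality
(quadratics require their linear term, interactions both parents).
Marginality is enforced by default because averaged coefficients of
non-hierarchical models are uninterpretable; a switch disables it.
Candidates are ranked by AIC; Akaike weights are
$w_m \propto e^{-\Delta_m/2}$; the confidence set is strictly
$\Delta < 2$.  `conditional_average()` averages each term over the selected
models containing it with renormalized weights, reports the revised
unconditional-variance standard error
$\widehat{se} = \sum_m w_m \sqrt{se_m^2 + (b_m - \bar b)^2}$, and defines a
term's importance as the summed renormalized weight of the selected models
containing it (terms present in every selected model therefore have
importance 1).

**Neutral model.** The mechanistic covariate is validated by randomization:
`neutral_aic_comparison()` redraws the set of "interacting" plant species
uniformly — from the species in flower during the parasitoid's activity
(randomizing the morphological match only) or from all species present
(randomizing the temporal and morphological match) — keeping the number of
interactions fixed at the trait-matched count, rebuilds the per-plot cover
covariate, re-standardizes, refits the reference model and records its
AIC.  The reference formula is the top-ranked trait-matching model; the
full selection procedure is *not* re-run per iteration, a tractability
choice that tests the covariate rather than the selection path.  Draws are
made at the species level, once per iteration, then summed per plot —
interaction is a species property, not a plot property.  Seeding is
hierarchical (mode offset + iteration), so reports are bit-identical under
one master seed.  The standalone default is 1000 iterations; the pipeline's
routine default is 200, which already pins the mean neutral AIC to well
within one AIC unit.

## 4. Multi-threshold multi-species parasitism

Parasitism rates of different herbivores are not substitutable, so
averaging them hides trade-offs.  Instead, for each herbivore a reference
maximum is the mean of its three highest plot-level rates (a guard against
a single outlying plot), per distance.  For thresholds
$\tau = 0.1, \dots, 0.9$ the multi-species parasitism of a plot is the
number of herbivores whose local rate *strictly exceeds* $\tau$ times their
reference maximum — "exceeds" is read strictly, and ties would be logged.
Plots missing any herbivore's rate are dropped by default (a complete-case
count of five is not comparable to a count over three), configurable to
counting over the available herbivores.  The resulting plot × threshold
table (27 complete plots × 9 thresholds = 243 rows per distance) is
modelled as a Poisson mixed model with the strip random intercept, the
standardized threshold as a continuous fixed effect, and candidates built
from the community predictors (linear + quadratic), the threshold, and
threshold-by-predictor interactions, capped at five fixed-effect variables
per model.  Within that cap the threshold interactions, which carry the
multifunctionality hypothesis, take the place of the pairwise community
interactions used in the per-herbivore analyses.  Counts within a plot are
not independent across thresholds — the model is descriptive of the sweep,
which is why inference centres on model-averaged effects rather than
single p-values.

## 5. The synthetic-data generator

`simulate_dataset()` emulates the field design so every stage is testable
offline: 8 sown assemblages — four categories crossing low/high functional
diversity with sown richness 14 (LFMS), 9 (HFLS), 14 (HFMS) and 29 (HFHS),
each in two species-identity variants — plus an unsown control, replicated
on 3 strips in 3 blocks (27 plots), with 5 herbivores at 5 and 20 m and 7
parasitoid taxa (the fifth herbivore hosts three morphospecies whose nectar
covers are averaged).

* **Flora**: a pool of 85 species; log-normal floral dimensions (medians
  ~3 mm opening, ~2 mm corolla, ~1.2 mm nectar depth; 60% with a nectar
  tube ~0.6 mm), nectar types 65% floral / 8% extrafloral / 4% both / 23%
  none, flowering onset uniform over days 75–170 with durations 25–70
  days.  These magnitudes put accessibility near its decision boundaries
  for parasitoid-sized insects, so the matching step is informative rather
  than saturated.
* **Assembly**: low-FD assemblages are a species and its nearest
  neighbours in Gower trait space; high-FD assemblages are greedy maximin
  selections.  This realizes the designed FD contrast without forcing the
  analysis outcome.
* **Surveys**: sown species establish with probability 0.85, 4–10
  spontaneous species invade at low cover (emulating a realized flora that
  only partly reflects the sown mixtures), gamma-Dirichlet covers are
  rescaled to a 60–95% total, and phenological stages are consistent with
  each species' window at the survey date (day 135).
* **Parasitoids**: 7 taxa, log-normal head widths (~0.55 mm) and proboscis
  dimensions, activity windows staggered ~12 days apart, 30–50 days long.
* **Parasitism**: the generative model mirrors the fitted one —
  $\mathrm{logit}(\pi) = \beta_0^{(h)} + m_d(\beta_{nec} Z_{nec} +
  \beta_{rich} Z_{rich} + \beta_{FD} Z_{FD} + \beta_{FD^2} Z_{FD}^2) +
  u_{strip}$, with binomial draws over 20–200 hosts examined.  Defaults:
  per-herbivore intercepts spanning baseline rates ~0.11–0.43,
  $\beta_{nec} = 0.5$, $\beta_{FD^2} = -0.3$ (the hump, injected on the
  per-herbivore latent scale so the multi-species hump *emerges* through
  the counting statistic), $\sigma_{strip} = 0.3$ (a moderate strip effect;
  no empirical value exists, so it is exposed in the config), and
  attenuation $m_{20} = 0.4$ at the far distance.

Seed substreams are independent: flora, parasitoids and parasitism each
re-seed from fixed offsets of the master seed, so changing one stream
leaves the others untouched.

**What passing tests show — and don't.**  The generator reproduces the
*statistical structure* the analyses assume: design geometry, mixed-type
traits, cover composition, binomial/Poisson noise, a strip-level random
effect, and effects injected on the model's own scale.  It does not emulate
spatial autocorrelation, between-year phenological turnover (one survey
season is generated, so covariates "averaged over years" reduce to the
single-survey values), observer error in cover estimation, or
herbivore-host population dynamics.  Green tests therefore certify the
correctness and calibration of the machinery, not the field conclusions.

## 6. Numerical choices and problem sizes

* Optimization: `lme4` with the optimizer's return code as the convergence
  criterion and a fixed two-step restart ladder (bobyqa, then Nelder–Mead);
  non-converged candidates are dropped from model sets with a warning
  count, and more than 10% failed neutral iterations is an error.
* Quadrature: 15 adaptive Gauss–Hermite nodes by default (`lme4` caps the
  order at 25; refinement from 15 to 25 moves the log-likelihood by less
  than $10^{-6}$ on the designs used here); Laplace (`nAGQ = 1`) in
  simulation loops.
* Ties: AIC ties in random-effect selection keep the first candidate and
  log the tie; the $\Delta < 2$ rule is strict at the boundary.
* Degenerate inputs: single-species communities give FDis/Rao 0; constant
  covariates standardize to 0 rather than NaN; empty confidence sets and
  empty multi-threshold datasets are errors.
* Simulation sizes in the test suite are chosen to hold Monte-Carlo error
  comfortably below the margins being asserted: 200 replicates for
  estimator bias/coverage, 100 for selection and hump-recovery rates, 50
  datasets × 200 iterations for the neutral power check, 20 for its null
  calibration.

## 7. Known limitations

* The accessibility tree is a reconstruction from the three named
  geometric constraints; a supplementary source with the exact branch
  order could replace it behind the same interface (the oracle tests
  would then be re-derived).
* Nectar *quantity*, concentration, and flower attractiveness are outside
  the accessibility model; cover is the only weighting.
* One random intercept only; crossed or nested random effects are out of
  scope, as are overdispersion terms.
* The multi-threshold Poisson model treats threshold rows as observations;
  its standard errors are conditional on the sweep construction.
* The neutral model refits only the best trait-matching formula, not the
  whole selection path.
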