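---
title: "Community fruit-body traits across forest microclimates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community fruit-body traits across forest microclimates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycotraits)
```

## The scientific question

Open forest canopies expose dead wood to heat, radiation and drought —
a "harsh" microclimate compared with the buffered conditions under closed
canopies. If fruit-body morphology helps macrofungi endure such
conditions, the composition of fruiting communities should shift with
canopy openness in trait space: for example, tough-fleshed fruit bodies
(dense, di-/trimitic hyphal systems; perithecial ascomycetes) lose water
more slowly than soft agaricoid or apothecial ones, so harsher
microclimates should carry a higher proportion of tough-fleshed species.

`mycotraits` implements the full analysis chain for testing such
hypotheses on presence/absence fruiting inventories from a blocked
dead-wood exposure experiment: trait assembly, per-log community trait
means, a fixed-marginal null model, and mixed-model / GLM inference.

## Species traits

Three species-level traits are used:

* **Fruit-body size** (mm): the arithmetic mean of the literature minimum
  and maximum cap diameter (pileate-stipitate, apothecia) or body width
  (pileate-sessile, perithecia), `mean_fruit_body_size()`.
* **Colour lightness** (%): the L coordinate of the HSL colour model,
  `L = (max(R,G,B) + min(R,G,B)) / 2 / 255 * 100`, sampled at nine pixels
  of a fruit-body photograph and averaged per species
  (`rgb_to_lightness()`, `species_lightness()`,
  `extract_species_lightness()`). The bi-hexcone formula is the standard
  HSL definition; pixels are averaged on the L scale. Pixel coordinates
  are supplied in a sample file so extractions are reproducible; no
  automatic fruit-body segmentation is attempted. PNG images are
  supported.
* **Toughness** (binary): Basidiomycota are coded from the taxonomic
  order — Polyporales, Gloeophyllales and Hymenochaetales tough,
  Agaricales soft; Ascomycota from the fruit-body type — perithecia
  tough, apothecia soft (`code_toughness()`). Orders outside the rule are
  left missing with a warning rather than guessed; they must be resolved
  through an explicit per-species override table passed to
  `build_trait_table()`, because no published rule exists for them.

Missing trait values propagate as `NA`: a species missing one trait is
excluded from that trait's community mean only, never from the community
matrix.

## Community traits

Survey records (year × log × species) are collapsed to a binary matrix
with `aggregate_years()` — presence in any retained year counts, and the
first survey year is excluded by default because early records are too
sparse for meaningful community means. Only logs with at least three
species are analysed (`filter_min_richness()`, threshold configurable;
one species is the sensitivity setting).

Three per-log responses (`community_trait_means()`):

* mean of `log10(size)` over the species present,
* mean of `log10(lightness)` over the species present,
* proportion of tough-fleshed species, arcsine-square-root transformed
  for modelling.

"Arcsine transform" is implemented as `asin(sqrt(p))`, the standard
variance-stabilising transform for proportions; plain `asin(p)` is
available behind a switch since the wording of the original protocol is
ambiguous. Sizes or lightness values of zero make `log10` undefined and
raise an error naming the species. Dead-wood amount per plot is
summarised as lateral truncated-cone surface area
(`frustum_surface()`; end caps excluded by default since fungi colonise
the lateral bark surface, toggleable).

## The independent-swap null model

Species richness differs between logs and covaries with any community
mean, and shifts in the underlying mycelial community could move trait
means without any fruit-body-level selection. Both concerns are addressed
by standardising each observed community trait against a null model that
**fixes both marginal sums** of the binary matrix: per-log richness and
per-species occupancy. The null hypothesis is a uniform distribution on
the *fill class* — all binary matrices sharing those margins.

`independent_swap()` samples from this distribution with a
checkerboard-swap Markov chain: repeatedly flip 2×2 submatrices equal to
`[[1,0],[0,1]]` or `[[0,1],[1,0]]`. Two implementation details matter and
were chosen deliberately:

* **Proposals draw two occupied cells** uniformly (flipping when they sit
  in distinct rows and columns with empty opposite corners), rather than
  two random rows and columns. On sparse community matrices (fill density
  ~0.07 here) random row/column quads are accepted in well under 1% of
  attempts, so any affordable attempt budget leaves the chain correlated
  with its starting matrix; occupied-cell proposals accept most attempts
  and mix two orders of magnitude faster. Because the number of occupied
  cells is invariant, this proposal is symmetric between any two matrices
  one swap apart.
* **Attempts are counted, not accepted flips.** With a symmetric proposal
  and "stay put" on rejection the chain is doubly stochastic and its
  stationary law is exactly uniform on the fill class. Counting only
  accepted flips would weight states by their number of available swaps,
  which is demonstrably non-uniform on small fill classes.

Uniformity is *tested, not assumed*: on an enumerable 3×3 fill class the
visit frequencies of 10^5 randomizations are compared against a
brute-force enumeration oracle with a chi-square test, and null means are
cross-checked against an independent implementation (picante) in the test
suite. The default budget of `10 * sum(m)` attempts (ten proposals per
occupied cell) reproduces the fully-mixed null mean on matrices of the
experiment's size; under-mixing is detectable as a systematic offset of
neutral SES away from zero, which the calibration tests would catch.

For each of `n_rand` (default 100) randomizations — each restarted from
the observed matrix — the community trait is recomputed, and

\[ \mathrm{SES} = \frac{\mathrm{observed} - \mathrm{mean}_{\mathrm{null}}}{\mathrm{SD}_{\mathrm{null}}} \]

per log (`ses_community_traits()`). SES is computed per log (the
modelling unit), on the same transformed scale as the observed response
(arcsine-square-root for toughness). A zero null SD flags the SES as
missing rather than zero. Because margins are fixed, per-log richness is
identical across all null matrices, so SES patterns cannot be pure
richness artifacts.

## Inference

All models treat the log as the observation and account for the layout
(5 blocks × 24 plots × 2 sampled logs) with nested random intercepts
"plot in block".

* **Overall canopy model** (`fit_trait_lme()`): each community trait
  (observed, and separately its SES — both through the identical code
  path) against canopy openness with tree species and the other two
  community trait means as fixed covariates. Retaining the other means as
  covariates, rather than running many independent tests, is the
  multiple-testing mitigation strategy; an optional Holm adjustment is
  not applied by default. Inference is Wald: `z = estimate / SE` against
  the standard normal (mixed models are reported as z, not t). The
  coefficient of determination is the marginal R² in the
  variance-partition sense: `var(Xb) / (var(Xb) + sum(random variances) +
  residual variance)`.
* **Lineage models**: `lineage_difference_test()` fits trait ~ lineage
  (plus covariates) on the stacked lineage-specific tables;
  `lineage_contrasts()` fits the full factorial lineage × tree × canopy
  model and reports least-squares-means-style canopy contrasts
  (open − closed) within each lineage (tree levels averaged with equal
  weight) and within each lineage × tree cell, using contrast vectors on
  the fixed-effect covariance matrix. Contrasts touching an empty design
  cell are flagged `NA`. The contrast machinery is cross-checked against
  emmeans to 1e-6 in the tests.
* **Single-model comparison** (`fit_canopy_glm()`): a binomial GLM with
  canopy openness (open = 1) as the response and all three community
  means as predictors, so the traits' Wald z values are comparable within
  one fit. Complete separation is detected and flagged.
* **Collinearity screen** (`collinearity_check()`): all pairwise Pearson
  correlations among the trait means (plus optional covariates), flagged
  at the conventional `|r| >= 0.7`.
* **Surface covariates**: the per-log sampled surface and the whole-plot
  dead-wood surface can be added to any LME (`surface =` argument); the
  default omits them, mirroring the final-model choice of dropping
  covariates that are significant in no model.

Factor coding is treatment contrasts with alphabetical reference levels
(Ascomycota, beech, closed), so reported signs are defined against those
references.

### Degenerate inputs

Constant responses yield zero slopes with undefined z (warning, not
error); constant covariates are dropped with a warning; singular
random-effect fits are kept with a note (variance at the boundary);
matrices without any checkerboard return unchanged with a warning and
SES flagged missing.

## The synthetic experiment

`generator_config()` / `simulate_experiment()` emulate the study design:
5 blocks × 24 plots (half open/closed canopy, half low/high local dead
wood; each block-canopy-amount cell holds 2 beech, 2 fir and 2 mixed
plots), two sampled logs per plot (240 sampled logs), logs around
33 cm × 5 m, and a 107-species pool with a 60/107 Basidiomycota share.

Traits are lineage-structured: log-normal sizes
(`log10` mean 1.6 vs 0.4, i.e. ~40 mm vs ~2.5 mm — Basidiomycota markedly
larger), truncated-normal lightness (means 62% vs 45% — Ascomycota
darker), and per-lineage toughness probabilities (0.6 vs 0.4). These
defaults echo the qualitative lineage differences reported for such
communities; the exact per-lineage frequencies of any real species pool
should be supplied via a real trait table when available. One species
lacks size and two lack lightness by default, emulating typical
literature-trait coverage (106/105/107 of 107).

Occurrence of species *j* on log *i* is a single Bernoulli draw with

```
logit(p_ij) = b0 + u_species(j) + u_plot(i)
            + open_i * (beta_tough_open * tough_j
                        + beta_size_open  * z(log10 size_j)
                        + beta_light_open * z(log10 lightness_j))
            + beta_tree * [tree_i == preferred_tree_j]
```

with `u_species ~ N(0, 1)` and `u_plot ~ N(0, 0.4)` creating the
occupancy and richness heterogeneity that the fixed-marginal null model
conditions on. Realized occurrences are then scattered over the survey
years for record realism (every present pair is recorded in at least one
retained year). The baseline `b0 = -3.2` gives a median per-log richness
of about 7–10 with ~95% of logs passing the three-species filter —
comfortably inside the intended 5–10 median.

Two structural properties were deliberate:

* **Neutral setting = exact null.** With the selection coefficients at
  zero the linear predictor is additive in a log effect and a species
  effect, so conditionally on the matrix margins the generated community
  is a *uniform* draw from its fill class (the Rasch sufficiency
  argument; verified against a full fill-class enumeration in
  development). The neutral generator therefore probes the null model's
  calibration exactly: mean per-log SES should be zero and the canopy
  LME should reject at its nominal rate. An earlier design that drew
  occurrences per survey year and aggregated violated this additivity
  and produced a detectable SES offset — the single-draw model is the
  correct neutral benchmark.
* **Tree preference is trait-blind.** `beta_tree` induces co-occurrence
  structure beyond the margins, but since preferences are independent of
  traits it shifts no trait expectation; it makes the neutral setting a
  slightly stricter test.

What the generator does *not* emulate: temporal turnover and succession,
abundance, spatial autocorrelation beyond the plot effect, phylogenetic
trait signal beyond the lineage split, and intraspecific trait
variability. Passing calibration and recovery tests on synthetic data
therefore shows the machinery is correct and well-calibrated under the
stated model, not that any particular field dataset satisfies that model.

## Numerical choices

* Swap chain: attempts counted (uniform stationary law); default
  `10 * sum(m)` attempts per randomization; each randomization restarts
  from the observed matrix; seeded runs are bit-reproducible (the kernel
  uses R's RNG).
* SES with zero null SD → `NA`, never 0.
* GLM convergence tolerance 1e-10 (tight enough that a single-binary-
  predictor fit reproduces the closed-form 2×2 log odds ratio to well
  below 1e-6).
* Master seeds are fanned out to independent sub-seeds per stage (pool,
  metadata, occurrences, each SES scope), so stages are individually
  reproducible.
* Problem sizes in the shipped tests: calibration uses 200 neutral
  assemblies (SES) and 500 neutral replicates (type-I error), recovery
  uses 200 selection runs, all at the full design size; structural tests
  use a reduced 2-block × 8-plot × 30-species design.

## Known limitations

* Presence/absence only; abundance-weighted community means are out of
  scope.
* The lightness operator consumes a pixel-sample file; it does not locate
  fruit bodies in photographs.
* Only the independent-swap null model is provided (no frequency,
  richness or curveball variants).
* Wald z inference on mixed models is asymptotic; with far fewer plots
  than this design the normal reference would be optimistic.
* Real-data sign conventions depend on the original factor coding; the
  package documents its own (alphabetical references) rather than
  guessing another analysis's.
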