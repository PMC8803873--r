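# mycotraits

Trait-based analysis of macrofungal fruiting communities across forest
microclimates.

## The problem

Open forest canopies create a harsh microclimate on dead wood — more
radiation, heat and drought than under a closed canopy. If fruit-body
morphology helps a fungus endure those conditions, fruiting communities
should shift in trait space with canopy openness: in particular,
tough-fleshed fruit bodies (polypores, perithecial ascomycetes) resist
desiccation better than soft agaricoid or apothecial ones, so open-canopy
logs should carry a higher *proportion of tough-fleshed species*.

`mycotraits` is for community ecologists analysing presence/absence
fruit-body inventories from blocked dead-wood experiments. It covers the
whole chain:

1. **Species traits** — mean fruit-body size from literature min/max,
   HSL colour lightness from photograph pixel samples
   (`L = (max(R,G,B) + min(R,G,B))/2/255 × 100`), and binary flesh
   toughness coded from taxonomy (Polyporales, Gloeophyllales,
   Hymenochaetales and perithecia tough; Agaricales and apothecia soft).
2. **Community traits** — per-log means of `log10(size)` and
   `log10(lightness)` over the species present, and the proportion of
   tough-fleshed species, `asin(sqrt(p))`-transformed; only logs with ≥ 3
   species are used.
3. **Null model** — the independent swap: checkerboard-swap randomization
   of the binary matrix that fixes *both* marginal sums (per-log richness
   and per-species occupancy), giving a standardized effect size per log,

   `SES = (observed − null mean) / null SD`

   over 100 randomizations, so trait–canopy patterns cannot be richness
   or occupancy artifacts.
4. **Inference** — linear mixed models of each community trait (observed
   and SES) on canopy openness with tree species and the other two trait
   means as covariates and nested `plot in block` random intercepts
   (Wald `z = estimate/SE`, marginal R²); least-squares-means canopy
   contrasts within lineages (Basidio- vs Ascomycota) and lineage × tree
   cells; a binomial GLM of canopy on all three trait means at once for
   within-model effect comparison; and a `|r| < 0.7` collinearity screen.
5. **Synthetic experiment** — a generator emulating the design (5 blocks
   × 24 plots, half open/half closed canopy, 2 sampled logs per plot,
   107 species in two lineages) with a logistic occupancy model and a
   tunable trait × canopy selection effect, so every stage is testable
   offline and the null model's calibration is verifiable.

## Worked example

Simulate the experiment with a strong toughness-by-canopy selection
(`beta_tough_open = 2` on the log-odds scale) and run the full analysis:

```r
library(mycotraits)
res <- run_full_analysis(
  synth_cfg = generator_config(beta_tough_open = 2),
  seed = 11, n_rand = 100)
print(res)
```

```
Community fruit-body trait analysis
  240 logs (237 passing the 3-species filter), 106 species
  null model: independent swap, 100 randomizations

Wald z by term (columns: trait_response):
                                  term size_obs_z size_ses_z ... toughness_obs_z toughness_ses_z
                             Intercept      -7.23      -0.42            3.39          -12.65
                Canopy openness - open       0.43       0.40           14.81           17.18
                          Tree species       0.04      -0.06            1.63            2.49
                                  ...
         Basidiomycota - Canopy - Open      -1.68      -0.02           10.52           13.26
            Ascomycota - Canopy - Open       0.18       0.59           13.77           13.43
                                  ...
                           Marginal R2       0.42       0.47            0.58            0.68
```

The injected selection is recovered exactly where it should appear: the
canopy term for **toughness** is large and positive for both the observed
proportion (z = 14.8) and its SES (z = 17.2), consistently within both
lineages, while size and lightness show no canopy signal (|z| ≤ 1.7).
Because the SES is computed against a null that fixes richness and
occupancy, the agreement of the OBS and SES columns says the pattern is a
genuine trait–microclimate association, not a richness artifact.

The single-model comparison tells the same story — toughness carries the
largest effect among the three traits:

```r
print(res$glm$obs)
#> GLM_BINOMIAL fit of canopy ~ traits (OBS)
#>                  term estimate     se     z        p
#>           (Intercept) -33.7400 11.460 -2.94 3.24e-03
#>       mean_log10_size   0.4888  1.482  0.33 7.41e-01
#>  mean_log10_lightness   9.7920  6.644  1.47 1.41e-01
#>       prop_tough_asin  18.5600  2.660  6.98 2.99e-12
```

`summary(res)` prints every model; `plot(res)` draws the trait-by-canopy
boxplots; `write_analysis(res, "out/")` writes all tables as CSV plus a
JSON run manifest. With real data, pass `records`, `meta` and `traits`
(see `?aggregate_years`, `?build_trait_table`) instead of a generator
config.

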