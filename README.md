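# cropdiv

Spatio-temporal analysis of crop species diversity from district-level
agricultural panels.

Long-run agricultural censuses record, for every district and year, the
area and production of each crop. `cropdiv` turns such panels into a
complete diversity analysis in the tradition of studies of the Green
Revolution in India: how did the effective number of crop species change
over five decades, at district, state and country level, and how is that
change related to agricultural intensification?

The package is aimed at quantitative agro-ecologists and agricultural
economists working with harmonized district × year × crop area/production
panels (or wanting to prototype such an analysis on simulated data before
the real compilation exists).

## What it computes

**Diversity.** Crop species diversity is the effective number of species

&nbsp;&nbsp;&nbsp;&nbsp;*D* = e^*H*,&nbsp;&nbsp; *H* = −Σᵢ *p*ᵢ ln *p*ᵢ,

where *p*ᵢ is the proportion of crop area under crop *i*: the number of
equally abundant crops with the same Shannon entropy as the observed mix.
Because datasets report different numbers of crops, sub-national values
can be adjusted to a common crop count by fitting the saturating
exponential *D* = *a* + *b*·e^(−*c·x*) to the diversity-versus-crop-count
curve and evaluating it at a common *x* (default 83 crops). Spatial
dissimilarity is the multiplicative partition *β* = *γ*/*α*: pooled
(country) diversity over the unweighted mean district diversity.

**Turnover.** Between an initial and a final 5-year period mean, a
crop × crop transition matrix allocates each district's area flows under
the conservative assumption that area a crop retained did not move
(diagonal = min(initial, final); losses are spread over gaining crops in
proportion to their gains; net expansion/contraction enters through
`__new__`/`__exit__` margins so area is conserved exactly).

**Intensification.** The relative intensity of a district is its
area-weighted cereal yield divided by the maximum such yield across all
districts and periods (*RI* ∈ (0, 1]). Change in diversity Δ*D* is
regressed on Δ*RI*, the initial cereal area share, and their interaction,
with the final model selected by AIC; a single-predictor baseline relates
Δ*D* to the initial sorghum/millet share in districts the cereal models do
not describe.

**Panel plumbing.** CSV ingest with validation, averaging of overlapping
sources, merging of split districts back to base-year boundaries, linear
gap imputation for series with at least 10 observations, state/country
aggregation, and aggregate-then-divide yields.

**Synthetic panels.** A seeded generator emulates the two dynamics such
analyses revolve around — districts that intensify and specialize in
high-yielding cereals, and districts that shift from declining cereals
into many small oilseed and horticultural crops — with injected missing
values and district-split events, so the whole pipeline is testable
without external data.

## Worked example

```r
library(cropdiv)

cfg <- run_config(
  scenario = scenario_config(n_districts = 30, n_states = 5, seed = 1),
  seed = 1
)
rep <- run_pipeline(cfg)
rep
#> <run_report> 30 base districts, 38160 records (738 imputed)
#> selected models:
#>   wheat: delta_D ~ delta_RI + area_share_t0 + delta_RI:area_share_t0
#>   cereals: delta_D ~ delta_RI

rep$ladders$cereals$best$coefficients
#> # A tibble: 2 × 4
#>   term        estimate std_error   p_value
#>   <chr>          <dbl>     <dbl>     <dbl>
#> 1 (Intercept)     3.78     0.709 0.0000111
#> 2 delta_RI      -10.2      1.97  0.0000160

rep$baseline$coefficients
#> # A tibble: 2 × 4
#>   term          estimate std_error     p_value
#>   <chr>            <dbl>     <dbl>       <dbl>
#> 1 (Intercept)      -2.43     0.619 0.000506
#> 2 area_share_t0    10.5      1.51  0.000000133
```

The selected cereal model says districts that intensified most (largest
rise in relative cereal yield) lost about 10 effective crop species per
unit of ΔRI — the Green-Revolution specialization signature — while the
baseline model's positive slope says districts that started with a large
sorghum/millet share subsequently diversified. On the same run the yearly
β series rises from 1.94 to 2.06 and pooled country diversity from 10.6
to 13.5 effective species while the district mean stays near 6: districts
grow more dissimilar even where their own diversity changes little.

All stage outputs (diversity series and summaries, β series, trends,
transition matrices, delta tables, model comparisons, run report) are
written as CSV when `run_config(out_dir = ...)` is set.

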