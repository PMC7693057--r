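# msar

Mean species abundance relationships (MSARs) for chemical stressors,
derived from ordinary chronic toxicity tests.

Species sensitivity distributions (SSDs) — the workhorse of aquatic risk
assessment — reduce each species to a single point statistic (EC10, EC50,
NOEC) and say nothing about how species *abundances* decline along an
exposure gradient. This package converts whole exposure–response curves
into a community-level exposure–abundance relationship, the metric used for
stressors such as land use and climate change, making chemical pressure
comparable with them and yielding abundance-based protective
concentrations.

The chain, per chemical:

1. **Fit** a two-parameter log-logistic curve
   `Ŷ(c) = 1 − 1/(1 + (c/C50)^β)` to each species × endpoint (survival,
   reproduction) test; algal abundance/growth tests are fitted directly on
   the abundance scale.
2. **Convert** to species exposure–abundance curves via population-growth
   theory: with lifetime fecundity `R0` and `r = ln(R0)/Tg`,

   ```
   K(c)/K(0) = [ −ln(1+(c/EC50)^βrep) − ln(1+(c/LC50)^βsurv) ] / ln(R0) + 1
   ```

   (clamped to [0, 1]; a missing endpoint drops its term).
3. **Aggregate**: `MSA(c) = (1/n) Σᵢ K(c)ᵢ/K(0)ᵢ`, refit with
   `MSA(c) = 1/(1+(c/a)^β)`, and read off the hazardous concentration
   `HC5 = a·(1/19)^(1/β)` (5% community abundance loss).
4. **Compare** with a companion log-logistic SSD fitted on EC10s from the
   same data (`HC5–EC10 = scale·(1/19)^(1/shape)`), and propagate fit
   uncertainty into Monte-Carlo confidence bands.

A synthetic-panel generator with known ground truth
(`generate_panel()`) makes every stage testable end to end.

## Worked example

```r
library(msar)

panel  <- generate_panel(panel_spec(n_species = 15), seed = 1)
fits   <- fit_panel(abbott_correct(panel$tox), panel$traits)
curves <- build_abundance_curves(fits, panel$traits)
msar   <- aggregate_msar(curves, default_conc_grid(fits$C50), "synthetic")
fit    <- fit_msar_loglogistic(msar)
glance(fit)
#> # A tibble: 1 × 7
#>   chemical  variant     a  beta    sse     n   hc5
#>   <chr>     <chr>   <dbl> <dbl>  <dbl> <int> <dbl>
#> 1 synthetic default  14.5  1.18 0.0916   201  1.20

ssd <- fit_ssd(species_ec10(fits), "synthetic")
env <- msar_envelope(fits, panel$traits, n_iter = 500, seed = 1,
                     grid = msar$grid)
report_comparison(env, ssd)
#> # A tibble: 1 × 11
#>   chemical  msar_hc5 msar_hc5_lower msar_hc5_upper ssd_hc5_ec10 ...
#> 1 synthetic     1.20          0.773           1.86        0.649 ...
```

Reading: the community half-maximal concentration is `a ≈ 14.5` µg/L with
community slope `β ≈ 1.2`; 5% of mean species abundance is lost at
`HC5 ≈ 1.20` µg/L (95% CI 0.77–1.86 from 500 Monte-Carlo iterations),
roughly 1.8× above the SSD's HC5–EC10 of 0.65 µg/L — using whole
exposure–response curves is less conservative than the EC10-based SSD on
the same data. `autoplot(env)`, `autoplot(ssd)` and
`plot_abundance_curves(curves)` draw the corresponding figures;
`variant_msar()` builds the reproduction-only and no-intraspecies-variation
community curves.

`run_pipeline(msar_config(...))` runs the whole chain (fits → curves →
MSAR → variants → SSD → envelope → comparison report) and serializes every
stage to JSON/CSV; a thin command-line wrapper with subcommands
(`simulate`, `fit`, `build`, `ssd`, `envelope`, `hc5`, `run`) is installed
at `inst/cli/msar`.

See the vignette (`vignettes/msar-methods.Rmd`) for the model, its
assumptions, numerical choices, and what the synthetic panels do and do
not emulate.

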