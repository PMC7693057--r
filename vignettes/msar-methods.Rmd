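---
title: "From chronic toxicity tests to mean species abundance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chronic toxicity tests to mean species abundance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(msar)
library(dplyr)
```

## The problem

Species sensitivity distributions (SSDs) summarize interspecies differences
in chemical sensitivity, but each species enters as a single point statistic
(an EC10, EC50 or NOEC), so an SSD says nothing about how far *abundances*
decline along an exposure gradient. Mean species abundance (MSA) — the mean,
over species, of abundance under disturbance relative to undisturbed
abundance — is the community metric used for stressors like land use and
climate change. This package derives exposure–MSA relationships (MSARs) for
chemicals from ordinary chronic toxicity tests, which makes chemical
pressure comparable to those other stressors and yields an abundance-based
hazardous concentration.

## The model

**Species responses.** Each species × endpoint (survival or reproduction)
test is summarized by a two-parameter log-logistic curve

$$\hat Y(c) \;=\; 1 - \frac{1}{1 + (c/C_{50})^{\beta}},$$

with half-maximal concentration $C_{50}$ (an LC50 or EC50, µg/L) and Hill
slope $\beta$. Both asymptotes are fixed (0 at the control, complete effect
at high exposure); no hormesis or partial-effect plateaus are modelled.

**From endpoints to abundance.** Exposure lowers survival and reproduction
jointly; the lifetime fecundity ratio is the product of the two unaffected
fractions,

$$\frac{R_0(c)}{R_0(0)} = \frac{1}{1+(c/EC_{50})^{\beta_{rep}}}\cdot
\frac{1}{1+(c/LC_{50})^{\beta_{surv}}}.$$

Under logistic growth the intrinsic rate of increase is
$r = \ln(R_0)/T_g$; assuming the generation time $T_g$ is unaffected by the
chemical and that relative changes in $r$ translate proportionally into
relative changes in carrying capacity $K$ (and hence abundance), the
species-level exposure–abundance curve is

$$\frac{K(c)}{K(0)} \;=\; \frac{-\ln\!\big(1+(c/EC_{50})^{\beta_{rep}}\big)
-\ln\!\big(1+(c/LC_{50})^{\beta_{surv}}\big)}{\ln R_0(0)} + 1 ,$$

with a missing endpoint simply dropping its log term. For algae and other
taxa whose tests measure abundance or growth directly, the analogous
one-term curve is fitted in a single step (`fit_abundance_direct()`), with
$R_0 = 2$ for clonal organisms.

Negative values of the abundance ratio mean the population cannot persist;
they are clamped to 0. MSA is defined on $[0,1]$, so some floor is forced;
clamping at the species level (rather than averaging raw negative values)
is the choice here — unclamped averaging would drag the community mean
further down at high concentrations where some populations are already
extinct, effectively double-counting their loss.

**Aggregation.** The community curve is the unweighted mean
$\mathrm{MSA}(c) = \tfrac1n \sum_i K(c)_i/K(0)_i$ over species, evaluated on
a log-spaced grid (200 points spanning two decades beyond the data on each
side, plus an exact control point). A decreasing log-logistic
$\mathrm{MSA}(c) = 1/(1+(c/a)^\beta)$ is then refitted through the grid —
the form is forced by $\mathrm{MSA}(0)=1$ — and the hazardous concentration
HC5 is read off this refit as $a\,(1/19)^{1/\beta}$ (5% community abundance
loss). Reading HC5 off the raw piecewise curve instead is available via
`hc5_from_msar(..., on = "raw")`.

**Companion SSD.** For comparison, a log-logistic SSD is fitted by maximum
likelihood to per-species EC10s extracted from the *same* fits (logistic
MLE on log concentration); its 5th percentile is the HC5–EC10. Per species
the most sensitive endpoint's EC10 is used — the usual regulatory
convention; a reproduction-preferred rule is available
(`species_ec10(rule = "reproduction")`) since the underlying choice is not
standardized.

## Fitting: numerical choices

* Least squares on the *mean* observed response fractions (an
  `n_subjects`-weighting flag exists but is off by default), with
  Levenberg–Marquardt iterations on $(\log C_{50}, \log\beta)$ — the log
  scale enforces positivity and stabilizes the covariance.
* Deterministic multistart: $C_{50}$ starts at the geometric mean of the
  two tested concentrations bracketing the half-maximal response (falling
  back to the median tested concentration), $\beta$ starts over
  $\{1, 0.5, 2, 4, 8\}$. Cost tolerance $10^{-10}$.
* Step-like data (all-or-nothing between two adjacent concentrations) put
  the optimum on a flat ridge in $\beta$; the optimizer is then accepted
  when a restart from the final iterate cannot improve the cost, rather
  than reported as a failure. Genuine non-convergence returns a flagged
  failure object, never silent `NA`s.
* The control concentration $c = 0$ is evaluated exactly (no
  log-transform of $c$ inside the model), and fitting the direct abundance
  model floors predictions at complete loss so observations beyond the
  extinction concentration do not bias the slope.
* Control responses above zero are rescaled out with the Abbott correction
  $(r - r_0)/(1 - r_0)$, floored at 0 — the standard chronic-test
  convention, applied per test group.

## Uncertainty propagation

Fit uncertainty is propagated by Monte Carlo: each iteration draws every
fit's $(\log C_{50}, \log\beta)$ from its asymptotic least-squares
covariance, scaled by an inverse-$\chi^2$ draw on the fit's residual
degrees of freedom so that the residual variance's own estimation error is
included (the draws are multivariate-$t$ rather than plug-in normal — with
only a handful of concentrations per test this matters). Species are
sampled independently; each iteration yields one possible MSAR, its
log-logistic refit, and one HC5. 1000 iterations by default; identical
inputs and seed give bit-identical envelopes.

Two presentation choices deserve comment:

* **The MSA band** is the pointwise 2.5th–97.5th percentile of the
  simulated curves, as usual.
* **The HC5 interval** is *not* the percentile interval of the simulated
  HC5s. The simulated HC5 distribution is structurally left-skewed: almost
  any dispersion in the species parameters flattens the aggregate curve,
  so draws rarely exceed the deterministic HC5 and the percentile upper
  bound hugs it from below. On known-truth synthetic panels the percentile
  interval covers only ~60–70% at nominal 95%, while the normal-theory
  interval on $\log$ HC5 (point estimate $\times\, e^{\pm z\,\hat\sigma}$,
  with $\hat\sigma$ the SD of the log simulated HC5s) is approximately
  calibrated. The normal-log interval is therefore the default
  (`hc5_ci_method = "normal"`), with the percentile version retained as an
  option.

Two further conditioning choices keep the simulation meaningful. When the
slope is weakly identified the asymptotic covariance diverges along the
flat direction, and a Gaussian with SD of dozens of log-units produces
physically absurd curves (slopes from $10^{-15}$ to $10^{15}$); eigenvalues
of the log-scale covariance are therefore capped at 4 (at most 2 natural
log-units of SD per direction). The cap, and the interval method above,
were chosen by calibrating HC5 interval coverage against known-truth
synthetic panels rather than fixed a priori. Lifetime fecundity $R_0$ is
held fixed throughout — its statistical uncertainty is not modelled, so
envelopes understate total uncertainty where $R_0$ is itself a rough
estimate (e.g. allometric).

## Lifetime fecundity and traits

`r0_from_traits()` resolves one $R_0$ per species with fixed precedence:
an experimental value wins; clonal species default to $R_0 = 2$; otherwise
$R_0 = \exp(r(W)\,T_g(W))$ from body mass $W$ with allometries
$r(W) = a_r W^{b_r}$, $T_g(W) = a_T W^{b_T}$. The canonical exponents are
opposite ($b_r = -1/4$, $b_T = +1/4$), making the estimate essentially
mass-independent; the intercepts are taxon-group-specific and must be
supplied — there is deliberately no default intercept, because a wrong
$R_0$ silently rescales every abundance curve.

## Variant community curves

Two variants isolate what drives the MSAR (`variant_msar()`):

* `reproduction_only` drops survival effects; since removing a damaging
  factor can only raise abundance, this curve lies at or above the default
  and its fitted $a$ is at least the default $a$.
* `no_intraspecies_variation` sends every slope to infinity, so each
  species responds all-or-nothing at its most sensitive half-maximal
  concentration; the curve then equals $1 - \mathrm{ECDF}$ of
  $\min(EC_{50}, LC_{50})$ and is steeper and more sensitive than the
  default. A species exactly at its threshold counts as lost (the step is
  closed on the right — an arbitrary but fixed tie-break). The step is a
  pure threshold rule: it does not pass through the population-growth
  conversion, consistent with reading the variant as "the curve depends
  only on the C50s".

## The synthetic panel generator

`generate_panel()` emulates the structure of compiled chronic data sets so
every stage is testable against known truth: by default 15 species — 60%
animals with both survival and reproduction tests, 20% with survival only,
20% clonal algae with a direct abundance test — with log-normal
interspecies spread of sensitivities of about an order of magnitude,
survival C50s a factor ~3 above reproduction C50s (reproduction is
typically the more sensitive chronic endpoint), Hill slopes uniform on
[1, 4], and animal $R_0$ log-normal around 20. Each simulated study tests
5 positive concentrations plus a control, log-spaced a factor 10 each side
of the species' most sensitive C50 (a ~3.2× dilution series, the usual
chronic design). Noise is binomial ($n = 20$ animals per survival group)
and truncated Gaussian (SD 0.05) on fractional responses.

What the generator does *not* emulate: real compilations mix studies of
unequal design and quality, concentrations are reported with varying
bioavailability context, endpoints only partially cover the reproduction
cycle, and interspecies sensitivities are correlated by taxonomy. Passing
recovery and coverage tests on these panels therefore demonstrates that
the estimation machinery is correct and calibrated under the stated
conditions, not that real-data MSARs carry these error rates.

Problem sizes used in the shipped validation: exact-recovery checks on
noise-free panels (tolerance $10^{-6}$); 100 replicate panels for HC5
recovery error; 200 replicates × 200 Monte-Carlo iterations (on a 60-point
grid) for interval-coverage checks.

## Worked example

```{r example}
panel <- generate_panel(panel_spec(n_species = 15), seed = 1)
fits <- fit_panel(abbott_correct(panel$tox), panel$traits)
curves <- build_abundance_curves(fits, panel$traits)
msar <- aggregate_msar(curves, default_conc_grid(fits$C50),
                       chemical = "synthetic")
fit <- fit_msar_loglogistic(msar)
glance(fit)

ssd <- fit_ssd(species_ec10(fits), "synthetic")
env <- msar_envelope(fits, panel$traits, n_iter = 500, seed = 1,
                     grid = msar$grid)
report_comparison(env, ssd)
```

The MSAR-based HC5 sits above the SSD's HC5–EC10: the community curve uses
whole exposure–response curves, under which 5% mean abundance loss occurs
at higher concentrations than the 5th percentile of the species' own 10%
effect concentrations. The `autoplot()` methods draw the community curve
with its band, and `plot_abundance_curves()` the species-level curves.

## Known limitations

* Bioavailability differences across tests and between laboratory and
  field (pH, DOC, hardness) are ignored; concentrations are taken at face
  value in µg/L.
* Interspecies interactions are absent: the MSAR is a sum of single-species
  projections, likely optimistic at the community level.
* $T_g$ is assumed unaffected by exposure, all age classes equally
  affected, and $r$-to-$K$ proportionality is taken as given.
* Reproduction endpoints covering only part of the reproductive cycle are
  treated as whole-cycle effects.
* The two-parameter response form cannot represent hormesis or partial
  maximal effects.
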