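# gppanel

Bayesian Gamma-Poisson panel models for state-year mortality counts, built
around one epidemiological question: how is household gun ownership
associated with firearm homicide deaths across the 50 US states, once
time-invariant state-level confounding is dealt with?

State-year death counts are overdispersed, and states differ in unmeasured
stable traits (culture, legislation history, urbanization) that plausibly
drive both gun prevalence and lethal violence. `gppanel` fits negative
binomial count regressions with a log-population offset under two
identification strategies:

* **Mundlak model (MM)** — partially pooled state intercepts plus the state
  mean of the exposure as a covariate. Because the state mean of ownership
  is a descendant of the unobserved state traits, conditioning on it blocks
  the confounding path while keeping the efficiency of partial pooling.
* **Fixed-effects model (FE)** — one freely estimated intercept per state,
  removing all time-invariant state confounding directly.

For state-year $i$ in state $S[i]$:

$$D_i \sim \text{GammaPoisson}(\lambda_i, \phi), \qquad
\log \lambda_i = \log \pi_i + \alpha_{S[i]} + \beta_1 G_i
 + \beta_2 VC_i + \beta_3 PC_i + \beta_4 VC_i \times PC_i
 \,[+\, \beta_5 \bar G_{S[i]}]$$

with population offset $\pi_i$, standardized gun ownership $G_i$,
standardized violent/property crime rates $VC_i, PC_i$, and (MM only) the
state-mean exposure $\bar G_{S[i]}$. Priors:
$\alpha_S \sim \mathcal N(\bar\alpha, \tau)$,
$\bar\alpha \sim \mathcal N(-10, 1)$, $\tau \sim \mathrm{Exp}(1)$,
$\beta_k \sim \mathcal N(0, 1)$ (FE instead:
$\alpha_S \sim \mathcal N(-10, 1)$ independently), and
$\phi \sim \mathrm{Exp}(1)$. The variance is
$\lambda + \lambda^2/\phi$ (mean/shape convention).

The original data sources are restricted, so the package ships a
causally structured synthetic panel generator: an unobserved state trait
raises both the baseline mortality rate and the state's mean ownership,
yearly ownership fluctuates within state, and crime rates follow AR(1)
series independent of the exposure. Everything — fitting, diagnostics,
highest-posterior-density intervals, incidence-rate-ratio reporting,
posterior predictive checks, and replicate recovery studies — runs on
those panels end to end.

## Worked example

```r
library(gppanel)

sim <- simulate_panel(generator_config(seed = 1))
panel <- sim$panel
calibration_report(panel)
#> # A tibble: 5 × 6
#>   variable                         median     iqr     min    max     sd
#>   <chr>                             <dbl>   <dbl>   <dbl>  <dbl>  <dbl>
#> 1 firearm_mortality                150     260.     9     3525   348.
#> 2 firearm_mortality_rate_per_100k    4.60    4.03   0.242   29.8   3.43
#> 3 gun_ownership_pct                 40.8    15.3    9.57    77.9  12.1
#> 4 violent_crime_rate               410.    213.     1      921.  153.
#> 5 property_crime_rate             3043.   1300.   611.    5661.  925.
```

A 900-record balanced panel on realistic scales: median 150 deaths per
state-year, mortality rates of a few per 100,000, ownership centred near
40% with an SD of ~12 percentage points. Fit the adjusted Mundlak model
(the generating slope is 0.06 per pooled SD of ownership):

```r
fit <- fit_model(panel, model_kind = "mundlak", adjusted = TRUE,
                 sampler = sampler_config(n_chains = 2, n_warmup = 500,
                                          n_samples = 500, seed = 2))
fit
#> <gp_fit> mundlak (adjusted)
#> # A tibble: 5 × 5
#>   parameter     mean     se hpdi_lower hpdi_upper
#>   <chr>        <dbl>  <dbl>      <dbl>      <dbl>
#> 1 b_gun     0.0421   0.0477   -0.0394      0.112
#> 2 b_vc      0.102    0.0217    0.0711      0.137
#> 3 b_pc      0.0424   0.0204    0.00956     0.0753
#> 4 b_vc_pc   0.000288 0.0183   -0.0282      0.0276
#> 5 b_gun_bar 0.183    0.0785    0.0658      0.315

s <- summarize_posterior(fit$posterior, "b_gun")
irr_from_coefficient(s$mean, exposure_sd_original_units = 13.6)
#> IRR 1.043 (4% change per 1 SD of exposure, SD = 13.6 percentage points)
```

Each row is the reporting triple — posterior mean, posterior SD, and the
89% highest-posterior-density interval. Here the exposure slope's
posterior mean of 0.042 sits within noise of the generating 0.06 and its
HPDI straddles zero; exponentiating gives the incidence rate ratio, a ~4%
increase in the firearm homicide rate per one SD (13.6 percentage points)
of household ownership. Convergence for every parameter is in
`fit$diagnostics` (split R-hat and effective sample size; all R-hat below
1.05 in this run).

The numbered drivers under `analysis/` run the full workflow — simulate,
fit all four reported specifications (MM/FE × unadjusted/adjusted),
posterior checks, and the replicate recovery study — writing tables,
draws, and manifests under `results/`:

```sh
Rscript analysis/01_simulate_panel.R --seed 1
Rscript analysis/02_fit_models.R    --seed 1
Rscript analysis/03_posterior_checks.R --seed 1
Rscript analysis/04_recovery_study.R --seed 1 --reps 20
```

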