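---
title: "Gamma-Poisson panel models with Mundlak and fixed-effects intercepts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-Poisson panel models with Mundlak and fixed-effects intercepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

`gppanel` estimates the association between household gun ownership and
firearm homicide counts on a balanced state-year panel (50 US states,
18 years in the emulated design). Counts per state-year are overdispersed
relative to the Poisson, and states differ in unmeasured, largely
time-invariant ways (culture, legislation history, urbanization) that
plausibly drive both ownership and lethal violence. The package therefore
fits Gamma-Poisson (negative binomial) regressions with a log-population
offset and two alternative intercept structures that each absorb
time-invariant state confounding, plus the machinery to check, summarize,
and stress-test those fits with no access to the restricted original data
sources.

## Likelihood and linear predictors

Deaths $D_i$ in state-year $i$ follow a Gamma-Poisson distribution with
mean $\lambda_i$ and shape $\phi$:

$$D_i \sim \text{GammaPoisson}(\lambda_i, \phi), \qquad
  \mathrm{Var}(D_i) = \lambda_i + \lambda_i^2 / \phi .$$

Negative-binomial parameterizations vary across software; everywhere in
this package the first parameter is the mean and the second the shape, so
$\phi \to \infty$ recovers the Poisson. The Mundlak model (MM) uses

$$\log \lambda_i = \log \pi_i + \alpha_{S[i]} + \beta_1 G_i
  + \beta_2 VC_i + \beta_3 PC_i + \beta_4\, VC_i \times PC_i
  + \beta_5 \bar G_{S[i]},$$

where $\pi_i$ is population (an offset, not a rate denominator inside the
likelihood), $G_i$, $VC_i$, $PC_i$ are the standardized exposure and crime
rates, and $\bar G_{S[i]}$ is the state mean of the standardized exposure.
The state intercepts are partially pooled,
$\alpha_S \sim \mathcal N(\bar\alpha, \tau)$ with
$\bar\alpha \sim \mathcal N(-10, 1)$ and $\tau \sim \mathrm{Exp}(1)$, and
all slopes have $\mathcal N(0, 1)$ priors. The fixed-effects model (FE)
drops the $\beta_5$ term and instead gives every state a free intercept
with an independent $\mathcal N(-10, 1)$ prior. An unadjusted variant of
either model omits $\beta_2$–$\beta_4$. A third variant,
`random_intercept`, keeps the partial pooling but omits the group-mean
term; it is deliberately misspecified under state-level confounding and
exists only for the bias demonstration below.

Why the group mean identifies the effect: if an unobserved state trait
$U_s$ raises both the baseline rate and the state's typical ownership
level, then $\bar G_s$ is a descendant of $U_s$ and shares its variation.
Conditioning on $\bar G_s$ therefore blocks the confounding path, and
$\beta_1$ is identified from within-state variation — the same source the
FE intercepts isolate, which is why the two models are expected to agree.

### Conventions worth stating

* Standardization is pooled over all state-years (one mean and one
  $n-1$-denominator SD per variable), not within state or year, so a unit
  of $G$ is one panel-wide SD of ownership (about 13.6 percentage points
  in the emulated design).
* The crime interaction is the product of the two standardized rates, not
  a separately standardized product, keeping $\beta_4$ on the same scale
  as the main effects.
* $\bar G_s$ is computed on the standardized scale, so $\beta_5$ shares
  units with $\beta_1$.
* The paper-style reporting "SE" is the posterior standard deviation.
* No prior for $\phi$ accompanies the published models; the package uses
  $\phi \sim \mathrm{Exp}(1)$, consistent with weakly informative
  defaults in the software family the models come from. It is a
  `model_config()` option, and `fixed_phi` pins the dispersion entirely.

## Posterior computation

The built-in sampler is an adaptive random-walk Metropolis, chosen for
auditable, dependency-free, bit-reproducible sampling. Design points:

* $\tau$ and $\phi$ are sampled on the log scale with the Jacobian
  adjustment; everything else on its natural scale.
* The state intercepts are proposed jointly and accepted per state, valid
  because the likelihood factorizes over states given the rest.
* Because the exposure varies mostly between states, $\beta_1$ sits on a
  posterior ridge with the intercepts (and with $\beta_5$ in the MM).
  Plain componentwise proposals mix poorly there, so the sampler adds
  ridge moves: an MM trade between $\beta_1$ and $\beta_5$ along the
  within-state component, a trade between $\beta_5$ and the intercepts
  that leaves the likelihood exactly invariant, and an FE trade between
  $\beta_1$ and the intercepts.
* Proposal scales adapt toward ~0.44 acceptance during warmup in windows
  of 50 iterations and are frozen afterwards.
* Chains start from data-informed, jittered (overdispersed) points; a
  start with non-finite posterior is re-jittered up to 20 times before an
  initialization failure is raised.
* Proposals whose rate overflows are rejected and counted in
  `sampler_warnings` — the generic analogue of divergence warnings from
  gradient-based samplers.

Defaults are 4 chains, 1000 warmup, and 1000 kept iterations. The
external backend (`backend = "external"`) runs the same model through
JAGS as an independent cross-check; the test suite verifies that both
backends agree on posterior means within Monte-Carlo error.

Convergence is assessed with split-$\hat R$ (each chain halved;
rank-normalized variant available) and an autocorrelation-based effective
sample size using Geyer's initial positive/monotone truncation. Both
return `NA` — never a silent 1 — when draws carry no variance.

## Reported quantities

Intervals are highest-posterior-density intervals at 89% mass: the
shortest contiguous window containing $\lceil 0.89\, n\rceil$ sorted
draws, ties broken toward the lowest lower bound. The test suite holds
this implementation to exact agreement with an exhaustive window scan.
Incidence rate ratios are $e^{\beta_1}$ per one pooled SD of exposure,
reported as percent change with integer rounding at display only.
Posterior predictive simulation draws Gamma-Poisson counts at each kept
draw's $(\lambda_i, \phi)$; pointwise 89% predictive coverage of the
observed counts is the accompanying calibration check. Density summaries
use a Gaussian kernel with Silverman's rule-of-thumb bandwidth (plots
only; no inferential quantity depends on the bandwidth).

## The synthetic panel generator

The original inputs (mortality extracts, crime rates, modeled ownership
estimates) are restricted, so all testing runs on synthetic panels whose
generating process encodes the identification structure explicitly:

* A state trait $U_s \sim \mathcal N(0,1)$ shifts the baseline log rate
  by $\gamma U_s$ (`confound_strength_gamma`, default 0.5) and the state
  mean ownership through
  $m_s = 40 + \sigma_B(\delta U_s + \sqrt{1-\delta^2}\, e_s)$ with
  independent $e_s$, between-state SD $\sigma_B = 13$ percentage points,
  and confound share $\delta$ (`confound_to_exposure_delta`, default
  0.5). Parameterizing $\delta$ as a dimensionless share keeps the
  between-state ownership SD calibrated no matter how strong the
  confounding is. State means are clipped to $[2, 70]$ percent (clips are
  counted in the truth record).
* Yearly ownership adds $\mathcal N(0, 4^2)$ percentage points of
  within-state noise. Survey-derived state ownership series drift by
  several points over two decades, and 4 pp keeps enough within-state
  information that neither intercept structure's weakly informative
  priors dominate the slope. Together with $\sigma_B = 13$ this gives a
  total exposure SD near the 13.6 percentage points the models' per-SD
  scale refers to.
* Violent and property crime rates follow stationary AR(1) series
  (means 400 and 3100 per 100,000, marginal SDs 150 and 900,
  autocorrelation 0.8), generated independently of ownership — matching
  the working assumption that crime rates are independent predictors, not
  mediators or confounders of the exposure. A coupling knob exists for
  sensitivity experiments and defaults to off.
* Populations are log-normal (median 4 million, log-SD 1) and constant
  within state by default — a simplification that sharpens recovery tests
  without changing the model structure; a drift option exists.
* True slopes default to $\beta_1 = 0.06$ per pooled SD (the headline
  unadjusted estimate), modest crime effects (0.10, 0.05, 0),
  $\bar\alpha = -10$ (about 4.5 deaths per 100,000 at covariate means),
  and $\phi = 5$ (moderate overdispersion). Slopes apply to covariates
  standardized within the realized panel, so stored truths are directly
  comparable to fitted coefficients.

What the generator does **not** emulate: spatial correlation between
neighbouring states, migration of firearms across state lines, national
time trends, population drift (by default), and exposure measurement
error. Passing recovery tests therefore demonstrates correctness of the
estimation machinery under the assumed causal structure, not robustness
of the substantive findings to violations of it.

## The replicate study

`recovery_study()` simulates panels, fits the requested variants, and
records the posterior mean, SD, 89% HPDI, coverage of the truth, and
bias for the exposure slope. The packaged study conditions are 20
replicates at full panel scale with 2 chains × 500 kept draws per fit —
sizes chosen so the whole study runs in a few minutes while leaving
every fit convergent ($\hat R$ well under 1.1). Three regularities are
asserted: HPDI coverage over the pooled MM and FE fits inside a binomial
band around 0.89; the pooled random-intercept model (no group-mean term)
deviating from the truth by more than 2 posterior SDs in most replicates
while MM and FE do not; and per-replicate MM-FE agreement within 2
posterior SDs. One caveat is worth recording: under between-state
confounding the FE variant's independent $\mathcal N(-10, 1)$ intercept
priors retain a small amount of between-state information, which pulls
its slope a few hundredths toward the confounded between-state
relationship. The printed prior is kept verbatim; the effect is visible
as a slightly lower FE coverage and is part of why the within-state
noise level above matters.

## Numerical and degenerate-input policy

* `standardize()` refuses constant vectors (degenerate variance) rather
  than returning zeros.
* `gamma_poisson_log_pmf()` validates its domain and works through
  log-gamma functions, exact for counts at least up to $10^6$.
* Overflowing linear predictors make the log likelihood $-\infty$ with a
  warning; samplers treat such points as rejected.
* Diagnostics on constant draws return `NA` sentinels; `hpdi()` on
  identical draws returns a zero-width interval, and on fewer than 10
  draws raises an error.
* Unbalanced panels are accepted with a warning; duplicate (state, year)
  pairs, negative counts, and out-of-range percentages are hard errors
  that name the offending rows.

## Limitations

The sampler is a random-walk method: it needs the ridge moves above to
mix on this model family, and very differently shaped models would need
new moves or the external backend. The analysis is ecological; nothing
in the package supports individual-level inference. No zero-inflated,
hurdle, time-varying-coefficient, or spatial variants are provided, and
model comparison (WAIC/LOO) is out of scope.
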