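---
title: "Discrimination-based sample sizes for prognostic survival studies"
author: "survDsize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrimination-based sample sizes for prognostic survival studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survDsize)
```

## The problem

Multivariable prognostic models of time-to-event data — Cox models whose
linear predictor (the *prognostic index*, PI) summarises a patient's risk —
are usually judged by their ability to discriminate between patients, not
by the significance of individual coefficients. Yet the only sample size
guidance in common use, events-per-variable rules, is coefficient-focused.
This package sizes prognostic studies directly on a discrimination target.

## The D measure

Royston and Sauerbrei's *D* quantifies observed separation in survival
across the risk ordering implied by a model. If the PI is normally
distributed with standard deviation σ\*, then

$$D = \kappa\,\sigma^*, \qquad \kappa = \sqrt{8/\pi} \approx 1.596,$$

and *D* is interpretable as the log hazard ratio between the two
equal-sized risk groups obtained by splitting the PI at its median. *D* is
estimated by an auxiliary Cox regression of the outcome on the *rankits*
of the PI — the expected standard-normal order statistics, Blom
approximation $\Phi^{-1}((i-3/8)/(n+1/4))$ — divided by κ
(`estimate_d()`, `rankit_scores()`). Because only ranks of the PI enter,
the estimate is invariant to any strictly increasing transformation of the
PI, and flips sign exactly when the PI is negated (ties receive the mean
of their positional rankits to preserve this). Efron's method handles tied
event times in the auxiliary fit.

*D* maps monotonically to an explained-variation measure
$R^2_D = (D^2/\kappa^2)\,/\,(\pi^2/6 + D^2/\kappa^2)$ (`d_to_r2()`), and an
empirical fractional-polynomial fit to published model pairs converts
Harrell's c-index to *D*: $D = 5.50(c-0.5) + 10.26(c-0.5)^3$ (`c_to_d()`,
valid for $c \ge 0.5$).

### Standard errors

The auxiliary-model standard error of $\hat D$ is biased downward,
increasingly so at high *D*. `bootstrap_se_d()` resamples subjects
(time, status, PI triples) with replacement, recomputing the rankits
within each resample; 500 replications is the recommended default when the
standard error feeds a λ estimate (below), particularly for $D \ge 2$.
Resamples with fewer than two events are skipped and counted; more than
50% skips aborts.

## The structural constant λ

For a fixed true *D* and covariate distribution, the variance of $\hat D$
is taken to be inversely proportional to the number of events *e*:
$e\,\mathrm{var}(\hat D) = \lambda$, a model- and disease-specific
constant. Two estimators are provided:

* **study-based** (`lambda_from_study()`): $\lambda_s = e_1\sigma_1^2$
  from a prior study's event count and SE of *D* — for the worked prior
  study here (502 events, SE 0.09), $\lambda_s = 4.0662$;
* **model-based** (`lambda_from_model()`): an empirical approximation
  fitted on simulated data,
  $\lambda_m = 2.66 + 1.26 D^{1.9} - 1.65 (D\cdot\mathrm{cens})^{1.3}$,
  taking only a target *D* and the anticipated censoring proportion.

λ is carried unrounded everywhere; rounding the displayed $\lambda_s$ of
4.1 to one decimal before use would shift a 558-event answer to 562.
`lambda_from_model()` warns outside the region the approximation was
fitted on (roughly $0.1 \le D \le 3.5$, censoring $\le 0.9$; published
*D* values top out near 3.4). Note the approximation is not monotone in
*D* near $D \approx 0.1$ once censoring is heavy (the negative
$(D\,\mathrm{cens})^{1.3}$ term decays more slowly than the $D^{1.9}$ term
grows); within the fitted region at censoring $\le 0.3$ it is strictly
increasing.

## The sample size family

All calculations return events $e$ and patients
$\lceil e/(1-\mathrm{cens})\rceil$, with the event count the **ceiling**
of the unrounded formula value — the convention that reproduces the
published worked examples.

* `events_significance(lambda, margin, alpha, sided, power)`:
  $e = \lambda (zz/\delta)^2$ with $zz = z_{1-\alpha/2}+z_{1-\beta}$
  (two-sided superiority) or $z_{1-\alpha}+z_{1-\beta}$ (one-sided
  non-inferiority against $H_0{:}\,D^*-D_2 \ge \delta$).
* `events_ci(lambda, width, alpha)`:
  $e = \lambda (z_{1-\alpha/2}/w)^2$ for a $100(1-\alpha)\%$ CI of
  half-width $w$. Algebraically identical to a two-sided
  significance design at 50% power with $\delta = w$.
* `events_with_prior(prior, ...)`: the ancestral forms that keep the prior
  study's variance $\sigma_1^2$ in the denominator,
  $e_2 = \lambda_s[(\delta/zz)^2 - \sigma_1^2]^{-1}$. These are feasible
  only for $\delta > \sigma_1 zz$ (or $w > \sigma_1 z_{1-\alpha/2}$) — the
  function reports the bound when violated — which limits their practical
  use; the fixed-target forms above are generally preferred. Note the
  prior study used in the examples (SE 0.09) makes a margin of 0.25
  infeasible in this form: the bound is 0.2634.
* `composite_events(delta_abs, p, ...)`: accepts whichever of an absolute
  precision $\delta_{abs}$ and a relative precision $pD$ needs fewer
  events at each *D*; the lower-envelope profile peaks at
  $D = \delta_{abs}/p$, where the maximum event count is the
  absolute-margin calculation with $\lambda_m$ evaluated at the peak.
  `achieved_margin()` inverts the calculation to show the precision
  actually delivered if *D* turns out different.

Normal quantiles are always computed in double precision, never taken
from 2-decimal tables: the ceiling makes results sensitive near .5
boundaries (the 444-event example is 443.4992 unrounded).

Defaults: α = 0.05, two-sided, power 0.90, censoring 0. When no value of
*D* is available at all, `decision_flow()` suggests the conversion path
from a published c-index and otherwise falls back to D = 1.4, the mean
over a large collection of published prognostic models — always flagged
as indicative.

## The simulator

`draw_survival_times()` generates the study conditions under which the
calculations are claimed to hold: a scalar covariate $X \sim N(0,1)$
standing in for a full multivariable PI, exponential event times by
inversion of the cumulative hazard, $T_s = -\log(U)e^{-\beta X}/h_0$, and
independent exponential censoring not depending on $X$. Under this model
the true discrimination is exactly $D = \beta\kappa$. The baseline hazard
defaults to 1: *D* and every calculation here are invariant to the time
scale. The censoring rate that yields a desired marginal censoring
proportion is solved numerically from
$P(T_c < T_s) = E_X[\theta/(\theta + h_0 e^{\beta X})]$
(`censoring_rate_for_target()`; at β = 0 this reduces to the closed form
$\theta = h_0\,\mathrm{cens}/(1-\mathrm{cens})$, used as a check).

Because the calculations are phrased in events, `exact_event_dataset()`
delivers exactly *e* events and $\mathrm{round}(e/(1-\mathrm{cens})) - e$
censored records, by oversampling a pool of twice the target size and
subsampling; the pool doubles and regenerates (bounded retries) on a
shortfall. A single seeded RNG stream drives generation and subsampling,
so every dataset is reproducible from its seed.

What the simulator does *not* emulate: non-exponential baselines,
informative censoring, non-normal prognostic indices, covariate
measurement error, and model-selection optimism. Passing tests therefore
show that the calculations are internally correct under their stated
assumptions, not that a real study with a skewed PI or informative
dropout will achieve nominal power.

## The Monte-Carlo validation harness

`run_significance_study()` checks power and type I error of a design:
λ is formed either from a simulated "first study" of $e_1$ events whose
$\sigma_1$ is bootstrapped (study-based) or from the approximation
(model-based); $e_2$ follows; then each replicate simulates an
exact-$e_2$-event dataset under the null and under the alternative,
estimates *D* with a bootstrap SE, and applies a Wald z-test. Both
sidedness variants test a shortfall of δ from the target: the one-sided
null is $D^*-D_2 \ge \delta$ and the two-sided null is $D^*-D_2 = \delta$,
so the statistic is centred at $D^*-\delta$ in both cases
($(\hat D - (D^*-\delta))/\widehat{se}$ against $z_{1-\alpha}$ or its
absolute value against $z_{1-\alpha/2}$). The type-I arm generates data at
the null value $D^*-\delta$; the power arm generates at $D^*$ — the
alternative the design's power statement refers to, and the *D* at which
the variance assumed by the calculation ($\lambda(D^*)/e_2$) actually
holds. Centring the two-sided test at $D^*$ instead, with power taken at
$D^*-\delta$, would make the harness report systematic over-powering
(~9% at the desk-scale parameters below), because
$\mathrm{var}(\hat D)$ at the smaller alternative is
$\lambda(D^*-\delta)/e_2 < \lambda(D^*)/e_2$. `run_coverage_study()` checks
the precision designs by the fraction of replicates with
$|\hat D - \beta\kappa| \le w$, which should approximate $1-\alpha$.

Model-based (λₘ) designs are expected to carry small power inaccuracies —
up to about 2% absolute at 80% nominal — reflecting the approximation
error in the λ model; acceptance of the harness results allows for this
on top of binomial Monte-Carlo error $\sqrt{p(1-p)/\mathrm{reps}}$.

### Problem sizes used in the shipped tests

The package's own test suite runs the harness at desk scale, chosen so
that Monte-Carlo error bounds are meaningful while the whole suite stays
quick: 200 replicate datasets of 500 events for estimator recovery; 300
replicates at each of 250/500/1000 events for the
$e\,\mathrm{var}(\hat D)$ constancy check; 500 replicates with 100
bootstrap reps per replicate for the power/type-I check of the two-sided
model-based design at $D = 1.6$, δ = 0.4, 20% censoring; and 500
replicates for coverage of the half-width-0.2 precision design. The
harness accepts larger `replications`/`boot` (the published studies used
2000 and 500) for closer reproduction.

## Numerical and design choices

* **Ceiling, not rounding,** of event counts: rounding-to-nearest fails to
  reproduce several published worked values (e.g. 557.16 → 558,
  752.3 → 753). Patients are the ceiling of events/(1−cens). One published
  patient count (601 for the 558-event design at 7% censoring) exceeds
  this convention's 558/0.93 = 600 by one; we keep the ceiling rule
  throughout rather than chase isolated rounding in the source values.
* **CI calculations use $z_{1-\alpha/2}$** throughout; the worked values
  391 and 444 confirm this.
* **Efron tie handling** in every Cox fit; simulated continuous times make
  ties rare, and Efron is the least biased common default.
* **Bootstrap resamples subjects,** not residuals, preserving the
  censoring pattern.
* The one-dimensional auxiliary Cox fits in bootstrap and Monte-Carlo
  loops go through `survival::coxph.fit` directly (the formula interface
  costs ~5× more); the tests verify the estimate against an independently
  optimised Efron partial likelihood.
* Degenerate inputs: a constant PI returns D = 0 with a warning;
  fewer than two events is an error; all-censored data is an error.

## Limitations

* No adjustment for case-mix differences between development and
  validation populations; the calculations assume comparable covariate
  distributions.
* No events-per-variable considerations: the number of candidate model
  variables (and selection-induced optimism in *D*) is outside scope.
* No competing risks, time-dependent covariates, or non-exponential
  simulation baselines.
* The c-to-D conversion is an empirical fit across heterogeneous
  published models; treat converted values as starting points, and prefer
  a direct *D* from a comparable study when one exists.
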