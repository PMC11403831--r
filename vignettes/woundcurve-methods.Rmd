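---
title: "Modelling wound-area trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wound-area trajectories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(woundcurve)
library(dplyr)
```

## The model

Trials of wound-healing interventions usually measure each wound's area many
times (here: at every dressing change, twice weekly for up to 70 days), yet
are commonly analysed by comparing means at a single landmark day. A
model-based analysis can use every measurement. `woundcurve` implements a
hierarchical log-linear model for longitudinal wound-area data built from
four assumptions: healing starts at enrolment (no lag phase), measurement
error is proportionate to wound area, biological variation in healing is
also proportionate to area, and wounds heal on average along a common curve
relating *proportionate* area to time.

Writing $y_i(t)$ for the measured area (cm²) of patient $i$'s wound at $t$
days post-randomisation, the data-generating process is multiplicative,

$$y_i(t) = y_i^*(0)\, f(t;\rho)\, u_i(t),$$

with $y_i^*(0)$ the true (error-free) baseline area, $f$ a healing-rate
function, and $u_i(t)$ lognormal noise. On the log scale this is linear:

$$\log y_i(t) = \beta_0 + \alpha_i + \log f(t;\rho_{d_i}) + e_{it},
\qquad \alpha_i \sim N(0, \tau^2),\; e_{it} \sim N(0, \omega^2),$$

where $d_i \in \{0, 1\}$ is the treatment arm; both arms share
$(\mu, \tau, \omega)$ (randomisation justifies a common baseline
distribution) while each arm has its own healing-rate parameters $\rho_0$,
$\rho_1$.

**The intercept convention.** The error factor is centred so that
measurements are correct on average: $\varepsilon_{it} = \log u_i(t) \sim
N(-\omega^2/2, \omega^2)$ gives $E[u_i(t)] = 1$ exactly. We parameterise in
$(\mu, \tau, \omega)$ with $\log y_i^*(0) \sim N(\mu, \tau^2)$ and define

$$\beta_0 = \mu - \omega^2/2.$$

This single identity reconciles the centred-error statement of the
data-generating process with the zero-mean error term of the regression
form, and it is what makes the closed-form treatment effect below equal
"mean baseline area × proportionate difference". It matters when
interpreting $\beta_0$ posteriors: the package reports $\mu$, not $\beta_0$.

## The healing-rate functions

Eleven families of $f(t;\rho)$ are available through
`healing_function()`:

```{r}
healing_families()
```

Families 1–8 satisfy $f(0) = 1$; the three log-scale families start at
$f(0) = e$ because the constant inside $\exp(1 + \dots)$ is retained exactly
as conventionally written even though it is absorbed by $\beta_0$ (a
non-identifiable shift — kept so fitted coefficients are comparable with the
standard parameterisation, and documented so $\beta_0$ is interpreted
correctly).

Two design points deserve notes:

* **Wendland families.** These are compactly supported: the mean trajectory
  reaches *exactly* zero at a finite time — the only families that can
  represent complete healing of the average wound. Time is rescaled as
  $s = t/t_{\max}$ with $t_{\max} = 100$ days by default, chosen larger than
  the 70-day trial horizon so unhealed wounds at trial end retain positive
  mean area. The conventional Wendland-1 form is sometimes printed as
  $(1+(p+1)s)(1+s)^{p+1}$, which does not vanish at $s = 1$; `woundcurve`
  implements the compactly supported form $(1+(p+1)s)(1-s)_+^{p+1}$, which
  does, and exposes the non-vanishing variant behind
  `as_printed = TRUE` strictly for audits.
* **Semiparametric family.** $f(t) = 1 - \sum_m p_m h_m(t)$ with a cubic
  B-spline basis, five interior knots spaced evenly over the time range
  (`spline_basis()`). The anchoring of $f$ at 1 is not implied by a raw
  B-spline basis, so each basis column is shifted by its value at $t = 0$,
  making $h_m(0) = 0$ and hence $f(0) = 1$ structural. This matches the
  anchored families and makes the $p_m$ identifiable against $\beta_0$.

Derivatives (`hf_deriv()`) are analytic for every family; the square-root
families have an unbounded derivative at $t = 0$, so evaluating their
derivative exactly at zero is a domain error rather than a silent
$\pm\infty$ — rate estimands only use $t > 0$.

```{r healing-functions}
grid <- seq(0, 100, 0.5)
hf <- healing_function("square_root", c(-0.004, -0.07))
w1 <- healing_function("wendland1", 2, t_max = 100)
plot(grid, hf_eval(hf, grid), type = "l", ylim = c(0, 1.1),
     xlab = "days", ylab = "proportionate area f(t)")
lines(grid, hf_eval(w1, grid), col = "steelblue")
legend("topright", c("square root", "Wendland 1"), lty = 1,
       col = c("black", "steelblue"), bty = "n")
```

## Priors

Weakly informative defaults (`prior_spec()`): $\mu \sim N(1, 2^2)$,
constraining mean baseline area to roughly 0–20 cm² (the inclusion-criterion
range of the motivating trial design); $\tau \sim N(0, 2^2)$ and $\omega
\sim N(0, 0.5^2)$, both truncated to $[0, \infty)$, allowing noise up to
around ±100%. No standard prior exists for the healing-rate parameters; each
component gets $N(0, 1)$ by default (`rho_sd`), deliberately wide relative
to per-day rates of realistic magnitude (order $10^{-3}$–$10^{-1}$). Time is
*not* internally rescaled to $[0,1]$: parameters stay in per-day units so
fitted values read directly as daily rates.

## Posterior sampling

`wound_fit()` uses a deterministic Metropolis-within-Gibbs sampler designed
around two geometric features of this posterior:

1. **Patient effects are integrated out analytically.** Conditional on
   $(\mu, \tau, \omega, \rho)$, each patient's residual vector is
   multivariate normal with compound-symmetry covariance
   $\omega^2 I + \tau^2 J$, so the collapsed likelihood needs only
   per-patient sufficient statistics (count, mean, within-patient sum of
   squares). Sampling $(\mu, \tau, \omega, \rho)$ against this collapsed
   likelihood removes the strong coupling between the global parameters and
   the $n$ patient effects that cripples a naive Gibbs scheme. $\mu$ then
   has a conjugate normal update; $\tau$ and $\omega$ are updated by
   stepping-out slice sampling ($\omega$ also shifts the mean through
   $\beta_0$, so it is never conjugate). The $\alpha_i$ are drawn from their
   exact normal conditional once per retained iteration, for the pointwise
   log-likelihood matrix and posterior predictive checks.
2. **Healing-rate parameters ride narrow ridges.** In e.g. the square-root
   family the regressors $t$ and $\sqrt t$ are nearly collinear over a
   twice-weekly schedule, so component-wise updates mix poorly. During the
   first half of warmup each $\rho$ component is slice-sampled along
   coordinate axes; the empirical covariance of those draws is then
   eigendecomposed, and subsequent slice updates move along the eigenvector
   directions with widths proportional to $\sqrt{\lambda_j}$.

Positivity of $f$ for the linear-scale families is enforced *softly*: any
proposal with $f(t) \le 0$ at an observed time has collapsed log-likelihood
$-\infty$ and is rejected by slice shrinkage. A hard constraint would be
wrong because the admissible $\rho$ region depends on the observed time
range. Initial values: $\mu$ at the log mean earliest-visit area; $\tau,
\omega$ at half their prior scale; $\rho$ at small healing-direction values,
re-jittered (up to 100 attempts) if $f \le 0$ anywhere. Defaults are 4
chains × 1000 warmup + 1000 retained iterations — ordinary practice, not a
claim about any particular published analysis; seeds and settings are
recorded in the fit's metadata. Convergence is reported via split-$\hat R$
(warning above 1.01, never a hard failure) and effective sample sizes from
`coda`. With no rows of data the sampler reproduces the prior exactly, which
the test suite exploits as a correctness check.

Observed areas of exactly zero cannot enter a lognormal likelihood. The
loading policy (`as_measurement_table()`) drops them with a counted warning
by default; an alternative policy flags them as left-censored at a detection
limit, and `log_lik_pointwise()` then uses the censored (lower-tail
probability) contribution. The MCMC front end fits the density likelihood;
the censored mode is provided at the likelihood level for completeness.

## Model comparison

`waic()` and `psis_loo()` score the draws × observations pointwise
log-likelihood matrix. Both are reported on the **elpd scale, larger =
better** — stated on every output, since deviance-scale conventions invert
the ordering. The pointwise likelihood is computed for $\log y$ without the
lognormal Jacobian $-\log y$; the term is parameter-free and common to all
eleven families, so every *difference* of criteria is unaffected, while
absolute elpd values carry this convention.

PSIS follows the standard recipe: per observation the importance ratios
$\exp(-\ell_s)$ are tail-smoothed by fitting a generalized Pareto
distribution (Zhang–Stephens quasi-Bayesian profile estimate, weakly
informative shape regularisation) to the largest 20% of ratios, replacing
them with its expected order statistics, truncating at the raw maximum. The
shape diagnostic $\hat k$ is returned per observation; values above 0.7 are
flagged and counted (`n_bad_k`), never silently dropped. Leave-one-out is at
the *observation* level — the standard formulation for these criteria;
patient-level (grouped) cross-validation would answer a different question
and is left as future work.

`posterior_predictive_check()` replicates the full dataset at the observed
design points from posterior draws (drawn patient effects + fresh
measurement noise) and overlays replicate densities (blue) on the observed
density (red). Because a visual check cannot be asserted in a test, the
companion statistic `ppc_coverage()` reports the fraction of grid points at
which the observed log-area density lies inside the pointwise min–max
envelope of the replicates, and `ppc_spread()` summarises replicate
variance so directional statements ("model A spreads its predictions more
widely than model B") are testable.

## Treatment-effect estimands

From posterior draws (all as `effect_curve` tibbles with pointwise means and
2.5/97.5% quantiles):

* `delta1()` — mean difference in area (cm²):
  $\delta_1(t) = \exp(\beta_0 + (\tau^2+\omega^2)/2)(f_1(t) - f_0(t))$,
  which under $\beta_0 = \mu - \omega^2/2$ equals
  $\exp(\mu + \tau^2/2)(f_1 - f_0)$ — the marginal mean baseline area times
  the proportionate difference. Without the $\beta_0$ convention this
  formula would overstate the mean by $\exp(\omega^2/2)$.
* `delta2()` — difference in proportionate area: $f_1(t) - f_0(t)$. Fitted
  curves need not start at 1 (the log families start at $e$), so the
  default reports the plain difference, and `normalize = TRUE` divides each
  arm by its own $f(0)$ for a genuinely proportionate contrast. Both are
  legitimate; the choice is surfaced rather than hidden.
* `rate_difference()` — cm²/day, instantaneous
  ($\exp(\mu+\tau^2/2)(f_1'(t) - f_0'(t))$) or average up to $T$
  ($\exp(\mu+\tau^2/2)[(f_1(T)-f_1(0)) - (f_0(T)-f_0(0))]/T$). These are
  reconstructed from the model's first principles; closed forms for rate
  contrasts are not part of the published model statement, so they are
  labelled as reconstructions, with both modes exposed.
* `proportion_healed()` — per arm and difference. Under the model the true
  area at $t$ is $\exp(w_i(0)) f(t)$ with $w_i(0) \sim N(\mu, \tau^2)$, so
  $P(\text{area} \le c) = \Phi\big((\log c - \mu - \log f(t))/\tau\big)$;
  also a reconstruction. Degenerate $\tau = 0$ draws give a step function
  (value 0.5 exactly at the boundary). The default threshold
  $c = 0.25$ cm² is an arbitrary near-complete re-epithelialisation proxy —
  user-set, and not a published value.
* `nonparametric_difference()` — the comparator: each patient's measurement
  nearest the landmark day within ± one visit window, Welch difference in
  means with a t-interval. Nearest-visit selection was chosen (over
  last-observation-carried-forward) as the more symmetric convention; the
  window default (3.5 days) is half the longest visit gap.

The algebraic identity $\delta_1(t) = \exp(\mu + \tau^2/2)\,\delta_2(t)$
holds draw by draw and is asserted in the tests, as is agreement of the
$\delta_1$ closed form with a brute-force simulation oracle ($10^6$
simulated wounds per arm).

## The synthetic-trial generator

No public dataset accompanies this class of trial, so `generate_trial()`
emulates the design: 130 patients randomised 1:1, visits at days 0, 3, 7,
10, … (alternating 3/4-day gaps, "twice weekly") up to day 70, baseline
areas within the 2–20 cm² inclusion range, and optionally several
measurement methods per image, per-visit dropout, and stopping of visits
once the true area crosses a healed threshold. Generating-truth defaults
(`trial_truth()`) were fixed once: $\mu = 1.5$ ($e^{1.5} = 4.48$ cm²,
matching reported baseline means of 4.1–4.6 cm² in this trial class),
$\tau = 0.5$, $\omega = 0.3$ (within the 0.2–0.5 band that is plausible for
imaging-based area measurement), square-root family with
$\rho = (-0.004, -0.07)$ in both arms — monotone healing with positive area
throughout the schedule, and a null treatment effect unless overridden.

Two honesty notes. First, truncating baselines to the inclusion range
mildly breaks the model's untruncated $N(\mu, \tau^2)$ assumption — kept as
realistic misspecification (it shrinks the apparent $\tau$), with
`truncate_baseline = FALSE` available for exact-recovery experiments.
Second, the generator shares one true area across measurement methods with
independent errors; analyses fit each method separately, so that
correlation structure is a simulator-only feature. What passing tests on
synthetic trials demonstrate is that the pipeline has the claimed operating
characteristics *under the model and design it emulates* — parameter
recovery with nominal coverage, correct model ranking, precision gains over
the landmark comparator. They cannot certify behaviour under features the
generator does not produce: lag phases, wound regrowth, assessor
disagreement, non-lognormal error, or informative missingness.

## Problem sizes and numerical choices in the tests

The test suite runs everything at sizes chosen to make each check
informative: full 130-patient trials with 2 chains × 400/400 iterations for
the 20-replicate coverage experiment; 60-patient trials for the 20-replicate
model-ranking experiment; an 8-patient, 4-visit instance (32 observations)
for the brute-force exact-LOO comparison, where each of 10 held-out
observations triggers a complete refit; $10^6$ simulated wounds per arm for
the estimand oracle. Slice widths, the $10^{-12}$ shrinkage floor, the
eigen-adaptation point (mid-warmup), and the $10^{-8}$ lower bound on
$\omega$ are implementation constants with no scientific content; the
$\hat k$ thresholds (0.5/0.7) and 20% tail fraction follow standard PSIS
practice.

## Known limitations

* Observation-level LOO only; no grouped (patient-level) cross-validation,
  Bayes factors, stacking, or model averaging.
* One wound per patient; no multi-wound nesting, no covariate adjustment,
  no lag-phase or autoregressive structure, no additive-error (linear-scale)
  alternatives.
* The three measurement methods are fitted separately; no joint
  multi-method measurement-error model.
* Time-to-healing survival analyses (hazard ratios) are out of scope; the
  proportion-healed curve is a model-derived summary, not a time-to-event
  analysis.
* The sampler is exact but single-threaded R; a 130-patient fit at default
  settings takes tens of seconds, which is fine for a trial analysis but
  slow for large simulation studies.
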