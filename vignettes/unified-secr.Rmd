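---
title: "A unified likelihood for capture-recapture and distance sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A unified likelihood for capture-recapture and distance sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unisecr)
```

## The model

`unisecr` estimates animal (or cue) density from surveys in which `K`
detectors at known locations record, over `S` occasions, which individuals
they detected — and, optionally, noisy information about where each
detected individual was. One likelihood covers the whole spectrum from
spatially explicit capture–recapture (SECR; capture locations only) through
hybrid designs (capture histories plus bearings, arrival times, received
signal strengths or estimated distances) to distance sampling and
mark-recapture distance sampling (locations observed exactly).

Animals are assumed to be distributed over the plane as a homogeneous
Poisson process with intensity $D$ (animals per unit area); each animal has
a single activity centre $x$ for the survey. An animal at $x$ is detected
by detector $k$ on one occasion with probability $p_k(x;\theta)$, giving a
per-occasion inclusion probability
$p_\cdot^{(s)}(x) = 1 - \prod_k \{1 - p_k(x)\}$ and an overall inclusion
probability $p_\cdot(x) = 1 - \{1 - p_\cdot^{(s)}(x)\}^S$. Detected animals
then form a thinned Poisson process with intensity $D\,p_\cdot(x)$ and
expected count $\lambda = \int D\,p_\cdot(x)\,dx$.

Writing $\omega_i$ for animal $i$'s capture history and $Y_i$ for its
supplementary observations, the likelihood marginalises the unknown
locations:

$$
L(D, \theta, \gamma) \;=\; P(n)\;\prod_{i=1}^{n}
\int \frac{D\,p_\cdot(x)}{\lambda}\;
\frac{P(\omega_i \mid x;\theta)}{1}\;
f(Y_i \mid x, \omega_i;\gamma)\; dx ,
$$

with $P(n)$ Poisson($\lambda$) by default. The $p_\cdot(x)$ in the
thinned-process density cancels against the conditioning inside
$P(\omega_i \mid x)$, which the implementation exploits for numerical
stability: the per-animal integrand is $D \cdot \Pr(\text{history at } x)
\cdot f(Y_i \mid x) / \lambda$, evaluated entirely in log space.

### Capture-history models

Three detector types are supported, each with its own conditional history
probability:

* **binary proximity** — independent Bernoulli indicators per detector;
* **count proximity** — Poisson counts with rate $\lambda_0 p_k(x)$; the
  occasion inclusion probability implied by this model is
  $1 - \exp\{-\lambda_0 \sum_k p_k(x)\}$, which keeps the conditional
  history distribution proper (it sums to one over all nonzero histories,
  and the package tests enumerate this);
* **multi-catch traps** — at most one detector per occasion, with
  multinomial cell probabilities given by relative hazards
  $r_k = h_k / \sum_j h_j$, where $h_k(x) = -\log\{1 - p_k(x)\}$. Defining
  the hazards from an arbitrary detection form keeps the competing-hazard
  construction available for every detection function.

With a single occasion (or a single detector) the history term reduces to
the familiar Huggins-style conditional likelihood; the test suite checks
this reduction to machine precision.

### Detection functions

* half-normal, $p(d) = \exp\{-d^2/(2\sigma^2)\}$, certain detection at
  distance zero (acoustic survey default);
* half-normal with estimable $g(0)$ on the logit scale, optionally with
  detector-specific parameters (two unequal aerial observers);
* hazard half-normal, $p(d) = 1 - \exp\{-\lambda_0 e^{-d^2/2\sigma^2}\}$;
* signal-strength threshold: received strength is Gaussian around
  $\mu(d) = \beta_0 + \beta_1 d$ (or $\exp(\beta_0+\beta_1 d)$ under a log
  link) with SD $\sigma_s$, and detection is the event that it reaches the
  processing cutoff $c$, so $p(d) = 1 - \Phi\{(c - \mu(d))/\sigma_s\}$.
  Detection *is* threshold exceedance here: combining this with an
  independent distance-based detection function is refused, and the
  retained strengths enter the likelihood as truncated-normal observation
  densities sharing $\beta_0,\beta_1,\sigma_s$. Both links are exposed;
  the identity link is the default.

### Supplementary observation models

Each kind contributes a conditional log-density given $x$, summed under
conditional independence:

* **bearings** — von Mises errors about the true bearing, concentration
  $\kappa$ (radians internally; compass-degree conversion provided).
  Bearings are taken as unbiased; bias parameters are deliberately not
  implemented.
* **times of arrival** — Gaussian errors with SD $\sigma_t$ (seconds)
  about emission time $+ d/\text{(sound speed)}$. Emission times are
  incidental parameters, removed by conditioning on the mean arrival time;
  equivalently (and the tests verify this numerically) by integrating a
  flat random effect for the emission time. A sound heard on one detector
  carries no timing information. The propagation slope is fixed at
  $1/330$ s/m by default and can be freed (`estimate_slope = TRUE`).
* **signal strengths** — the truncated-normal densities described above.
* **distances** — unbiased gamma errors with shape $\alpha$ (error CV
  $1/\sqrt{\alpha}$), mean equal to the true distance; per-observer
  $\alpha$ optional.
* **exact locations** — distance-sampling mode: the marginal integral is
  replaced by evaluation of the integrand at the observed location (not by
  a delta spike inside the quadrature, which would depend on the mesh).

Multiplicative constants free of parameters and of $x$ are dropped
throughout, so AIC comparisons are valid only between models fitted to the
same data with the same observation structure; `compare_models()` enforces
the same-data requirement with a fingerprint.

## Spatial integration

All integrals over the plane are midpoint sums over a rectangular habitat
mask: grid points at spacing $s$ each represent a cell of area $s^2$. This
is standard SECR practice; its error is controlled empirically by the
package's convergence tests, which require the rate $\lambda$ and every
per-animal marginal to agree with quarter-spacing evaluation to better
than 0.5% on the fixture surveys.

Two numerical points deserve emphasis.

* **Buffer width must accommodate the fit, not just the truth.** The mask
  must extend far enough that $p_\cdot(x)$ is negligible at its edge for
  every parameter value the optimiser will visit. In weakly identified
  designs (e.g. three co-linear detectors whose recaptures never span more
  than twice their spacing) the fitted scale wanders far above its true
  value, and a buffer adequate at the truth truncates $\lambda$ for those
  fits and inflates the density estimate's upper tail. `fit_unisecr()`
  warns whenever the fitted edge inclusion probability exceeds $10^{-3}$;
  the shipped gibbon-type design uses a 10 km buffer for this reason.
  Quadrature resolution, by contrast, mainly affects sharply concentrated
  observation models (tight bearings need cells small relative to the
  bearing wedge).
* **Degenerate regions.** Probabilities are clamped to
  $[10^{-300}, 1-10^{-12}]$ so that log-space matrix products stay finite;
  a per-animal log-marginal below $-600$ is indistinguishable from a zero
  integrand (an impossible history) and is reported as $-\infty$ with a
  warning naming the animal, while the optimiser sees the smooth raw value.

## Fitting, uncertainty, model choice

Parameters are transformed (log for $D$, scales, $\kappa$, $\sigma_t$,
$\sigma_s$, $\alpha$, $\lambda_0$; logit for $g(0)$; identity for the
signal-strength regression coefficients and the TOA slope) and the
likelihood is maximised by BFGS with, by default, three starts — the
supplied start plus two jittered on the transformed scale (SD 0.25,
seed-controlled). The covariance matrix is the inverse of a central
finite-difference Hessian (step $10^{-4}$ on the transformed scale);
standard errors map to the natural scale by the delta method, CVs are
SE/estimate (equivalently the transformed-scale SE for log-linked
parameters), and Wald intervals are formed on the transformed scale and
back-transformed. Non-convergence is flagged in the result, never thrown.
Density is reported in user-chosen units (per hectare, per km², per m²);
everything internal is in metres and per-m².

The number-of-detections model is Poisson by default. The binomial
alternative treats the population as a fixed `N` spread over the region
implied by `N` and the density, so the mean inclusion probability is
$\lambda/N$; this parametrisation keeps density identified and converges
to the Poisson model as `N` grows, a limit the tests check.

## Location posteriors

Given (fitted) parameters, each animal's location posterior over the mask
is proportional to $f(Y_i\mid x)\,\Pr(\omega_i \mid x)\,D\,p_\cdot(x)$,
normalised over cells. Point summaries report both the posterior mode and
mean, since either may be wanted as "the" location estimate.
Highest-density regions are returned as cell sets: cells are ranked by
weight and accumulated until the requested mass is covered, which makes
regions minimal under ties and automatically nested across levels;
`plot()` interpolates contours for display only.

## The simulator and the shipped designs

`sim_population()` draws a Poisson number of animals uniformly over the
mask rectangle — the simulation region coincides with the estimator's
integration region, so simulator and likelihood describe the same
truncated world. `sim_detections()` thins by the detection model (drawing
latent received strengths for the threshold model, so detection and the
retained strengths are generated jointly), and `sim_observations()` adds
von Mises bearings, gamma distances and arrival times with emission times
uniform over the occasion. `run_study()` simulates once per replicate and
fits every model variant to the same data (common random numbers, one RNG
stream per replicate derived from the master seed), so variant comparisons
are paired; summaries are over converged fits, with a variant flagged
unreliable beyond 20% failures. Studies default to 100 replicates, a
desk-scale choice; per-fit starts default to the generating values with a
single optimisation start, adequate when the fitted model matches the
generator.

Three preset designs emulate the motivating survey types:

* `design_gibbon()` — three in-line listening posts 500 m apart, density
  0.32 groups/km², half-normal scale 1248 m, $g(0)=1$, von Mises bearings.
  A single such array yields only ~6 expected detections at this truth, so
  the survey is replicated as independent sessions, 13 by default, putting
  the expected total at ~77 detected calls; the multi-session
  log-likelihood is the sum over sessions (for identical sessions this is
  likelihood-equivalent to one pooled survey). The bearing concentration
  of trained listeners is not something the source analyses report; the
  default $\kappa = 70$ (angular SD ≈ 7°) is a realistic placeholder, and
  the capture-history-only results do not depend on it.

  This design is a deliberately poor one for capture histories alone:
  recaptures never span more than 1 km, so the data say almost nothing
  about detection beyond that range, and the capture-history-only
  likelihood is often *bimodal*, with a small-scale/high-density mode
  (scale far below truth, density several times truth) competing with a
  truth-adjacent mode. The density estimator's sampling distribution is
  correspondingly heavy-tailed to the right — its mean percent bias is
  dominated by the minority of replicates in which the small-scale mode
  wins, which also makes that mean a fragile summary: it carries a
  Monte-Carlo standard error of roughly 9 percentage points per 100
  replicates, and which mode wins in a borderline dataset can depend on
  the mask. Adding the bearings removes both the bias and the bimodality.
* `design_frog()` — six microphones in a 10 m × 6 m rectangle,
  signal-strength threshold detection plus arrival times. The acoustic
  parameters (155 dB source level, −2.1 dB/m decay, 6 dB receive SD,
  130 dB cutoff, 2 ms timing error at 330 m/s) are realistic values for a
  calling-frog chorus recorded at metre scales, chosen once; density is
  calibrated so the expected number of detected clicks is 345.
* `design_whale()` — two co-located aerial observers with observer-specific
  half-normal detection ($g(0)$ 0.98 and 0.30), gamma distance errors with
  CV 32% ($\alpha = 9.77$), cue density 1.72 per ha. The detection scales
  are not reported by the source analyses, so the first observer's scale
  is calibrated to give an expected sample size of 70 (landing near
  250 m), with the second fixed at three quarters of the first. Without
  the distance observations this design is unfittable — co-located
  detectors carry no distance information, and the model constructor
  refuses that combination.

What the simulator does *not* emulate: animal movement within or between
occasions, non-uniform density surfaces, covariate effects on detection,
correlated observation errors across detectors, distance-dependent bearing
error, and uncertain identity of recaptures. Passing simulation tests
therefore demonstrates correctness of the implemented model, not
robustness of the estimator to these violations in field data.

## Problem sizes in the shipped tests

The test-suite studies run at deliberately modest sizes chosen as this
package's own desk-scale defaults: 200 replicates for the
capture-history-only bias study in the gibbon design, 100 replicates per
observation-model family for density-recovery checks at survey-realistic
sample sizes (about 77, 345 and 70 detections), and 25–30 replicates for
the paired CV-ordering comparisons. The acceptance script defaults to 500
replicates for the bias study. Quadrature-convergence fixtures use masks
of a few hundred to a few hundred thousand points as noted above.

## Known limitations

Only rectangular masks and planar Cartesian coordinates are supported (no
polygon habitat or geographic projections). Density is homogeneous;
covariates, density surfaces, open populations, movement and identity
uncertainty are out of scope. Interval estimates are Wald-type on the
transformed scale; profile or bootstrap intervals are not provided.
Exact-location (DS/MRDS) mode is implemented for binary proximity
detectors on a single-type array. Arrival-time data are treated
per-occasion with an independent emission time per occasion.
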