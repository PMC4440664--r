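# unisecr

Density estimation for wildlife surveys in which detectors at known
locations record *which* individuals they detected, and possibly noisy
information about *where* each one was. `unisecr` implements, in one
likelihood, the continuum from spatially explicit capture–recapture (SECR:
capture locations only), through hybrid designs in which capture histories
are supplemented by estimated bearings, times of arrival, received signal
strengths or estimated distances, to distance sampling (DS) and
mark-recapture distance sampling (MRDS), where locations are observed
exactly. Typical users are ecologists and biostatisticians analysing
acoustic arrays (gibbon or frog choruses on microphone/listener arrays),
camera or trap grids, and double-observer visual surveys with distance
measurement error.

## The model

Animals occur as a homogeneous Poisson process with intensity *D*; an
animal at *x* is detected by detector *k* on an occasion with probability
*p<sub>k</sub>(x; θ)* (half-normal, half-normal with estimable *g*(0),
hazard half-normal, or signal-strength threshold exceedance). With
*p*<sub>·</sub>(*x*) the probability of being detected at least once and
λ = ∫ *D p*<sub>·</sub>(*x*) d*x*, the likelihood of observing *n* animals
with capture histories ω and location observations *Y* is

```
L(D, θ, γ) = P(n; λ) × ∏ᵢ ∫ [D p·(x)/λ] · P(ωᵢ | x; θ) · f(Yᵢ | x, ωᵢ; γ) dx
```

with the integral evaluated over a discrete habitat mask. Supplementary
observation models *f*(*Y* | *x*): von Mises bearings, Gaussian arrival
times (emission times conditioned away), truncated-normal signal
strengths sharing parameters with the threshold detection model, gamma
distance estimates, or exact locations (DS/MRDS). Estimation is maximum
likelihood with delta-method uncertainty; animal locations are recovered
afterwards as posteriors over the mask via Bayes' theorem.

## Worked example

Simulate an acoustic survey shaped like a gibbon listening-post design
(three in-line posts 500 m apart, replicated as 13 independent arrays so
that about 77 calls are detected), then fit models with and without the
bearing data:

```r
library(unisecr)
set.seed(2)

design <- design_gibbon()          # truth: D = 0.32 groups/km2, sigma = 1248 m
survey <- sim_survey(design)

model <- unisecr_model(survey$capture, design$layout, design$mask,
                       detfn_halfnormal(),
                       observation = list(obs_bearing(70)),
                       obs = survey$obs, D_units = "per_km2")
fit <- fit_unisecr(model, start = c(D = 0.32, sigma = 1248, kappa = 70))
fit
#> Unified SECR/DS fit: 79 animals, 13 session(s)
#> log-likelihood: -334.206   AIC: 674.412
#> density units: per_km2
#>
#>    par   estimate        se    cv fixed
#>      D    0.35024   0.08555 0.244 FALSE
#>  sigma 1205.00000 135.30000 0.112 FALSE
#>  kappa   37.68200   7.90000 0.210 FALSE
```

Density is recovered close to the simulated truth (0.35 vs 0.32 groups
per km², CV 24%). Dropping the bearings and refitting the
capture-history-only model on the same data:

```r
model0 <- unisecr_model(survey$capture, design$layout, design$mask,
                        detfn_halfnormal(), obs = survey$obs,
                        D_units = "per_km2")
fit0 <- fit_unisecr(model0, start = c(D = 0.32, sigma = 1248))
coef(fit0)[["D"]]                       # 0.52 groups/km2
fit0$estimates$cv[1]                    # CV 62%
```

The point estimate drifts to 0.52 with a CV of 62%: with only seven
possible capture histories on three co-linear posts, the capture histories
alone barely pin down the detection scale, and the bearings more than
halve the density CV. Where each animal probably was:

```r
post <- location_posterior(fit, animals = 1)
post
#> Location posterior for 1 animal(s) over 6885 mask cells
#>   animal 1: mode (1750, 750)  mean (1866, 924)
probability_contours(post, c(0.5, 0.9))$cell_counts
#> 50% 90%
#>   5  19
```

`run_study()` repeats simulate-and-fit over many replicates with paired
random numbers to compare estimator properties across model variants, and
`design_frog()` / `design_whale()` provide microphone-array
(signal strength + time of arrival) and double-observer
(distance measurement error) designs. Surveys stored as CSV files are
read with `read_bundle()`; a thin command-line wrapper for fitting,
simulation and location estimation is installed under `inst/cli/`.

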