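# Shared fixtures and independent oracle helpers, built in code.

# Small in-line array (gibbon-like geometry scaled down where noted).
line_layout <- function(K = 3, spacing = 500, type = "proximity_binary",
                        S = 1L) {
  survey_layout(detector_array((seq_len(K) - 1) * spacing, rep(0, K),
                               type = type), S)
}

# All nonzero binary capture histories for K detectors, S occasions.
enumerate_histories <- function(K, S) {
  g <- expand.grid(rep(list(0:1), K * S))
  g <- as.matrix(g[rowSums(g) > 0, , drop = FALSE])
  lapply(seq_len(nrow(g)), function(i) array(g[i, ], c(1, K, S)))
}

# All nonzero multi-catch histories: per occasion, either no capture (0) or
# capture at one of the K traps (1..K).
enumerate_multicatch <- function(K, S) {
  g <- expand.grid(rep(list(0:K), S))
  g <- as.matrix(g[rowSums(g) > 0, , drop = FALSE])
  lapply(seq_len(nrow(g)), function(i) {
    om <- array(0L, c(1, K, S))
    for (s in seq_len(S)) if (g[i, s] > 0) om[1, g[i, s], s] <- 1L
    om
  })
}

# First-principles probability of a binary proximity capture history given
# location, conditional on detection: independent Bernoulli cells divided by
# the inclusion probability. Deliberately written without package internals.
oracle_binary_history_prob <- function(om, p_k, S) {
  num <- 1
  for (s in seq_len(S)) {
    num <- num * prod(p_k^om[1, , s] * (1 - p_k)^(1 - om[1, , s]))
  }
  pdot_occ <- 1 - prod(1 - p_k)
  num / (1 - (1 - pdot_occ)^S)
}

# Frog-like array with half-normal detection + TOA (used for recovery
# studies of the arrival-time model); density calibrated to the target
# expected sample size.
toa_design <- function(target_n = 345, sigma = 8, sigma_toa = 0.002,
                       buffer = 30, spacing = 2.5) {
  detectors <- detector_array(c(0, 5, 10, 0, 5, 10), c(0, 0, 0, 6, 6, 6))
  layout <- survey_layout(detectors, 1L, durations = 1800)
  mask <- build_mask(detectors, buffer = buffer, spacing = spacing)
  detection <- detfn_halfnormal(sigma = sigma)
  pars <- c(D = 1, sigma = sigma, sigma_toa = sigma_toa, slope_toa = 1 / 330)
  eff <- sum(p_dot_total(mask, detection, layout, pars)) *
    attr(mask, "cell_area") * 1e-4
  pars[["D"]] <- target_n / eff
  list(name = "toa", layout = layout, mask = mask, detection = detection,
       observation = list(obs_toa(sigma_toa = sigma_toa, sound_speed = 330)),
       pars = pars, D_units = "per_ha", n_sessions = 1L)
}

# A small simulated survey with bearings, handy for likelihood and posterior
# tests: single session, modest mask.
small_bearing_survey <- function(seed = 5, D = 30, sigma = 400, kappa = 20,
                                 buffer = 1570, spacing = 200) {
  set.seed(seed)
  layout <- line_layout(K = 3, spacing = 500)
  mask <- build_mask(layout$detectors, buffer, spacing)
  detection <- detfn_halfnormal(sigma = sigma)
  pars <- c(D = D, sigma = sigma, kappa = kappa)
  design <- list(layout = layout, mask = mask, detection = detection,
                 observation = list(obs_bearing(kappa)), pars = pars,
                 D_units = "per_km2", n_sessions = 1L)
  dat <- sim_survey(design)
  c(design, list(data = dat))
}
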