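#' Supplementary observation models
#'
#' Constructors for the models of the noisy location observations that can
#' accompany capture histories. Values supplied here are starting values for
#' fitting and truth for simulation.
#'
#' * `obs_bearing()`: estimated bearings from detector to animal, von Mises
#'   observation error with concentration `kappa` centred on the true
#'   bearing (bearings are assumed unbiased).
#' * `obs_toa()`: times of arrival of a sound at the detectors. Arrival-time
#'   error is Gaussian with standard deviation `sigma_toa` (seconds); the
#'   propagation slope is `1 / sound_speed` (seconds per metre), fixed by
#'   default and estimable with `estimate_slope = TRUE`. The unknown emission
#'   times are incidental parameters, eliminated by conditioning on the mean
#'   arrival time, so only sounds detected at two or more detectors carry
#'   timing information.
#' * `obs_distance()`: estimated detector-to-animal distances with unbiased
#'   gamma errors of shape `alpha` (error CV `1/sqrt(alpha)`);
#'   `per_detector = TRUE` gives each detector/observer its own shape.
#' * `obs_exact()`: locations observed without error (conventional DS/MRDS);
#'   the marginal integral over location is replaced by evaluation at the
#'   observed location.
#'
#' Received signal strengths are specified through [detfn_ss()], which
#' defines both the detection process (threshold exceedance) and the
#' observation density (normal truncated at the cutoff) with shared
#' parameters.
#'
#' @param kappa von Mises concentration, `> 0` (`0` is the uniform limit).
#' @param sigma_toa arrival-time error SD in seconds, `> 0`.
#' @param sound_speed speed of sound in metres per second.
#' @param estimate_slope logical; estimate the propagation slope rather than
#'   fixing it at `1 / sound_speed`?
#' @param alpha gamma shape of the distance-estimation error, `> 0`.
#' @param per_detector logical; detector-specific `alpha`?
#' @return An object of class `unisecr_obs`.
#' @name obsmodels
NULL

new_obs <- function(kind, start, links, extra = list()) {
  structure(c(list(kind = kind, start = start, links = links), extra),
            class = "unisecr_obs")
}

#' @rdname obsmodels
#' @export
obs_bearing <- function(kappa = 10) {
  if (kappa < 0) stop("kappa must be >= 0")
  new_obs("bearing", c(kappa = kappa), c(kappa = "log"))
}

#' @rdname obsmodels
#' @export
obs_toa <- function(sigma_toa = 0.002, sound_speed = 330,
                    estimate_slope = FALSE) {
  if (sigma_toa <= 0) stop("sigma_toa must be > 0")
  new_obs("toa",
          c(sigma_toa = sigma_toa, slope_toa = 1 / sound_speed),
          c(sigma_toa = "log", slope_toa = "identity"),
          extra = list(estimate_slope = estimate_slope))
}

#' @rdname obsmodels
#' @export
obs_distance <- function(alpha = 10, per_detector = FALSE) {
  if (alpha <= 0) stop("alpha must be > 0")
  new_obs("distance", c(alpha = alpha), c(alpha = "log"),
          extra = list(per_detector = per_detector))
}

#' @rdname obsmodels
#' @export
obs_exact <- function() {
  new_obs("exact", stats::setNames(numeric(0), character(0)),
          stats::setNames(character(0), character(0)))
}

#' @export
print.unisecr_obs <- function(x, ...) {
  cat("Observation model:", x$kind, "\n")
  if (length(x$start)) print(x$start)
  invisible(x)
}

obs_par_info <- function(obs, K) {
  nm <- names(obs$start)
  if (obs$kind == "distance" && isTRUE(obs$per_detector)) {
    return(data.frame(name = paste("alpha", seq_len(K), sep = "."),
                      link = "log", start = unname(obs$start[["alpha"]]),
                      stringsAsFactors = FALSE))
  }
  data.frame(name = nm, link = unname(obs$links[nm]),
             start = unname(obs$start[nm]),
             stringsAsFactors = FALSE)
}

log_bessel_I0 <- function(kappa) {
  # log I0(kappa), stable for large kappa via the exponentially scaled form.
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

#' Von Mises bearing log-likelihood
#'
#' Log-density of observed bearings at the detectors that detected an
#' animal located at `x`: for each observation,
#' `kappa * cos(y_k - b_k(x)) - log(2 * pi * I0(kappa))`, where `b_k(x)` is
#' the true bearing from detector `k` to `x` and `I0` the modified Bessel
#' function of order 0. `kappa = 0` gives the circular-uniform density.
#'
#' @param y numeric vector of length `K`: observed bearings in radians, `NA`
#'   at detectors without an observation.
#' @param x a single location (length-2 numeric).
#' @param detectors a [detector_array()].
#' @param kappa von Mises concentration (`>= 0`).
#' @param omega optional 0/1 detection indicators of length `K`; an
#'   observation at a non-detecting detector is an error.
#' @return The summed log-density over the observed bearings.
#' @export
bearing_loglik <- function(y, x, detectors, kappa, omega = NULL) {
  obs <- check_obs_alignment(y, omega, nrow(detectors))
  if (kappa < 0) stop("kappa must be >= 0")
  if (!any(obs)) return(0)
  b <- bearings(detectors, x)[obs, 1]
  sum(kappa * cos(y[obs] - b) - log(2 * pi) - log_bessel_I0(kappa))
}

#' Time-of-arrival log-likelihood
#'
#' Log-density of the arrival times of one sound at the `m` detectors that
#' detected it, conditional on the mean arrival time (which eliminates the
#' unknown emission time). With `delta_k(x) = y_k - slope * d_k(x)` and
#' `dbar` their mean:
#' `((1 - m)/2) * log(2 * pi * sigma_toa^2) - sum((delta - dbar)^2) / (2 * sigma_toa^2)`.
#' A sound heard at a single detector contributes 0: one arrival time
#' carries no location information once the emission time is unknown.
#'
#' @param y numeric vector of length `K`: arrival times in seconds, `NA` at
#'   detectors that did not detect the sound.
#' @inheritParams bearing_loglik
#' @param sigma_toa arrival-time error SD in seconds (`> 0`).
#' @param slope propagation slope in seconds per metre (reciprocal of the
#'   sound speed).
#' @return The log-density (a scalar; 0 when `m = 1`).
#' @export
toa_loglik <- function(y, x, detectors, sigma_toa, slope = 1 / 330,
                       omega = NULL) {
  obs <- check_obs_alignment(y, omega, nrow(detectors))
  if (sigma_toa <= 0) stop("sigma_toa must be > 0")
  m <- sum(obs)
  if (m <= 1L) return(0)
  d <- distances(detectors, x)[obs, 1]
  delta <- y[obs] - slope * d
  (1 - m) / 2 * log(2 * pi * sigma_toa^2) -
    sum((delta - mean(delta))^2) / (2 * sigma_toa^2)
}

#' Signal-strength log-likelihood
#'
#' Log-density of received signal strengths at the detectors that detected a
#' sound from `x`, under the threshold-detection model: each observation is
#' normal with mean `mu(d_k(x))` and SD `sigma_s`, truncated below at the
#' cutoff `c` (values below `c` were filtered out, so could not have been
#' observed):
#' `log N(y_k; mu(d_k), sigma_s^2) - log(1 - F_k(c))`.
#'
#' @param y numeric vector of length `K`: received strengths in dB, `NA` at
#'   non-detections; observed values must be `>= cutoff`.
#' @inheritParams bearing_loglik
#' @inheritParams ss_threshold_p
#' @return The summed log-density.
#' @export
ss_loglik <- function(y, x, detectors, beta0, beta1, sigma_s, cutoff,
                      link = c("identity", "log"), omega = NULL) {
  link <- match.arg(link)
  obs <- check_obs_alignment(y, omega, nrow(detectors))
  if (sigma_s <= 0) stop("sigma_s must be > 0")
  if (!any(obs)) return(0)
  if (any(y[obs] < cutoff)) {
    stop("received strength below the cutoff is inconsistent with detection")
  }
  d <- distances(detectors, x)[obs, 1]
  mu <- ss_mean(d, beta0, beta1, link)
  sum(stats::dnorm(y[obs], mu, sigma_s, log = TRUE) -
        stats::pnorm(cutoff, mu, sigma_s, lower.tail = FALSE, log.p = TRUE))
}

#' Estimated-distance log-likelihood
#'
#' Log-density of estimated distances from the detecting observers to an
#' animal at `x`, under unbiased gamma measurement error: each estimate has
#' a gamma density with shape `alpha` and mean `d_k(x)` (rate
#' `alpha / d_k(x)`), so the error CV is `1 / sqrt(alpha)`.
#'
#' @param y numeric vector of length `K`: estimated distances in metres
#'   (`> 0`), `NA` at non-detections.
#' @inheritParams bearing_loglik
#' @param alpha gamma shape (`> 0`); scalar or per-detector vector of
#'   length `K`.
#' @return The summed log-density.
#' @export
distance_loglik <- function(y, x, detectors, alpha, omega = NULL) {
  obs <- check_obs_alignment(y, omega, nrow(detectors))
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (!any(obs)) return(0)
  if (any(y[obs] <= 0)) stop("estimated distances must be > 0")
  d <- distances(detectors, x)[obs, 1]
  a <- rep_len(alpha, nrow(detectors))[obs]
  sum(stats::dgamma(y[obs], shape = a, rate = a / d, log = TRUE))
}

#' Joint supplementary log-likelihood at a point
#'
#' Sum of the per-kind supplementary log-likelihoods for one animal at
#' location `x`, under conditional independence of the observation types
#' given location. Parameter-free multiplicative constants are omitted
#' throughout. An `obs_exact()` component contributes 0 and requires
#' `y` to equal `x` (location observed without error).
#'
#' @param obs named list of per-kind observation vectors (names among
#'   `"bearing"`, `"toa"`, `"ss"`, `"distance"`, `"exact"`), each of length
#'   `K` with `NA` at non-detections (`"exact"`: a length-2 location).
#' @param x a single location (length-2 numeric).
#' @param models list of `unisecr_obs` / [detfn_ss()] models, pairwise of
#'   distinct kinds.
#' @param detectors a [detector_array()].
#' @param omega optional 0/1 detection indicators of length `K`.
#' @return The summed log-density.
#' @export
joint_supplementary_loglik <- function(obs, x, models, detectors,
                                       omega = NULL) {
  kinds <- vapply(models, obs_kind, character(1))
  if (anyDuplicated(kinds)) stop("duplicate observation kinds in model list")
  total <- 0
  for (m in models) {
    kind <- obs_kind(m)
    y <- obs[[kind]]
    if (is.null(y)) next
    total <- total + switch(kind,
      bearing = bearing_loglik(y, x, detectors, m$start[["kappa"]], omega),
      toa = toa_loglik(y, x, detectors, m$start[["sigma_toa"]],
                       m$start[["slope_toa"]], omega),
      ss = ss_loglik(y, x, detectors, m$start[["beta0_ss"]],
                     m$start[["beta1_ss"]], m$start[["sigma_ss"]],
                     m$cutoff, m$link, omega),
      distance = distance_loglik(y, x, detectors, m$start[["alpha"]], omega),
      exact = if (isTRUE(all.equal(as.numeric(y), as.numeric(x),
                                   tolerance = 1e-8))) 0 else -Inf
    )
  }
  total
}

obs_kind <- function(model) {
  if (inherits(model, "unisecr_detfn")) {
    if (model$form != "ss_threshold") {
      stop("only the signal-strength detection model doubles as an ",
           "observation model")
    }
    return("ss")
  }
  model$kind
}

check_obs_alignment <- function(y, omega, K) {
  if (length(y) != K) stop("observation vector must have one slot per detector")
  obs <- !is.na(y)
  if (!is.null(omega) && any(obs & omega == 0)) {
    stop("observation recorded at a detector that did not detect the animal")
  }
  obs
}
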