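#' Capture-history data
#'
#' Holds the detection indicators (or counts) `omega[i, k, s]` for detected
#' animal (or cue) `i` at detector `k` on occasion `s`. Only detected animals
#' are recorded: every animal must have at least one detection.
#'
#' @param omega an `n x K x S` array of 0/1 indicators (binary proximity,
#'   multi-catch) or nonnegative integer counts (count proximity). An
#'   `n x K` matrix is promoted to a single occasion.
#' @param ids optional animal identifiers (row names).
#' @return An object of class `capture_data` with elements `omega`, `n`,
#'   `K`, `S` and `ids`.
#' @export
capture_data <- function(omega, ids = NULL) {
  if (length(dim(omega)) == 2L) omega <- array(omega, c(dim(omega), 1L))
  if (length(dim(omega)) != 3L) stop("omega must be an n x K x S array")
  if (any(omega < 0) || any(omega != round(omega))) {
    stop("omega entries must be nonnegative integers")
  }
  n <- dim(omega)[1L]
  if (n > 0 && any(apply(omega, 1, sum) == 0)) {
    stop("every recorded animal must have at least one detection")
  }
  ids <- ids %||% if (n > 0) seq_len(n) else integer()
  structure(list(omega = omega, n = n, K = dim(omega)[2L], S = dim(omega)[3L],
                 ids = ids),
            class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  cat("Capture data:", x$n, "animals,", x$K, "detectors,", x$S,
      "occasion(s),", sum(x$omega > 0), "detections\n")
  invisible(x)
}

#' Log-probability of a single-occasion capture history given location
#'
#' The probability of the occasion-`s` history `omega_s`, conditional on the
#' animal being detected on that occasion, for an animal located at `x`:
#'
#' * binary proximity: `prod_k B(omega_k, p_k(x)) / p.s(x)`;
#' * multi-catch: multinomial with index 1 and relative-hazard probabilities
#'   `r_k(x) = h_k(x) / sum_k h_k(x)`, with `h_k = -log(1 - p_k)`;
#' * count proximity: `prod_k Po(omega_k, lambda0 * p_k(x)) / p.s(x)` with
#'   the occasion inclusion probability `p.s = 1 - exp(-lambda0 sum_k p_k)`
#'   implied by the Poisson model.
#'
#' @param omega_s integer vector of length `K` (the occasion's history,
#'   with at least one detection).
#' @param x a single location (length-2 numeric).
#' @param model a `unisecr_detfn`.
#' @param detectors a [detector_array()]; its type selects the form.
#' @param pars optional named parameter vector overriding `model$start`.
#' @param lambda0 Poisson rate multiplier for count detectors.
#' @return The log-probability (a scalar).
#' @export
logP_history_given_x <- function(omega_s, x, model, detectors, pars = NULL,
                                 lambda0 = 1) {
  if (sum(omega_s) == 0) stop("omega_s must contain a detection (w.i.s = 1)")
  p <- drop(det_prob_matrix(model, pars %||% model$start,
                            distances(detectors, x)))
  type <- detector_type(detectors)
  if (type == "multicatch") {
    if (sum(omega_s > 0) > 1L) {
      stop("multi-catch traps cannot detect one animal at two detectors in ",
           "one occasion")
    }
    h <- -log1p(-p)
    return(log(h[which(omega_s > 0)]) - log(sum(h)))
  }
  if (type == "proximity_count") {
    log_ps <- log(-expm1(-lambda0 * sum(p)))
    return(sum(stats::dpois(omega_s, lambda0 * p, log = TRUE)) - log_ps)
  }
  log_ps <- log(-expm1(sum(log1p(-p))))
  sum(stats::dbinom(omega_s, 1, p, log = TRUE)) - log_ps
}

#' Log-probability of all capture histories given animal locations
#'
#' The capture-history likelihood `P(Omega | X)` over all animals and
#' occasions: for animal `i` at `x_i`,
#' `prod_s B(w.is, p.s(x_i)) Pr(w_is | w.is = 1)^{w.is} / p.(x_i)`,
#' where `p.(x)` is the overall inclusion probability. This is the direct
#' (per-animal loop) evaluation used as a readable reference and for small
#' problems; model fitting uses an equivalent vectorised path.
#'
#' @param capture a [capture_data()].
#' @param X an `n x 2` matrix of animal locations.
#' @param model a `unisecr_detfn`.
#' @param layout a [survey_layout()].
#' @inheritParams logP_history_given_x
#' @return The total log-probability. Animals at locations with zero
#'   inclusion probability contribute `-Inf` (with a warning).
#' @export
logP_Omega_given_X <- function(capture, X, model, layout, pars = NULL,
                               lambda0 = 1) {
  X <- as_points(X)
  if (nrow(X) != capture$n) stop("need one location per detected animal")
  if (capture$n == 0L) return(0)
  pars <- pars %||% model$start
  detectors <- layout$detectors
  S <- layout$n_occasions
  if (capture$S != S) stop("capture data and layout disagree on occasions")
  total <- 0
  for (i in seq_len(capture$n)) {
    x <- X[i, ]
    ps <- p_dot_occasion(x, model, detectors, pars, lambda0)
    pdot <- -expm1(S * log1p(-ps))
    if (pdot <= 0) {
      warning("animal ", capture$ids[i], ": zero inclusion probability at its location")
      return(-Inf)
    }
    li <- -log(pdot)
    for (s in seq_len(S)) {
      w <- capture$omega[i, , s]
      if (sum(w) > 0) {
        li <- li + log(ps) +
          logP_history_given_x(w, x, model, detectors, pars, lambda0)
      } else {
        li <- li + log1p(-ps)
      }
    }
    total <- total + li
  }
  total
}
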