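#' Half-normal detection probability
#'
#' `p(d) = exp(-d^2 / (2 * scale^2))`: certain detection at distance zero,
#' Gaussian-shaped decay with range governed by `scale` (metres).
#'
#' @param d distance(s) in metres, `>= 0`.
#' @param scale half-normal scale parameter in metres, `> 0`.
#' @return Detection probabilities in `[0, 1]`.
#' @examples
#' halfnormal_p(0, 500)        # 1
#' halfnormal_p(500, 500)      # exp(-1/2)
#' @export
halfnormal_p <- function(d, scale) {
  if (any(!is.finite(scale)) || any(scale <= 0)) stop("scale must be > 0")
  exp(-d^2 / (2 * scale^2))
}

#' Half-normal detection with estimable intercept
#'
#' `p(d) = logit^{-1}(g0_logit) * exp(-d^2 / (2 * scale^2))`: a half-normal
#' detection function whose value at distance zero, `g(0)`, may be below 1
#' (as in mark-recapture distance sampling, where duplicate detections by two
#' observers identify `g(0)`).
#'
#' @inheritParams halfnormal_p
#' @param g0_logit intercept on the logit scale; `logit^{-1}(g0_logit)` is
#'   the detection probability at distance zero.
#' @return Detection probabilities in `[0, 1]`.
#' @export
halfnormal_g0_p <- function(d, scale, g0_logit) {
  if (any(!is.finite(scale)) || any(scale <= 0)) stop("scale must be > 0")
  stats::plogis(g0_logit) * exp(-d^2 / (2 * scale^2))
}

#' Signal-strength threshold detection probability
#'
#' For acoustic surveys in which received signals weaker than a cutoff `c`
#' are filtered out, detection is the event that the received signal strength
#' exceeds `c`. With expected received strength `mu(d) = beta0 + beta1 * d`
#' (identity link) or `exp(beta0 + beta1 * d)` (log link) and Gaussian
#' receive error with standard deviation `sigma_s`,
#' `p(d) = 1 - Phi((c - mu(d)) / sigma_s)`.
#'
#' @param d distance(s) in metres.
#' @param beta0 source-level intercept (dB).
#' @param beta1 propagation-loss slope (dB per metre; usually negative).
#' @param sigma_s receive-error standard deviation (dB), `> 0`.
#' @param cutoff detection threshold `c` (dB).
#' @param link `"identity"` or `"log"` link for the expected strength.
#' @return Detection probabilities in `[0, 1]`.
#' @export
ss_threshold_p <- function(d, beta0, beta1, sigma_s, cutoff,
                           link = c("identity", "log")) {
  link <- match.arg(link)
  if (any(!is.finite(sigma_s)) || any(sigma_s <= 0)) stop("sigma_s must be > 0")
  mu <- ss_mean(d, beta0, beta1, link)
  stats::pnorm(cutoff, mean = mu, sd = sigma_s, lower.tail = FALSE)
}

ss_mean <- function(d, beta0, beta1, link) {
  eta <- beta0 + beta1 * d
  if (link == "log") exp(eta) else eta
}

# ---- detection model objects -------------------------------------------------

new_detfn <- function(form, start, links, fixed = character(),
                      per_detector = FALSE, extra = list()) {
  structure(c(list(form = form, start = start, links = links, fixed = fixed,
                   per_detector = per_detector), extra),
            class = "unisecr_detfn")
}

#' Detection-function model specifications
#'
#' Constructors for the detection sub-model handed to [fit_unisecr()] and the
#' simulator. Supplied parameter values are used as starting values (truth,
#' for simulation); any of them can be fixed via the `fixed` argument of
#' [fit_unisecr()].
#'
#' * `detfn_halfnormal()`: half-normal with `g(0) = 1` ([halfnormal_p()]).
#' * `detfn_halfnormal_g0()`: half-normal with estimable `g(0)`
#'   ([halfnormal_g0_p()]); `per_detector = TRUE` gives every detector its own
#'   `sigma` and `g0` (needed when detectors differ greatly in efficiency,
#'   e.g. two aerial observers).
#' * `detfn_hazard_halfnormal()`: hazard half-normal
#'   `p(d) = 1 - exp(-lambda0 * exp(-d^2/(2 sigma^2)))`.
#' * `detfn_ss()`: signal-strength threshold detection
#'   ([ss_threshold_p()]). When this form is used, detection *is* threshold
#'   exceedance and the received strengths double as supplementary data with
#'   the same parameters; it cannot be combined with an independent
#'   distance-based detection function.
#'
#' @param sigma half-normal scale (metres).
#' @param g0 detection probability at distance zero, in `(0, 1)`.
#' @param per_detector logical; detector-specific parameters (suffixed
#'   `.1`, `.2`, ...)?
#' @param lambda0 hazard intercept (`> 0`).
#' @param beta0,beta1,sigma_s,cutoff,link signal-strength parameters, see
#'   [ss_threshold_p()].
#' @return An object of class `unisecr_detfn`.
#' @name detfn
NULL

#' @rdname detfn
#' @export
detfn_halfnormal <- function(sigma = NULL) {
  new_detfn("halfnormal", start = c(sigma = sigma %||% NA_real_),
            links = c(sigma = "log"))
}

#' @rdname detfn
#' @export
detfn_halfnormal_g0 <- function(sigma = NULL, g0 = 0.8, per_detector = FALSE) {
  new_detfn("halfnormal_g0",
            start = c(sigma = sigma %||% NA_real_, g0 = g0),
            links = c(sigma = "log", g0 = "logit"),
            per_detector = per_detector)
}

#' @rdname detfn
#' @export
detfn_hazard_halfnormal <- function(lambda0 = 1, sigma = NULL) {
  new_detfn("hazard_halfnormal",
            start = c(lambda0 = lambda0, sigma = sigma %||% NA_real_),
            links = c(lambda0 = "log", sigma = "log"))
}

#' @rdname detfn
#' @export
detfn_ss <- function(beta0, beta1, sigma_s, cutoff,
                     link = c("identity", "log")) {
  link <- match.arg(link)
  if (sigma_s <= 0) stop("sigma_s must be > 0")
  new_detfn("ss_threshold",
            start = c(beta0_ss = beta0, beta1_ss = beta1, sigma_ss = sigma_s),
            links = c(beta0_ss = "identity", beta1_ss = "identity",
                      sigma_ss = "log"),
            extra = list(cutoff = cutoff, link = link))
}

#' @export
print.unisecr_detfn <- function(x, ...) {
  cat("Detection function:", x$form,
      if (isTRUE(x$per_detector)) "(per-detector parameters)", "\n")
  print(x$start)
  invisible(x)
}

# Parameter table (names on the natural scale, links, starts) for a detection
# model on an array of K detectors.
det_par_info <- function(detfn, K) {
  nm <- names(detfn$start)
  if (isTRUE(detfn$per_detector)) {
    name <- as.vector(t(outer(nm, seq_len(K), paste, sep = ".")))
    link <- rep(unname(detfn$links[nm]), each = K)
    start <- rep(unname(detfn$start[nm]), each = K)
  } else {
    name <- nm
    link <- unname(detfn$links[nm])
    start <- unname(detfn$start[nm])
  }
  data.frame(name = name, link = link, start = start,
             stringsAsFactors = FALSE)
}

# K x n matrix of per-detector, per-occasion detection probabilities at the
# given points, from a named natural-scale parameter vector.
det_prob_matrix <- function(detfn, pars, distmat) {
  K <- nrow(distmat)
  get <- function(base) {
    if (isTRUE(detfn$per_detector)) pars[paste(base, seq_len(K), sep = ".")]
    else rep_len(pars[[base]], K)
  }
  p <- switch(detfn$form,
    halfnormal = exp(-distmat^2 / (2 * get("sigma")^2)),
    halfnormal_g0 = stats::plogis(stats::qlogis(get("g0"))) *
      exp(-distmat^2 / (2 * get("sigma")^2)),
    hazard_halfnormal = -expm1(-get("lambda0") *
      exp(-distmat^2 / (2 * get("sigma")^2))),
    ss_threshold = {
      mu <- ss_mean(distmat, pars[["beta0_ss"]], pars[["beta1_ss"]], detfn$link)
      stats::pnorm(detfn$cutoff, mean = mu, sd = pars[["sigma_ss"]],
                   lower.tail = FALSE)
    },
    stop("unknown detection form: ", detfn$form)
  )
  pmin(pmax(p, 0), 1)
}

# ---- inclusion probabilities -------------------------------------------------

#' Per-occasion and overall inclusion probabilities
#'
#' `p_dot_occasion()` is the probability that an animal at `x` is detected by
#' at least one detector on one occasion,
#' `1 - prod_k (1 - p_k(x))`; `p_dot_total()` is the probability of detection
#' at least once during the whole survey, `1 - prod_s (1 - p.s(x))`. For
#' count detectors the occasion probability follows the Poisson detection
#' model, `1 - exp(-lambda0 * sum_k p_k(x))`.
#'
#' @param x point coordinates (`n x 2` matrix or length-2 vector).
#' @param model a `unisecr_detfn` specification with parameter values in its
#'   `start` slot, or a named parameter vector via `pars`.
#' @param detectors a [detector_array()].
#' @param pars optional named natural-scale parameter vector overriding the
#'   values stored in `model`.
#' @param lambda0 Poisson detection rate multiplier, used only for
#'   `proximity_count` detector arrays.
#' @return Vector of probabilities, one per point.
#' @export
p_dot_occasion <- function(x, model, detectors, pars = NULL, lambda0 = 1) {
  p <- det_prob_matrix(model, pars %||% model$start, distances(detectors, x))
  if (detector_type(detectors) == "proximity_count") {
    -expm1(-lambda0 * colSums(p))
  } else {
    -expm1(colSums(log1p(-p)))
  }
}

#' @rdname p_dot_occasion
#' @param layout a [survey_layout()]; its occasion count `S` enters as
#'   `1 - (1 - p.s)^S`.
#' @export
p_dot_total <- function(x, model, layout, pars = NULL, lambda0 = 1) {
  ps <- p_dot_occasion(x, model, layout$detectors, pars, lambda0)
  -expm1(layout$n_occasions * log1p(-ps))
}
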