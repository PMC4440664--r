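# Generative model for surveys: animal point process, detection thinning,
# supplementary observation noise, and the replication driver for
# simulation studies.

#' Von Mises random deviates
#'
#' Samples angles from a von Mises distribution with mean direction `mu`
#' and concentration `kappa`, by the Best-Fisher rejection algorithm
#' (`kappa = 0` gives circular-uniform draws).
#'
#' @param n number of draws.
#' @param mu mean direction(s), radians.
#' @param kappa concentration (`>= 0`).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  mu <- rep_len(mu, n)
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    todo <- n - filled
    u1 <- stats::runif(todo); u2 <- stats::runif(todo); u3 <- stats::runif(todo)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nok <- sum(ok)
    if (nok > 0) {
      out[filled + seq_len(nok)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      filled <- filled + nok
    }
  }
  (mu + out) %% (2 * pi)
}

#' Simulate an animal population over the mask region
#'
#' Draws a homogeneous Poisson number of animals with rate
#' `D * area(region)` and places them uniformly over the rectangular region
#' represented by the mask (cell centres extended by half a cell), so the
#' simulation region coincides with the estimator's integration region.
#'
#' @param D density in `D_units`.
#' @param mask a [build_mask()] mask.
#' @param D_units density units.
#' @return An `N x 2` matrix of locations (possibly zero rows).
#' @export
sim_population <- function(D, mask, D_units = c("per_ha", "per_km2", "per_m2")) {
  D_units <- match.arg(D_units)
  area <- nrow(mask) * mask_cell_area(mask)
  N <- stats::rpois(1, D * d_unit_factor(D_units) * area)
  sp <- attr(mask, "spacing") / 2
  rx <- range(mask[, 1]) + c(-sp, sp)
  ry <- range(mask[, 2]) + c(-sp, sp)
  cbind(x = stats::runif(N, rx[1], rx[2]), y = stats::runif(N, ry[1], ry[2]))
}

#' Simulate detections of a set of animals
#'
#' Applies the detection model independently per animal, detector and
#' occasion: Bernoulli for binary proximity detectors, Poisson counts for
#' count detectors, competing-hazard assignment to at most one trap per
#' occasion for multi-catch traps. For the signal-strength threshold model,
#' a latent received strength is drawn per animal-detector-occasion and
#' detection is the event that it reaches the cutoff; the strengths of
#' detections are retained as observations. Undetected animals are dropped.
#'
#' @param points `N x 2` matrix of animal locations.
#' @param layout a [survey_layout()].
#' @param detection a [detfn] specification.
#' @param pars optional named parameter overrides (defaults to the values in
#'   `detection`).
#' @param lambda0 Poisson rate multiplier for count detectors.
#' @return List with `capture` (a [capture_data()] for the detected
#'   animals), `locations` (their true locations), `detected` (row indices
#'   into `points`) and, for signal-strength detection, `ss` (the observed
#'   strengths, `n x K x S` with `NA` at non-detections).
#' @export
sim_detections <- function(points, layout, detection, pars = NULL,
                           lambda0 = 1) {
  points <- as_points(points)
  detectors <- layout$detectors
  type <- detector_type(detectors)
  K <- nrow(detectors); S <- layout$n_occasions; N <- nrow(points)
  pars <- pars %||% detection$start
  empty <- function() list(
    capture = capture_data(array(0L, c(0, K, S))),
    locations = points[0, , drop = FALSE], detected = integer(0))
  if (N == 0) return(empty())
  d <- distances(detectors, points)              # K x N
  ss_values <- NULL
  if (detection$form == "ss_threshold") {
    mu <- ss_mean(d, pars[["beta0_ss"]], pars[["beta1_ss"]], detection$link)
    ss_lat <- array(stats::rnorm(N * K * S, mean = rep(t(mu), S),
                                 sd = pars[["sigma_ss"]]), c(N, K, S))
    om <- (ss_lat >= detection$cutoff) * 1L
    ss_values <- ifelse(om == 1L, ss_lat, NA_real_)
  } else if (type == "proximity_count") {
    p <- det_prob_matrix(detection, pars, d)
    om <- array(stats::rpois(N * K * S, lambda = rep(lambda0 * t(p), S)),
                c(N, K, S))
  } else if (type == "multicatch") {
    p <- det_prob_matrix(detection, pars, d)
    h <- -log1p(-pmin(p, 1 - 1e-12))             # K x N hazards
    hdot <- colSums(h)
    pocc <- -expm1(-hdot)
    om <- array(0L, c(N, K, S))
    for (s in seq_len(S)) {
      caught <- which(stats::runif(N) < pocc)
      for (i in caught) {
        om[i, sample.int(K, 1, prob = h[, i]), s] <- 1L
      }
    }
  } else {
    p <- det_prob_matrix(detection, pars, d)
    om <- array((stats::runif(N * K * S) < rep(t(p), S)) * 1L, c(N, K, S))
  }
  keep <- which(apply(om, 1, sum) > 0)
  if (length(keep) == 0) return(empty())
  out <- list(capture = capture_data(om[keep, , , drop = FALSE]),
              locations = points[keep, , drop = FALSE], detected = keep)
  if (!is.null(ss_values)) out$ss <- ss_values[keep, , , drop = FALSE]
  out
}

#' Simulate supplementary location observations
#'
#' Draws one observation per detection from the stated error models:
#' von Mises bearings about the true bearing, normal arrival times
#' `t0 + d / sound_speed + error` with the emission time `t0` uniform over
#' the occasion, and gamma-distributed distance estimates with mean equal to
#' the true distance. (Signal strengths are generated by [sim_detections()]
#' since they drive detection itself.)
#'
#' @param capture a [capture_data()] from [sim_detections()].
#' @param points true locations of the detected animals (`n x 2`).
#' @param observation list of [obsmodels] specifications.
#' @param layout the [survey_layout()].
#' @param pars optional named parameter overrides.
#' @return A [supplementary_data()] object (or `NULL` if no observation
#'   model is given).
#' @export
sim_observations <- function(capture, points, observation, layout,
                             pars = NULL) {
  if (length(observation) == 0L) return(NULL)
  points <- as_points(points)
  detectors <- layout$detectors
  n <- capture$n; K <- capture$K; S <- capture$S
  om <- capture$omega
  args <- list(capture = capture)
  d <- if (n > 0) distances(detectors, points) else matrix(0, K, 0)
  for (m in observation) {
    p0 <- pars %||% m$start
    if (m$kind == "bearing") {
      y <- array(NA_real_, c(n, K, S))
      if (n > 0) {
        b <- bearings(detectors, points)         # K x n
        idx <- which(om > 0, arr.ind = TRUE)
        if (nrow(idx)) {
          y[idx] <- rvonmises(nrow(idx), b[cbind(idx[, 2], idx[, 1])],
                              p0[["kappa"]])
        }
      }
      args$bearing <- y
    } else if (m$kind == "toa") {
      y <- array(NA_real_, c(n, K, S))
      if (n > 0) {
        dur <- layout$durations %||% rep(1800, S)
        for (s in seq_len(S)) {
          t0 <- stats::runif(n, 0, dur[s])
          idx <- which(om[, , s, drop = FALSE] > 0, arr.ind = TRUE)
          if (nrow(idx)) {
            y[cbind(idx[, 1], idx[, 2], s)] <-
              t0[idx[, 1]] + p0[["slope_toa"]] * d[cbind(idx[, 2], idx[, 1])] +
              stats::rnorm(nrow(idx), 0, p0[["sigma_toa"]])
          }
        }
      }
      args$toa <- y
    } else if (m$kind == "distance") {
      y <- array(NA_real_, c(n, K, S))
      if (n > 0) {
        idx <- which(om > 0, arr.ind = TRUE)
        if (nrow(idx)) {
          a <- if (isTRUE(m$per_detector)) {
            rep_len(p0[grep("^alpha", names(p0))], K)[idx[, 2]]
          } else p0[["alpha"]]
          dk <- d[cbind(idx[, 2], idx[, 1])]
          y[idx] <- stats::rgamma(nrow(idx), shape = a, rate = a / dk)
        }
      }
      args$distance <- y
    } else if (m$kind == "exact") {
      args$exact <- points
    }
  }
  do.call(supplementary_data, args)
}

#' Simulate a complete survey from a design
#'
#' Generates `n_sessions` independent sessions: a Poisson population over
#' the mask region, detection thinning, and supplementary observations.
#'
#' @param design a design list as returned by [design_gibbon()] and
#'   friends: components `layout`, `mask`, `detection`, `observation`,
#'   `pars` (named truth, density in `D_units`), `D_units`, `n_sessions`,
#'   and optionally `lambda0`.
#' @return List with per-session lists `capture`, `obs`, `locations`.
#' @export
sim_survey <- function(design) {
  ns <- design$n_sessions %||% 1L
  lam0 <- if ("lambda0" %in% names(design$pars)) design$pars[["lambda0"]]
          else design$lambda0 %||% 1
  capture <- obs <- locations <- vector("list", ns)
  for (j in seq_len(ns)) {
    pop <- sim_population(design$pars[["D"]], design$mask, design$D_units)
    det <- sim_detections(pop, design$layout, design$detection, design$pars,
                          lambda0 = lam0)
    o <- sim_observations(det$capture, det$locations,
                          design$observation %||% list(), design$layout,
                          design$pars)
    if (!is.null(det$ss)) {
      args <- list(capture = det$capture, ss = det$ss)
      if (!is.null(o)) args <- c(args, unclass(o)[names(o) != "ss"])
      o <- do.call(supplementary_data, args)
    }
    capture[[j]] <- det$capture; obs[[j]] <- o
    locations[[j]] <- det$locations
  }
  list(capture = capture, obs = obs, locations = locations)
}

#' Simulate surveys from a fitted model
#'
#' Parametric-bootstrap style simulation: surveys generated from the fitted
#' parameter values with the fitted model's geometry and observation
#' structure.
#'
#' @param object a `unisecr_fit`.
#' @param nsim number of replicate surveys.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` survey lists as from [sim_survey()].
#' @export
simulate.unisecr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  model <- object$model
  sess <- model$sessions[[1]]
  design <- list(layout = sess$layout, mask = sess$mask,
                 detection = model$detection,
                 observation = model$observation,
                 pars = object$pars, D_units = model$D_units,
                 n_sessions = length(model$sessions))
  lapply(seq_len(nsim), function(i) sim_survey(design))
}

#' Run a simulation study
#'
#' The replication driver for estimator-property studies: per replicate,
#' simulate one survey from the design's true parameters and fit every
#' model variant to the *same* simulated data (paired comparisons by common
#' random numbers; each replicate has its own RNG stream derived from the
#' master seed). Summaries are computed over converged replicates only.
#'
#' @param design a design list (see [sim_survey()]).
#' @param variants named list of model variants; each is a list with
#'   components `detection`, `observation` (default: the generating models),
#'   `fixed`, and optional `start`. `NULL` entries inherit from the design.
#' @param n_sims number of replicates.
#' @param seed master seed.
#' @param n_starts optimisation starts per fit (starts at the generating
#'   values, so 1 is usually adequate; increase for difficult likelihoods).
#' @param keep_fits retain the full fit objects (memory-heavy).
#' @return An object of class `study_result`: per-variant data frames of
#'   per-replicate estimates, and a `summary` data frame with the mean
#'   density estimate, percent bias, sampling SD, CV (SD / true density) and
#'   convergence-failure count. A variant with more than 20% failures is
#'   flagged unreliable.
#' @export
run_study <- function(design, variants = list(generating = list()),
                      n_sims = 100L, seed = 1L, n_starts = 1L,
                      keep_fits = FALSE) {
  stopifnot(n_sims >= 1L)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2^31 - 2, n_sims)
  if (is.null(names(variants))) {
    names(variants) <- paste0("variant", seq_along(variants))
  }
  res <- lapply(variants, function(v) vector("list", n_sims))
  fits <- if (keep_fits) lapply(variants, function(v) vector("list", n_sims))
  for (r in seq_len(n_sims)) {
    set.seed(rep_seeds[r])
    data <- sim_survey(design)
    for (vn in names(variants)) {
      v <- variants[[vn]]
      fit <- tryCatch({
        model <- unisecr_model(
          capture = data$capture, layout = design$layout, mask = design$mask,
          detection = v$detection %||% design$detection,
          observation = v$observation %||% design$observation %||% list(),
          obs = data$obs,
          D_units = design$D_units,
          count_model = design$count_model %||% "poisson", N = design$N)
        start <- v$start %||%
          design$pars[intersect(names(design$pars), model$par_table$name)]
        suppressWarnings(fit_unisecr(model, start = start,
                                     fixed = v$fixed, n_starts = n_starts,
                                     seed = rep_seeds[r], hessian = FALSE))
      }, error = function(e) NULL)
      if (is.null(fit)) {
        res[[vn]][[r]] <- list(D = NA_real_, converged = FALSE, n = NA_real_)
      } else {
        res[[vn]][[r]] <- list(D = unname(coef(fit)[["D"]]),
                               converged = fit$convergence$converged,
                               n = fit$n)
        if (keep_fits) fits[[vn]][[r]] <- fit
      }
    }
  }
  D_true <- design$pars[["D"]]
  per_variant <- lapply(res, function(rr) {
    data.frame(D = vapply(rr, `[[`, 0, "D"),
               converged = vapply(rr, `[[`, TRUE, "converged"),
               n = vapply(rr, `[[`, 0, "n"))
  })
  summ <- do.call(rbind, lapply(names(per_variant), function(vn) {
    df <- per_variant[[vn]]
    ok <- df$converged & is.finite(df$D)
    D <- df$D[ok]
    data.frame(variant = vn, n_sims = n_sims, n_used = sum(ok),
               n_fail = sum(!ok), mean_D = mean(D),
               pct_bias = 100 * mean((D - D_true) / D_true),
               sd_D = stats::sd(D), cv = stats::sd(D) / D_true,
               mean_n = mean(df$n[ok]),
               unreliable = mean(!ok) > 0.2,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_variant = per_variant, summary = summ,
                 D_true = D_true, seed = seed, n_sims = n_sims,
                 fits = fits),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation study:", x$n_sims, "replicates, true D =", x$D_true,
      "(seed", paste0(x$seed, ")\n"))
  s <- x$summary
  num <- c("mean_D", "pct_bias", "sd_D", "cv", "mean_n")
  s[num] <- lapply(s[num], signif, 4)
  print(s, row.names = FALSE)
  if (any(x$summary$unreliable)) {
    cat("NOTE: variants flagged unreliable had >20% convergence failures\n")
  }
  invisible(x)
}
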