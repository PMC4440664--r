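# Likelihood engine. All evaluation is in log space, vectorised over the
# mask via dense matrix products (animals x detectors %*% detectors x mask).

P_EPS_HI <- 1e-12    # keep 1 - p away from 0 so log1p(-p) stays finite
P_EPS_LO <- 1e-300   # keep p away from 0 so 0 * log(p) cannot give NaN

# Per-animal log-marginals below this are numerically indistinguishable from
# a zero integrand (the animal's history is impossible everywhere on the
# mask) and are reported as -Inf by the exported likelihood functions. The
# optimiser works with the raw finite values, which keep the objective
# smooth near impossible regions.
LOG_ZERO <- -600

clamp_p <- function(p) pmin(pmax(p, P_EPS_LO), 1 - P_EPS_HI)

# Per-session parameter-dependent pieces shared by several outputs.
session_kernel <- function(sess, model, pars) {
  p <- clamp_p(det_prob_matrix(model$detection, pars, sess$dist))
  logp <- log(p)
  logq <- log1p(-p)
  if (sess$type == "proximity_count") {
    lam0 <- pars[["lambda0"]]
    log_1m_pocc <- -lam0 * colSums(p)
  } else {
    log_1m_pocc <- colSums(logq)
  }
  log_1m_ptot <- sess$S * log_1m_pocc
  pdot_tot <- -expm1(log_1m_ptot)
  list(p = p, logp = logp, logq = logq, log_1m_pocc = log_1m_pocc,
       pdot_tot = pdot_tot, sum_pdot = sum(pdot_tot))
}

# Group x M matrix of log P(omega_i | x) over mask points.
log_num_matrix <- function(sess, ker, pars) {
  G <- nrow(sess$Agrp); M <- sess$M
  if (G == 0L) return(matrix(0, 0, M))
  if (sess$type == "proximity_binary") {
    out <- sess$Agrp %*% (ker$logp - ker$logq)
    out <- out + rep(sess$S * colSums(ker$logq), each = G)
  } else if (sess$type == "proximity_count") {
    lam0 <- pars[["lambda0"]]
    out <- sess$Agrp %*% ker$logp
    out <- out + rowSums(sess$Agrp) * log(lam0) - sess$lgam
    out <- out + rep(-sess$S * lam0 * colSums(ker$p), each = G)
  } else {  # multicatch
    h <- -ker$logq
    logh <- log(pmax(h, 1e-300))
    loghsum <- log(colSums(h))
    log_pocc <- log(-expm1(ker$log_1m_pocc))
    out <- sess$Agrp %*% logh +
      outer(sess$ndetgrp, log_pocc - loghsum) +
      outer(sess$S - sess$ndetgrp, ker$log_1m_pocc)
  }
  out
}

# n x M matrix of supplementary log-densities over mask points (0 if none).
log_supp_matrix <- function(sess, model, pars) {
  n <- sess$n; M <- sess$M
  if (length(sess$obs) == 0L) return(NULL)
  out <- matrix(0, n, M)
  ob <- sess$obs
  if (!is.null(ob$bearing)) {
    kappa <- pars[["kappa"]]
    bm <- sess$bear_mask
    out <- out + kappa * (ob$bearing$C %*% cos(bm) + ob$bearing$S %*% sin(bm))
    out <- out - ob$bearing$m * (log(2 * pi) + log_bessel_I0(kappa))
  }
  if (!is.null(ob$toa)) {
    st <- pars[["sigma_toa"]]; b1 <- pars[["slope_toa"]]
    t <- ob$toa
    d <- sess$dist; d2 <- d^2
    sum_d2 <- t$syy - 2 * b1 * (t$Wy %*% d) + b1^2 * (t$W %*% d2)
    sdelta <- t$sy - b1 * (t$W %*% d)
    ssq <- sum_d2 - sdelta^2 / t$m          # sum (delta - deltabar)^2, rows x M
    term <- (1 - t$m) / 2 * log(2 * pi * st^2) - ssq / (2 * st^2)
    agg <- rowsum(term, t$animal)
    out[as.integer(rownames(agg)), ] <- out[as.integer(rownames(agg)), ] + agg
  }
  if (!is.null(ob$ss)) {
    det <- model$detection
    mu <- ss_mean(sess$dist, pars[["beta0_ss"]], pars[["beta1_ss"]], det$link)
    sig <- pars[["sigma_ss"]]
    logtail <- stats::pnorm(det$cutoff, mu, sig, lower.tail = FALSE,
                            log.p = TRUE)
    s <- ob$ss
    quad <- s$syy - 2 * (s$Wy %*% mu) + s$W %*% (mu^2)
    out <- out - s$m * (log(sig) + 0.5 * log(2 * pi)) - quad / (2 * sig^2) -
      s$W %*% logtail
  }
  if (!is.null(ob$distance)) {
    dd <- ob$distance
    d <- pmax(sess$dist, 1e-300)
    logd <- log(d); invd <- 1 / d
    if (any(startsWith(names(pars), "alpha."))) {
      for (k in seq_len(sess$K)) {
        a <- pars[[paste0("alpha.", k)]]
        out <- out + dd$W[, k] * (a * log(a) - lgamma(a)) +
          (a - 1) * dd$Wly[, k] -
          a * outer(dd$W[, k], logd[k, ]) - a * outer(dd$Wy[, k], invd[k, ])
      }
    } else {
      a <- pars[["alpha"]]
      out <- out + dd$m * (a * log(a) - lgamma(a)) + (a - 1) * dd$sly -
        a * (dd$W %*% logd) - a * (dd$Wy %*% invd)
    }
  }
  out
}

# Per-animal marginal log-likelihood contributions for one session:
# log int D(x) P(omega_i|x) f(Y_i|x) dx - log lambda. Returns the per-group
# values plus weights (groups collapse identical histories when there are no
# supplementary data).
session_animal_terms <- function(sess, model, pars) {
  ker <- session_kernel(sess, model, pars)
  log_eff <- log(ker$sum_pdot * sess$cell_area)   # log(lambda / D)
  if (!is.null(sess$exact)) {
    # DS/MRDS mode: evaluate the integrand at the observed locations.
    pex <- clamp_p(det_prob_matrix(model$detection, pars, sess$dist_exact))
    lpe <- log(pex); lqe <- log1p(-pex)
    if (sess$type != "proximity_binary") {
      stop("exact-location mode is implemented for binary proximity ",
           "detectors (DS/MRDS surveys)")
    }
    num <- rowSums(sess$A * t(lpe - lqe)) + sess$S * colSums(lqe)
    return(list(values = num - log_eff, weights = rep(1, sess$n), ker = ker))
  }
  L <- log_num_matrix(sess, ker, pars)
  supp <- log_supp_matrix(sess, model, pars)
  if (!is.null(supp)) L <- L + supp        # groups == animals when supp given
  vals <- row_logsumexp(L) + log(sess$cell_area) - log_eff
  list(values = vals, weights = sess$weights, ker = ker)
}

get_D_m2 <- function(model, pars) {
  unname(pars[["D"]]) * d_unit_factor(model$D_units)
}

#' Expected number of detections
#'
#' The rate `lambda = integral of D(x) * p.(x) dx`, evaluated by midpoint
#' quadrature over the habitat mask(s); summed across sessions.
#'
#' @param model a [unisecr_model()].
#' @param pars named natural-scale parameter vector (defaults to the model's
#'   starting values).
#' @return Expected detection count.
#' @export
lambda_rate <- function(model, pars = NULL) {
  pars <- complete_pars(model, pars)
  Dm2 <- get_D_m2(model, pars)
  sum(vapply(model$sessions, function(sess) {
    ker <- session_kernel(sess, model, pars)
    Dm2 * ker$sum_pdot * sess$cell_area
  }, numeric(1)))
}

#' Log-probability of the number of detections
#'
#' Poisson log-mass `Po(n; lambda)` under the point-process count model, or
#' binomial log-mass `Bin(n; N, pbar)` when the number of animals is a fixed
#' `N` (spread over the region implied by `N` and the density, so the mean
#' inclusion probability is `pbar = lambda / N`). The binomial model
#' converges to the Poisson one as `N` grows with density held fixed.
#'
#' @inheritParams lambda_rate
#' @param n detection count; defaults to the observed total.
#' @return Log-probability.
#' @export
log_Pn <- function(model, pars = NULL, n = NULL) {
  pars <- complete_pars(model, pars)
  n <- n %||% model$n_total
  lam <- lambda_rate(model, pars)
  if (model$count_model == "binomial") {
    if (n > model$N) stop("n cannot exceed N under the binomial count model")
    pbar <- min(lam / model$N, 1 - 1e-12)
    return(stats::dbinom(n, model$N, pbar, log = TRUE))
  }
  stats::dpois(n, lam, log = TRUE)
}

#' Marginal log-likelihood contribution of one animal
#'
#' The log of the animal's marginal density: its capture history and
#' supplementary observations integrated over the unknown location,
#' `log int f_x(x) P(omega_i | x) f(Y_i | x, omega_i) dx`, with
#' `f_x(x) = D(x) p.(x) / lambda` and the integral evaluated over the mask.
#'
#' @inheritParams lambda_rate
#' @param i animal index within the session.
#' @param session session index.
#' @return Log-density (scalar). `-Inf`, with a warning naming the animal,
#'   if the integrand vanishes everywhere on the mask.
#' @export
animal_marginal_loglik <- function(model, i, session = 1L, pars = NULL) {
  pars <- complete_pars(model, pars)
  sess <- model$sessions[[session]]
  if (i < 1 || i > sess$n) stop("no animal ", i, " in session ", session)
  terms <- session_animal_terms(sess, model, pars)
  val <- terms$values[sess$group_index[i]]
  if (!is.finite(val) || val < LOG_ZERO) {
    warning("animal ", sess$capture$ids[i],
            ": integrand is zero everywhere on the mask")
    val <- -Inf
  }
  val
}

#' Full marginal log-likelihood
#'
#' `log P(n) + sum_i log` (per-animal marginal), summed over sessions: the
#' likelihood of the detection count, capture histories and supplementary
#' location observations with animal locations integrated out.
#'
#' @inheritParams lambda_rate
#' @return Log-likelihood (scalar; `-Inf` if any animal's integrand
#'   vanishes).
#' @export
full_loglik <- function(model, pars = NULL) {
  full_loglik_raw(model, pars, zero_is_inf = TRUE)
}

# Raw objective (zero_is_inf = FALSE): no zero-integrand thresholding, used
# by the optimiser to keep the objective smooth near impossible regions.
full_loglik_raw <- function(model, pars = NULL, zero_is_inf = FALSE) {
  pars <- complete_pars(model, pars)
  Dm2 <- get_D_m2(model, pars)
  total <- 0
  lam_total <- 0
  for (sess in model$sessions) {
    terms <- session_animal_terms(sess, model, pars)
    if (zero_is_inf && length(terms$values) &&
        min(terms$values) < LOG_ZERO) {
      return(-Inf)
    }
    lam <- Dm2 * terms$ker$sum_pdot * sess$cell_area
    lam_total <- lam_total + lam
    if (model$count_model == "poisson") {
      total <- total + stats::dpois(sess$n, lam, log = TRUE)
    }
    total <- total + sum(terms$weights * terms$values)
    if (!is.finite(total)) return(-Inf)
  }
  if (model$count_model == "binomial") {
    pbar <- min(lam_total / model$N, 1 - 1e-12)
    total <- total + stats::dbinom(model$n_total, model$N, pbar, log = TRUE)
  }
  if (!is.finite(total)) return(-Inf)
  total
}

# Fill in a full named natural-scale parameter vector from the model's table,
# overridden by any user-supplied entries. NA starts are given heuristics.
complete_pars <- function(model, pars = NULL) {
  tab <- model$par_table
  out <- stats::setNames(tab$start, tab$name)
  if (!is.null(pars)) {
    unknown <- setdiff(names(pars), tab$name)
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    out[names(pars)] <- pars
  }
  if (anyNA(out)) out <- default_starts(model, out)
  out
}

default_starts <- function(model, pars) {
  sigma_names <- grep("^sigma(\\.[0-9]+)?$", names(pars), value = TRUE)
  need_sigma <- sigma_names[is.na(pars[sigma_names])]
  if (length(need_sigma)) {
    s0 <- mean(vapply(model$sessions, function(sess) {
      det <- sess$layout$detectors
      if (nrow(det) > 1) {
        dd <- distances(det, det)
        max(mean(dd[dd > 0]), attr(sess$mask, "buffer") / 4)
      } else attr(sess$mask, "buffer") / 3
    }, numeric(1)))
    pars[need_sigma] <- s0
  }
  if (is.na(pars[["D"]])) {
    tmp <- pars; tmp[["D"]] <- 1
    eff <- sum(vapply(model$sessions, function(sess) {
      session_kernel(sess, model, tmp)$sum_pdot * sess$cell_area
    }, numeric(1)))
    pars[["D"]] <- max(model$n_total, 1) / eff / d_unit_factor(model$D_units)
  }
  pars
}
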