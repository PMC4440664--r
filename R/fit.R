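#' Fit the unified SECR/DS model by maximum likelihood
#'
#' Maximises the marginal likelihood over density, detection and
#' observation-model parameters on a transformed scale (log for strictly
#' positive parameters, logit for `g0`, identity otherwise) with a
#' quasi-Newton optimiser and jittered restarts. Variances come from the
#' inverse of a central finite-difference Hessian at the optimum and are
#' carried to the natural scale by the delta method; Wald intervals are
#' formed on the transformed scale and back-transformed.
#'
#' @param model a [unisecr_model()], or a [capture_data()] if the remaining
#'   pieces are given via `...` (passed to [unisecr_model()]).
#' @param start optional named natural-scale starting values (density in the
#'   model's `D_units`); unspecified entries get data-driven defaults.
#' @param fixed named list/vector of parameters to hold fixed at the given
#'   values.
#' @param n_starts number of optimisation starts; starts after the first are
#'   jittered on the transformed scale (SD 0.25). The best converged
#'   optimum is reported.
#' @param seed integer seed controlling the jitter.
#' @param method optimiser passed to [stats::optim()].
#' @param hessian_step central finite-difference step on the transformed
#'   scale.
#' @param hessian compute the Hessian (and hence SEs/CVs)? Skipping it
#'   speeds up simulation studies that only use point estimates.
#' @param ... further arguments to [unisecr_model()] when `model` is raw
#'   capture data.
#' @return An object of class `unisecr_fit` with components `estimates`
#'   (natural-scale estimates, SEs and CVs), `vcov` (transformed scale, free
#'   parameters), `logLik`, `AIC`, `convergence` and the model object.
#'   Non-convergence is flagged, not thrown.
#' @seealso [compare_models()], [location_posterior()],
#'   [simulate.unisecr_fit()]
#' @export
fit_unisecr <- function(model, start = NULL, fixed = NULL, n_starts = 3L,
                        seed = 1L, method = "BFGS", hessian_step = 1e-4,
                        hessian = TRUE, ...) {
  if (inherits(model, "capture_data") || is.list(model) &&
      !inherits(model, "unisecr_model")) {
    model <- unisecr_model(model, ...)
  }
  stopifnot(inherits(model, "unisecr_model"))
  tab <- model$par_table
  pars0 <- complete_pars(model, start)
  tab$start <- unname(pars0[tab$name])
  if (!is.null(fixed)) {
    fixed <- unlist(fixed)
    unknown <- setdiff(names(fixed), tab$name)
    if (length(unknown)) stop("cannot fix unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    tab$start[match(names(fixed), tab$name)] <- unname(fixed)
    tab$fixed[tab$name %in% names(fixed)] <- TRUE
  }
  free <- !tab$fixed
  if (!any(free)) stop("model has no free parameters")
  if (sum(free) > 10L) stop("more than 10 free parameters; simplify the model")

  full_nat <- stats::setNames(tab$start, tab$name)
  t_free <- mapply(link_apply, tab$start[free], tab$link[free])
  links_free <- tab$link[free]
  names_free <- tab$name[free]

  negll <- function(tv) {
    nat <- full_nat
    nat[names_free] <- mapply(link_invert, tv, links_free)
    ll <- full_loglik_raw(model, nat)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  set.seed(as.integer(seed))
  best <- NULL
  trials <- list()
  for (r in seq_len(n_starts)) {
    tv0 <- if (r == 1L) t_free else t_free + stats::rnorm(length(t_free), 0, 0.25)
    opt <- tryCatch(
      stats::optim(tv0, negll, method = method,
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    trials[[length(trials) + 1L]] <- opt
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("optimisation failed from every start")
  }
  converged <- best$convergence == 0 && best$value < 1e9

  vcov_t <- NULL
  if (hessian) {
    H <- fd_hessian(negll, best$par, hessian_step)
    vcov_t <- tryCatch(solve(H), error = function(e) NULL)
  }
  ok_vcov <- !is.null(vcov_t) && all(is.finite(vcov_t)) &&
    all(diag(vcov_t) >= 0)
  if (ok_vcov) {
    vcov_t <- (vcov_t + t(vcov_t)) / 2
    dimnames(vcov_t) <- list(names_free, names_free)
  } else {
    vcov_t <- NULL
  }

  nat_hat <- full_nat
  nat_hat[names_free] <- mapply(link_invert, best$par, links_free)
  se_nat <- cv <- rep(NA_real_, nrow(tab))
  se_t <- rep(NA_real_, nrow(tab))
  if (!is.null(vcov_t)) {
    sdt <- sqrt(diag(vcov_t))
    se_t[free] <- sdt
    dinv <- mapply(link_deriv, best$par, links_free)
    se_nat[free] <- abs(dinv) * sdt
    cv[free] <- ifelse(nat_hat[names_free] != 0,
                       se_nat[free] / abs(nat_hat[names_free]), NA_real_)
  }
  est <- data.frame(par = tab$name, link = tab$link,
                    estimate = unname(nat_hat[tab$name]),
                    se = se_nat, cv = cv, se_trans = se_t,
                    fixed = tab$fixed, stringsAsFactors = FALSE)

  ll <- -best$value
  k <- sum(free)
  structure(list(model = model, estimates = est, pars = nat_hat,
                 vcov = vcov_t, logLik = ll, AIC = 2 * k - 2 * ll,
                 npar = k, n = model$n_total,
                 convergence = list(converged = converged,
                                    code = best$convergence,
                                    n_starts = length(trials),
                                    counts = best$counts),
                 seed = seed, D_units = model$D_units,
                 fingerprint = data_fingerprint(model),
                 notes = paste("Log-likelihood omits multiplicative",
                               "constants free of parameters; compare AIC",
                               "only across models fitted to the same data",
                               "with the same observation structure.")),
            class = "unisecr_fit") |>
    warn_buffer()
}

# Central finite-difference Hessian on the transformed scale.
fd_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

# Warn when detection probability at the mask edge is non-negligible at the
# fitted parameters (buffer likely too small).
warn_buffer <- function(fit) {
  pars <- fit$pars
  for (sess in fit$model$sessions) {
    edge <- mask_edge_index(sess$mask)
    pd <- p_dot_total(sess$mask[edge, , drop = FALSE], fit$model$detection,
                      sess$layout, pars,
                      lambda0 = if ("lambda0" %in% names(pars))
                        pars[["lambda0"]] else 1)
    if (any(pd > 1e-3)) {
      warning("estimated detection probability exceeds 0.001 at the mask ",
              "edge (max ", signif(max(pd), 3), "); the buffer may be too ",
              "small", call. = FALSE)
      break
    }
  }
  fit
}

#' @export
print.unisecr_fit <- function(x, ...) {
  cat("Unified SECR/DS fit:", x$n, "animals,",
      length(x$model$sessions), "session(s)\n")
  cat("log-likelihood:", format(x$logLik, digits = 6),
      "  AIC:", format(x$AIC, digits = 6),
      if (!x$convergence$converged) "  [NOT CONVERGED]", "\n")
  cat("density units:", x$D_units, "\n\n")
  est <- x$estimates
  est$estimate <- signif(est$estimate, 5)
  est$se <- signif(est$se, 4)
  est$cv <- signif(est$cv, 3)
  print(est[, c("par", "estimate", "se", "cv", "fixed")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.unisecr_fit <- function(object, level = 0.95, ...) {
  est <- object$estimates
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- hi <- rep(NA_real_, nrow(est))
  free <- !est$fixed & !is.na(est$se_trans)
  if (any(free)) {
    tv <- mapply(link_apply, est$estimate[free], est$link[free])
    lo[free] <- mapply(link_invert, tv - z * est$se_trans[free],
                       est$link[free])
    hi[free] <- mapply(link_invert, tv + z * est$se_trans[free],
                       est$link[free])
  }
  est$lower <- lo; est$upper <- hi
  out <- list(estimates = est, logLik = object$logLik, AIC = object$AIC,
              n = object$n, convergence = object$convergence,
              level = level, D_units = object$D_units)
  class(out) <- "summary.unisecr_fit"
  out
}

#' @export
print.summary.unisecr_fit <- function(x, ...) {
  cat("Unified SECR/DS model fit\n")
  cat("n =", x$n, " logLik =", format(x$logLik, digits = 6),
      " AIC =", format(x$AIC, digits = 6), "\n")
  cat(sprintf("%d%% Wald intervals on the transformed scale, back-transformed\n",
              round(100 * x$level)))
  est <- x$estimates
  num <- c("estimate", "se", "cv", "lower", "upper")
  est[num] <- lapply(est[num], signif, 4)
  print(est[, c("par", "estimate", "se", "cv", "lower", "upper", "fixed")],
        row.names = FALSE)
  if (!x$convergence$converged) cat("WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
coef.unisecr_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$par)
}

#' @export
vcov.unisecr_fit <- function(object, ...) object$vcov

#' @export
logLik.unisecr_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
confint.unisecr_fit <- function(object, parm, level = 0.95, ...) {
  s <- summary(object, level = level)$estimates
  out <- as.matrix(s[, c("lower", "upper")])
  rownames(out) <- s$par
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predicted detection probabilities from a fit
#'
#' Evaluates the fitted per-detector detection function at given distances
#' (`type = "detection"`) or the fitted overall inclusion probability
#' `p.(x)` at given locations (`type = "pdot"`).
#'
#' @param object a `unisecr_fit`.
#' @param newdata distances in metres (`type = "detection"`) or an `n x 2`
#'   matrix of locations (`type = "pdot"`).
#' @param type `"detection"` or `"pdot"`.
#' @param session session whose geometry is used for `"pdot"`.
#' @param ... unused.
#' @return Numeric vector (for `"detection"` with per-detector parameters, a
#'   `K x n` matrix).
#' @export
predict.unisecr_fit <- function(object, newdata = NULL,
                                type = c("detection", "pdot"),
                                session = 1L, ...) {
  type <- match.arg(type)
  pars <- object$pars
  model <- object$model
  sess <- model$sessions[[session]]
  if (type == "pdot") {
    pts <- newdata %||% sess$mask
    return(p_dot_total(pts, model$detection, sess$layout, pars,
                       lambda0 = if ("lambda0" %in% names(pars))
                         pars[["lambda0"]] else 1))
  }
  d <- newdata %||% seq(0, attr(sess$mask, "buffer"), length.out = 101)
  dm <- matrix(rep(d, each = sess$K), nrow = sess$K)
  p <- det_prob_matrix(model$detection, pars, dm)
  if (isTRUE(model$detection$per_detector)) p else p[1, ]
}

#' Plot a fitted detection function
#'
#' @param x a `unisecr_fit`.
#' @param to maximum distance (metres); defaults to the mask buffer.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.unisecr_fit <- function(x, to = NULL, ...) {
  sess <- x$model$sessions[[1]]
  to <- to %||% attr(sess$mask, "buffer")
  d <- seq(0, to, length.out = 201)
  p <- predict(x, newdata = d, type = "detection")
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  graphics::matplot(d, t(p), type = "l", lty = 1, xlab = "distance (m)",
                    ylab = "detection probability", ylim = c(0, 1), ...)
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Builds a delta-AIC table for a set of fits of the *same* data; fits whose
#' data fingerprints differ are refused, since omitted likelihood constants
#' make AIC comparable only within one data set.
#'
#' @param ... `unisecr_fit` objects (or one list of them), optionally named.
#' @return A data frame sorted by AIC with columns `model`, `npar`,
#'   `logLik`, `AIC`, `dAIC`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "unisecr_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "unisecr_fit")))
  fp <- vapply(fits, `[[`, numeric(1), "fingerprint")
  if (length(unique(fp)) != 1L) {
    stop("fits are not all of the same data; AIC comparison refused")
  }
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  out <- data.frame(model = nm,
                    npar = vapply(fits, `[[`, numeric(1), "npar"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}
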