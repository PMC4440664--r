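#' Posterior distribution of animal locations
#'
#' Applies Bayes' theorem at the fitted (or supplied) parameters to obtain,
#' for each detected animal, the posterior probability of its location over
#' the mask cells: weights proportional to
#' `f(Y_i | x, omega_i) * P(omega_i | x) * D(x) * p.(x)`, normalised over
#' the mask. Point summaries (posterior mode and mean) are reported
#' alongside the full cell weights.
#'
#' @param fit a `unisecr_fit`, or a [unisecr_model()] together with `pars`.
#' @param animals indices of animals to include (default: all in the
#'   session).
#' @param session session index.
#' @param pars named natural-scale parameters (required if `fit` is a bare
#'   model).
#' @return An object of class `location_posterior`: list with `weights`
#'   (`n x M`, rows summing to 1), `mask`, `mode` and `mean` (`n x 2`
#'   matrices), and the animal ids.
#' @export
location_posterior <- function(fit, animals = NULL, session = 1L,
                               pars = NULL) {
  if (inherits(fit, "unisecr_fit")) {
    model <- fit$model
    pars <- complete_pars(model, pars %||% fit$pars)
  } else {
    model <- fit
    pars <- complete_pars(model, pars)
  }
  sess <- model$sessions[[session]]
  if (!is.null(sess$exact)) {
    stop("locations were observed exactly; there is no posterior to compute")
  }
  animals <- animals %||% seq_len(sess$n)
  ker <- session_kernel(sess, model, pars)
  L <- log_num_matrix(sess, ker, pars)
  supp <- log_supp_matrix(sess, model, pars)
  rows <- sess$group_index[animals]
  L <- L[rows, , drop = FALSE]
  if (!is.null(supp)) L <- L + supp[animals, , drop = FALSE]
  # D(x) is homogeneous, so it cancels in the normalisation; p.(x) cancels
  # against the conditioning in P(omega | x).
  lse <- row_logsumexp(L)
  if (any(!is.finite(lse))) {
    stop("posterior integrand is zero everywhere for animal ",
         paste(sess$capture$ids[animals[!is.finite(lse)]], collapse = ", "))
  }
  w <- exp(L - lse)
  mode_idx <- max.col(w, ties.method = "first")
  post_mode <- sess$mask[mode_idx, , drop = FALSE]
  post_mean <- cbind(x = as.vector(w %*% sess$mask[, 1]),
                     y = as.vector(w %*% sess$mask[, 2]))
  structure(list(weights = w, mask = sess$mask, animals = animals,
                 ids = sess$capture$ids[animals], mode = post_mode,
                 mean = post_mean),
            class = "location_posterior")
}

#' @export
print.location_posterior <- function(x, ...) {
  cat("Location posterior for", nrow(x$weights), "animal(s) over",
      ncol(x$weights), "mask cells\n")
  for (i in seq_len(min(nrow(x$weights), 5))) {
    cat(sprintf("  animal %s: mode (%.0f, %.0f)  mean (%.0f, %.0f)\n",
                x$ids[i], x$mode[i, 1], x$mode[i, 2],
                x$mean[i, 1], x$mean[i, 2]))
  }
  invisible(x)
}

#' Highest-density location regions
#'
#' For each animal and probability level, finds the smallest set of mask
#' cells whose total posterior mass reaches the level: cells are ranked by
#' weight and the threshold is the weight of the last cell needed.
#'
#' @param post a [location_posterior()].
#' @param levels probability levels in `(0, 1]`.
#' @return An object of class `probability_contours`: list with `thresholds`
#'   (`n x length(levels)` matrix of weight thresholds), `membership` (list
#'   of `n x M` logical matrices, one per level) and `cell_counts`.
#' @export
probability_contours <- function(post, levels = c(0.5, 0.9)) {
  stopifnot(inherits(post, "location_posterior"))
  if (length(levels) == 0L) stop("at least one probability level is required")
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]")
  n <- nrow(post$weights)
  thresholds <- matrix(NA_real_, n, length(levels),
                       dimnames = list(post$ids, paste0(levels * 100, "%")))
  membership <- lapply(levels, function(l) matrix(FALSE, n, ncol(post$weights)))
  names(membership) <- paste0(levels * 100, "%")
  for (i in seq_len(n)) {
    w <- post$weights[i, ]
    ord <- order(w, decreasing = TRUE)
    cs <- cumsum(w[ord])
    for (j in seq_along(levels)) {
      need <- which(cs >= levels[j] - 1e-12)[1]
      thresholds[i, j] <- w[ord[need]]
      # take cells in rank order so ties cannot inflate the region
      keep <- ord[seq_len(need)]
      keep <- keep[w[keep] > 0]
      membership[[j]][i, keep] <- TRUE
    }
  }
  structure(list(thresholds = thresholds, membership = membership,
                 levels = levels,
                 cell_counts = vapply(membership, rowSums,
                                      numeric(n))),
            class = "probability_contours")
}

#' @export
print.probability_contours <- function(x, ...) {
  cat("Highest-density regions at levels",
      paste(x$levels, collapse = ", "), "\n")
  cc <- x$cell_counts
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1)
  cat("cells per region (first animals):\n")
  print(utils::head(cc))
  invisible(x)
}

#' Plot a location posterior
#'
#' Displays one animal's posterior as an image over the mask with
#' highest-density contour overlays and the detector positions.
#'
#' @param x a [location_posterior()].
#' @param animal which animal (row of the posterior) to draw.
#' @param levels contour probability levels.
#' @param detectors optional [detector_array()] to overlay.
#' @param ... passed to [graphics::image()].
#' @export
plot.location_posterior <- function(x, animal = 1L, levels = c(0.5, 0.9),
                                    detectors = NULL, ...) {
  mask <- x$mask
  xs <- sort(unique(mask[, 1])); ys <- sort(unique(mask[, 2]))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(mask[, 1], xs), match(mask[, 2], ys))] <- x$weights[animal, ]
  graphics::image(xs, ys, z, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  pc <- probability_contours(
    structure(list(weights = x$weights[animal, , drop = FALSE],
                   mask = mask, ids = x$ids[animal]),
              class = "location_posterior"), levels)
  graphics::contour(xs, ys, z, levels = pc$thresholds[1, ], add = TRUE,
                    labels = paste0(levels * 100, "%"))
  if (!is.null(detectors)) {
    graphics::points(detectors[, 1], detectors[, 2], pch = 4, lwd = 2)
  }
  invisible(x)
}
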