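#' Supplementary observation data
#'
#' Aligns noisy location observations with a capture history. Each component
#' is an `n x K` matrix (single occasion) or `n x K x S` array with `NA`
#' wherever the animal was not detected; an observation at a non-detection
#' is an error. `exact` is an `n x 2` matrix of locations observed without
#' error (DS/MRDS surveys) and must cover every animal when present.
#'
#' @param capture a [capture_data()].
#' @param bearing observed bearings (radians, internal convention).
#' @param toa times of arrival (seconds).
#' @param ss received signal strengths (dB).
#' @param distance estimated distances (metres).
#' @param exact exactly observed locations (`n x 2`, metres).
#' @return An object of class `supplementary_data` (a named list of aligned
#'   arrays).
#' @export
supplementary_data <- function(capture, bearing = NULL, toa = NULL, ss = NULL,
                               distance = NULL, exact = NULL) {
  stopifnot(inherits(capture, "capture_data"))
  out <- list()
  for (kind in c("bearing", "toa", "ss", "distance")) {
    y <- switch(kind, bearing = bearing, toa = toa, ss = ss,
                distance = distance)
    if (is.null(y)) next
    if (length(dim(y)) == 2L) y <- array(y, c(dim(y), 1L))
    if (!all(dim(y) == dim(capture$omega))) {
      stop(kind, " observations must match the capture array dimensions")
    }
    bad <- which(!is.na(y) & capture$omega == 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(kind, " observation at a non-detection (animal ",
           paste(unique(bad[, 1]), collapse = ", "), ")")
    }
    out[[kind]] <- y
  }
  if (!is.null(exact)) {
    exact <- as_points(exact)
    if (nrow(exact) != capture$n) {
      stop("exact locations must be given for every detected animal")
    }
    out$exact <- exact
  }
  structure(out, class = "supplementary_data")
}

#' Assemble a unified capture-recapture / distance-sampling model
#'
#' Binds data (capture histories and optional supplementary observations),
#' survey geometry and sub-model specifications into a single object on
#' which the likelihood is evaluated and maximised. Multi-session surveys
#' (independent replicate arrays sharing all parameters) are specified by
#' passing lists of capture data (and, if the geometry differs, lists of
#' layouts/masks); the log-likelihood is the sum over sessions.
#'
#' @param capture a [capture_data()] or list of them (one per session).
#' @param layout a [survey_layout()] or list (recycled across sessions).
#' @param mask a [build_mask()] mask or list (recycled across sessions).
#' @param detection a [detfn] detection specification.
#' @param observation list of [obsmodels] observation specifications. When
#'   `detection` is [detfn_ss()] the signal-strength observation model is
#'   implied and must not be listed separately.
#' @param obs a [supplementary_data()] object or list of them per session.
#' @param D starting (or true) animal density in `D_units`.
#' @param D_units units for density: `"per_ha"`, `"per_km2"` or `"per_m2"`.
#'   All user-facing densities (starts, estimates, simulation truth) are in
#'   these units; internally everything is per square metre.
#' @param count_model distribution of the number of detections: `"poisson"`
#'   (animals from a homogeneous Poisson process, the default) or
#'   `"binomial"` (fixed number `N` in the region).
#' @param N fixed population size for `count_model = "binomial"`.
#' @param lambda0 starting value for the Poisson detection rate multiplier
#'   (count detectors only).
#' @return An object of class `unisecr_model`.
#' @export
unisecr_model <- function(capture, layout, mask, detection,
                          observation = list(), obs = NULL,
                          D = NULL, D_units = c("per_ha", "per_km2", "per_m2"),
                          count_model = c("poisson", "binomial"), N = NULL,
                          lambda0 = 1) {
  D_units <- match.arg(D_units)
  count_model <- match.arg(count_model)
  stopifnot(inherits(detection, "unisecr_detfn"))
  if (inherits(capture, "capture_data")) capture <- list(capture)
  n_sess <- length(capture)
  layouts <- if (inherits(layout, "survey_layout")) rep(list(layout), n_sess)
             else layout
  masks <- if (inherits(mask, "unisecr_mask")) rep(list(mask), n_sess)
           else mask
  if (!is.null(obs) && inherits(obs, "supplementary_data")) obs <- list(obs)
  obs <- obs %||% rep(list(NULL), n_sess)
  stopifnot(length(layouts) == n_sess, length(masks) == n_sess,
            length(obs) == n_sess)

  if (!is.list(observation) || inherits(observation, "unisecr_obs")) {
    observation <- list(observation)
  }
  kinds <- vapply(observation, function(m) m$kind, character(1))
  if (anyDuplicated(kinds)) stop("duplicate observation kinds")
  if (detection$form == "ss_threshold" && "ss" %in% kinds) {
    stop("signal-strength observations are implied by detfn_ss(); do not ",
         "list them separately")
  }

  # Identifiability guard: co-located detectors carry no distance information.
  if (length(observation) == 0L && detection$form != "ss_threshold") {
    colocated <- vapply(layouts, function(l) {
      K <- nrow(l$detectors)
      K > 0 && all(distances(l$detectors, l$detectors[1, ]) < 1e-9)
    }, logical(1))
    if (all(colocated)) {
      stop("a distance-dependent detection function cannot be estimated ",
           "from detectors at a single location; add supplementary ",
           "location observations")
    }
  }

  types <- vapply(layouts, function(l) detector_type(l$detectors), character(1))
  if (count_model == "binomial") {
    if (is.null(N)) stop("count_model = 'binomial' requires N")
    if (N < sum(vapply(capture, `[[`, 0, "n"))) stop("N must be >= n")
  }

  # Keep only the observation kinds the model actually uses, so that e.g. a
  # capture-history-only variant can be fitted to data carrying bearings or
  # signal strengths (detection is then a distance model and the strengths
  # are deliberately ignored).
  modeled <- kinds
  if (detection$form == "ss_threshold") modeled <- c(modeled, "ss")
  obs <- lapply(obs, function(o) {
    if (is.null(o)) return(NULL)
    o <- o[intersect(names(o), c(modeled, if ("exact" %in% modeled) "exact"))]
    if (length(o) == 0L) NULL else structure(o, class = "supplementary_data")
  })

  sessions <- vector("list", n_sess)
  for (j in seq_len(n_sess)) {
    sessions[[j]] <- prep_session(capture[[j]], layouts[[j]], masks[[j]],
                                  obs[[j]], detection, observation)
  }

  pars <- build_par_table(detection, observation, layouts,
                          any(types == "proximity_count"), lambda0)
  if (!is.null(D)) pars$start[pars$name == "D"] <- D

  structure(list(sessions = sessions, detection = detection,
                 observation = observation, count_model = count_model, N = N,
                 D_units = D_units, par_table = pars,
                 n_total = sum(vapply(capture, `[[`, 0, "n"))),
            class = "unisecr_model")
}

#' @export
print.unisecr_model <- function(x, ...) {
  cat("Unified SECR/DS model:", length(x$sessions), "session(s),",
      x$n_total, "detected animals\n")
  cat("  detection:", x$detection$form, " count model:", x$count_model, "\n")
  if (length(x$observation)) {
    cat("  observations:",
        paste(vapply(x$observation, `[[`, "", "kind"), collapse = ", "), "\n")
  }
  cat("  density units:", x$D_units, "\n")
  invisible(x)
}

build_par_table <- function(detection, observation, layouts, any_count,
                            lambda0) {
  K <- max(vapply(layouts, function(l) nrow(l$detectors), integer(1)))
  tabs <- list(data.frame(name = "D", link = "log", start = NA_real_,
                          fixed = FALSE, stringsAsFactors = FALSE))
  dt <- det_par_info(detection, K)
  dt$fixed <- FALSE
  tabs <- c(tabs, list(dt))
  if (any_count) {
    tabs <- c(tabs, list(data.frame(name = "lambda0", link = "log",
                                    start = lambda0, fixed = FALSE)))
  }
  for (m in observation) {
    ot <- obs_par_info(m, K)
    if (nrow(ot) == 0L) next
    ot$fixed <- ot$name == "slope_toa" & !isTRUE(m$estimate_slope)
    tabs <- c(tabs, list(ot))
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# Precompute everything about one session that does not depend on parameters.
prep_session <- function(capture, layout, mask, obs, detection, observation) {
  stopifnot(inherits(capture, "capture_data"),
            inherits(layout, "survey_layout"),
            inherits(mask, "unisecr_mask"))
  if (capture$S != layout$n_occasions) {
    stop("capture data and layout disagree on the number of occasions")
  }
  if (capture$K != nrow(layout$detectors)) {
    stop("capture data and layout disagree on the number of detectors")
  }
  detectors <- layout$detectors
  type <- detector_type(detectors)
  om <- capture$omega
  n <- capture$n; K <- capture$K; S <- capture$S
  if (type == "multicatch" && n > 0) {
    percocc <- apply(om > 0, c(1, 3), sum)
    if (any(percocc > 1)) {
      stop("multi-catch traps cannot detect an animal at two detectors in ",
           "one occasion")
    }
  }
  if (type == "proximity_binary" && any(om > 1)) {
    stop("binary proximity data cannot contain counts > 1; use a ",
         "'proximity_count' detector array")
  }
  dist <- distances(detectors, mask)               # K x M
  A <- if (n > 0) apply(om, c(1, 2), sum) else matrix(0, 0, K)
  ndet <- if (n > 0) apply(om > 0, c(1, 3), any) else matrix(FALSE, 0, S)
  ndet <- if (n > 0) rowSums(matrix(ndet, n, S)) else numeric(0)

  ss_mod <- if (detection$form == "ss_threshold") detection else NULL
  have_obs <- !is.null(obs) && length(obs) > 0
  # Group animals with identical capture histories when nothing else
  # distinguishes them (big saving for capture-history-only fits).
  if (!have_obs && n > 0) {
    key <- apply(matrix(om, n), 1, paste, collapse = ",")
    grp <- match(key, unique(key))
    idx <- which(!duplicated(key))
    weights <- as.vector(table(grp)[as.character(seq_along(idx))])
    Agrp <- A[idx, , drop = FALSE]
    ndetgrp <- ndet[idx]
    lgam <- rowSums(lgamma(matrix(om, n) + 1))[idx]
  } else {
    grp <- seq_len(n); idx <- seq_len(n)
    weights <- rep(1, n)
    Agrp <- A; ndetgrp <- ndet
    lgam <- if (n > 0) rowSums(lgamma(matrix(om, n) + 1)) else numeric(0)
  }

  sess <- list(capture = capture, layout = layout, mask = mask, type = type,
               n = n, K = K, S = S, M = nrow(mask),
               cell_area = mask_cell_area(mask), dist = dist,
               A = A, ndet = ndet, Agrp = Agrp, ndetgrp = ndetgrp,
               weights = weights, group_index = grp, rep_index = idx,
               lgam = lgam, obs = list(), exact = NULL)

  if (have_obs) {
    if (!is.null(obs$exact)) {
      sess$exact <- obs$exact
      sess$dist_exact <- distances(detectors, obs$exact)   # K x n
    }
    if (!is.null(obs$bearing)) {
      y <- obs$bearing
      sess$bear_mask <- bearings_safe(detectors, mask)     # K x M
      cosy <- ifelse(is.na(y), 0, cos(y)); siny <- ifelse(is.na(y), 0, sin(y))
      sess$obs$bearing <- list(
        C = apply(cosy, c(1, 2), sum), S = apply(siny, c(1, 2), sum),
        m = apply(!is.na(y), 1, sum))
    }
    if (!is.null(obs$toa)) {
      y <- obs$toa
      rows <- list(); ai <- integer(0)
      for (s in seq_len(dim(y)[3])) {
        ys <- y[, , s, drop = FALSE][, , 1, drop = FALSE]
        dim(ys) <- dim(y)[1:2]
        keep <- which(rowSums(!is.na(ys)) >= 2)
        for (i in keep) { rows[[length(rows) + 1L]] <- ys[i, ]; ai <- c(ai, i) }
      }
      if (length(rows)) {
        Y <- do.call(rbind, rows)
        W <- !is.na(Y); Y0 <- ifelse(W, Y, 0)
        sess$obs$toa <- list(W = W * 1, Wy = Y0, m = rowSums(W),
                             syy = rowSums(Y0^2), sy = rowSums(Y0),
                             animal = ai)
      }
    }
    if (!is.null(obs$ss)) {
      if (is.null(ss_mod)) stop("ss data require the detfn_ss() detection model")
      y <- obs$ss
      if (any(y < ss_mod$cutoff, na.rm = TRUE)) {
        stop("received signal strengths below the cutoff are inconsistent ",
             "with detection")
      }
      W <- apply(!is.na(y), c(1, 2), sum)
      Y0 <- ifelse(is.na(y), 0, y)
      sess$obs$ss <- list(W = W, Wy = apply(Y0, c(1, 2), sum),
                          syy = apply(Y0^2, 1, sum), m = rowSums(W))
    }
    if (!is.null(obs$distance)) {
      y <- obs$distance
      if (any(y <= 0, na.rm = TRUE)) stop("estimated distances must be > 0")
      W <- apply(!is.na(y), c(1, 2), sum)
      Y0 <- ifelse(is.na(y), 0, y)
      L0 <- ifelse(is.na(y), 0, log(pmax(y, 1e-300)))
      sess$obs$distance <- list(W = W, Wy = apply(Y0, c(1, 2), sum),
                                Wly = apply(L0, c(1, 2), sum),
                                m = rowSums(W), sly = apply(L0, 1, sum))
    }
  }
  sess
}
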