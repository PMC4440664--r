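# Readers and writers for the plain-text survey formats and JSON fit output.
# CSV dialect: comma-separated, header row, '.' decimal; occasion and
# detector indices are 1-based in files.

#' Read a survey bundle from CSV files
#'
#' Reads detector coordinates, capture histories and (optionally)
#' supplementary observations, validates their cross-references, and
#' returns them as one bundle ready for [unisecr_model()].
#'
#' File formats:
#' * traps: header `id,x,y`, coordinates in metres;
#' * captures: header `id,occasion,detector,value` (long form; `value` is 1
#'   or a count), or a wide form whose header is `id` followed by one
#'   column per detector of binary indicators (single occasion);
#' * observations: header `id,detector,occasion,kind,value` with `kind` in
#'   `bearing` (radians, or degrees clockwise from north with
#'   `bearing_unit = "deg_north"`), `toa` (seconds), `ss` (dB),
#'   `dist` (metres).
#'
#' @param traps_path,captures_path,obs_path file paths (`obs_path` optional).
#' @param detector_type detector type for the array.
#' @param n_occasions number of occasions `S`.
#' @param bearing_unit unit of bearing observations in the file.
#' @return An object of class `survey_bundle`: list with `layout`,
#'   `capture`, `obs` and `provenance`.
#' @export
read_bundle <- function(traps_path, captures_path, obs_path = NULL,
                        detector_type = "proximity_binary",
                        n_occasions = 1L,
                        bearing_unit = c("rad", "deg_north")) {
  bearing_unit <- match.arg(bearing_unit)
  traps <- utils::read.csv(traps_path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(traps))) {
    stop("trap file must have header id,x,y")
  }
  detectors <- detector_array(traps$x, traps$y, type = detector_type)
  layout <- survey_layout(detectors, n_occasions)
  K <- nrow(detectors); S <- as.integer(n_occasions)

  cap <- utils::read.csv(captures_path, stringsAsFactors = FALSE)
  if (all(c("id", "occasion", "detector") %in% names(cap))) {
    if (is.null(cap$value)) cap$value <- 1L
    if (nrow(cap) > 0) {
      det_idx <- match(cap$detector, traps$id)
      if (anyNA(det_idx)) {
        stop("capture rows reference unknown detectors: rows ",
             paste(which(is.na(det_idx)), collapse = ", "))
      }
      if (any(cap$occasion < 1 | cap$occasion > S)) {
        stop("capture rows reference occasions outside 1..", S)
      }
      keydup <- duplicated(cap[, c("id", "occasion", "detector")])
      if (any(keydup)) {
        stop("duplicate animal-detector-occasion capture rows: rows ",
             paste(which(keydup), collapse = ", "))
      }
    }
    ids <- unique(cap$id)
    omega <- array(0L, c(length(ids), K, S))
    if (nrow(cap) > 0) {
      omega[cbind(match(cap$id, ids), match(cap$detector, traps$id),
                  as.integer(cap$occasion))] <- as.integer(cap$value)
    }
  } else if ("id" %in% names(cap)) {
    wide <- as.matrix(cap[, setdiff(names(cap), "id"), drop = FALSE])
    if (ncol(wide) != K) stop("wide capture matrix must have K detector columns")
    ids <- cap$id
    omega <- array(as.integer(wide), c(nrow(wide), K, 1L))
    S <- 1L
  } else {
    stop("capture file must have header id,occasion,detector,value ",
         "(or wide form with an id column)")
  }
  capture <- capture_data(omega, ids = ids)

  obs <- NULL
  if (!is.null(obs_path)) {
    ob <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
    need <- c("id", "detector", "occasion", "kind", "value")
    if (!all(need %in% names(ob))) {
      stop("observation file must have header id,detector,occasion,kind,value")
    }
    kinds_map <- c(bearing = "bearing", toa = "toa", ss = "ss",
                   dist = "distance")
    if (!all(ob$kind %in% names(kinds_map))) {
      stop("unknown observation kind(s): ",
           paste(setdiff(unique(ob$kind), names(kinds_map)), collapse = ", "))
    }
    ai <- match(ob$id, ids)
    di <- match(ob$detector, traps$id)
    oi <- as.integer(ob$occasion)
    bad <- which(is.na(ai) | is.na(di) | oi < 1 | oi > S)
    if (length(bad) == 0) {
      orphan <- which(omega[cbind(ai, di, oi)] == 0)
      bad <- orphan
    }
    if (length(bad)) {
      stop("observations with no matching capture: rows ",
           paste(bad, collapse = ", "))
    }
    args <- list(capture = capture)
    for (kk in unique(ob$kind)) {
      rows <- ob$kind == kk
      val <- ob$value[rows]
      if (kk == "bearing" && bearing_unit == "deg_north") {
        val <- deg_north_to_rad(val)
      }
      y <- array(NA_real_, c(length(ids), K, S))
      y[cbind(ai[rows], di[rows], oi[rows])] <- val
      args[[kinds_map[[kk]]]] <- y
    }
    obs <- do.call(supplementary_data, args)
  }

  prov <- list(
    files = c(traps = traps_path, captures = captures_path,
              obs = obs_path %||% NA_character_),
    md5 = tools::md5sum(c(traps_path, captures_path,
                          if (!is.null(obs_path)) obs_path)),
    bearing_unit = bearing_unit)
  message("read bundle: ", capture$n, " animals, ", sum(capture$omega > 0),
          " detections",
          if (!is.null(obs)) paste0("; observation kinds: ",
                                    paste(names(obs), collapse = ", ")))
  structure(list(layout = layout, capture = capture, obs = obs,
                 provenance = prov),
            class = "survey_bundle")
}

#' Write a survey bundle to CSV files
#'
#' Inverse of [read_bundle()]: writes trap, capture and observation CSVs in
#' the long formats that [read_bundle()] reads back.
#'
#' @param capture a [capture_data()].
#' @param layout the [survey_layout()].
#' @param dir output directory (created if needed).
#' @param obs optional [supplementary_data()].
#' @param prefix file-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_bundle <- function(capture, layout, dir, obs = NULL, prefix = "survey") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, paste0(prefix, "_traps.csv"))
  cp <- file.path(dir, paste0(prefix, "_captures.csv"))
  op <- file.path(dir, paste0(prefix, "_obs.csv"))
  det <- layout$detectors
  utils::write.csv(data.frame(id = seq_len(nrow(det)), x = det[, 1],
                              y = det[, 2]), tp, row.names = FALSE)
  idx <- which(capture$omega > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 3], idx[, 2]), , drop = FALSE]
  utils::write.csv(data.frame(id = capture$ids[idx[, 1]],
                              occasion = idx[, 3], detector = idx[, 2],
                              value = capture$omega[idx]),
                   cp, row.names = FALSE)
  paths <- c(tp, cp)
  if (!is.null(obs)) {
    rows <- list()
    km <- c(bearing = "bearing", toa = "toa", ss = "ss", distance = "dist")
    for (kind in intersect(names(obs), names(km))) {
      y <- obs[[kind]]
      idx <- which(!is.na(y), arr.ind = TRUE)
      rows[[kind]] <- data.frame(id = capture$ids[idx[, 1]],
                                 detector = idx[, 2], occasion = idx[, 3],
                                 kind = km[[kind]], value = y[idx])
    }
    if (length(rows)) {
      utils::write.csv(do.call(rbind, rows), op, row.names = FALSE)
      paths <- c(paths, op)
    }
  }
  invisible(paths)
}

#' Write a fit to JSON
#'
#' Serialises estimates, transformed-scale covariance, CVs, AIC and fitting
#' metadata to JSON. A fit without a valid covariance (non-convergence or a
#' singular Hessian) stores `vcov` as null with a flag. Output is
#' deterministic: two writes of one fit are byte-identical.
#'
#' @param fit a `unisecr_fit`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "unisecr_fit"))
  payload <- list(
    package = "unisecr",
    version = as.character(utils::packageVersion("unisecr")),
    D_units = fit$D_units,
    n = fit$n,
    estimates = fit$estimates,
    vcov = if (is.null(fit$vcov)) NULL else {
      list(par = colnames(fit$vcov), matrix = unname(as.matrix(fit$vcov)))
    },
    vcov_available = !is.null(fit$vcov),
    logLik = fit$logLik, AIC = fit$AIC, npar = fit$npar,
    convergence = fit$convergence[c("converged", "code", "n_starts")],
    seed = fit$seed, fingerprint = fit$fingerprint, notes = fit$notes)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a fit written by [write_fit()]
#'
#' @param path JSON path.
#' @return A list with the stored estimates, covariance and metadata (not a
#'   refittable `unisecr_fit`; the data are not stored).
#' @export
read_fit <- function(path) {
  out <- jsonlite::fromJSON(path)
  if (isTRUE(out$vcov_available)) {
    m <- out$vcov$matrix
    dimnames(m) <- list(out$vcov$par, out$vcov$par)
    out["vcov"] <- list(m)
  } else {
    out["vcov"] <- list(NULL)
  }
  out
}

#' Export a mask as CSV
#'
#' @param mask a [build_mask()] mask.
#' @param path output path; columns `x,y`.
#' @return Invisibly, `path`.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(data.frame(x = mask[, 1], y = mask[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}
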