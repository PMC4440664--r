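#' Detector arrays
#'
#' A detector array holds the planar coordinates (metres) of the `K` detectors
#' of a survey, together with the detector type. Detector types:
#' `"proximity_binary"` records a binary detected/not-detected indicator per
#' detector and occasion (detectors do not detain animals, so within-occasion
#' detections at several detectors are possible); `"proximity_count"` records
#' a detection count per detector and occasion; `"multicatch"` detains the
#' animal for the remainder of the occasion, so at most one detector can
#' record it per occasion.
#'
#' @param x,y numeric vectors of detector coordinates in metres. `x` may also
#'   be a two-column matrix or data frame, in which case `y` is ignored.
#' @param type detector type, one of `"proximity_binary"`,
#'   `"proximity_count"`, `"multicatch"`.
#' @return An object of class `detector_array`: a `K x 2` coordinate matrix
#'   with a `type` attribute.
#' @examples
#' detector_array(c(0, 500, 1000), c(0, 0, 0))
#' @export
detector_array <- function(x, y = NULL,
                           type = c("proximity_binary", "proximity_count",
                                    "multicatch")) {
  type <- match.arg(type)
  if (is.matrix(x) || is.data.frame(x)) {
    coords <- as.matrix(x[, 1:2])
  } else {
    coords <- cbind(x, y)
  }
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("need at least one detector")
  stopifnot_finite(coords, "detector coordinates")
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(coords, type = type, class = c("detector_array", "matrix", "array"))
}

#' @export
print.detector_array <- function(x, ...) {
  cat("Detector array:", nrow(x), "detectors, type", attr(x, "type"), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

detector_type <- function(detectors) attr(detectors, "type") %||% "proximity_binary"

#' Survey layout
#'
#' Bundles a detector array with the number of sampling occasions `S` and
#' optional occasion durations (seconds; used by the time-of-arrival
#' simulator to draw emission times).
#'
#' @param detectors a [detector_array()].
#' @param n_occasions number of occasions `S >= 1`.
#' @param durations optional numeric vector of occasion durations in seconds
#'   (recycled to length `S`).
#' @return An object of class `survey_layout`.
#' @export
survey_layout <- function(detectors, n_occasions = 1L, durations = NULL) {
  stopifnot(inherits(detectors, "detector_array"))
  n_occasions <- as.integer(n_occasions)
  if (n_occasions < 1L) stop("n_occasions must be >= 1")
  if (!is.null(durations)) durations <- rep_len(as.numeric(durations), n_occasions)
  structure(list(detectors = detectors, n_occasions = n_occasions,
                 durations = durations),
            class = "survey_layout")
}

#' @export
print.survey_layout <- function(x, ...) {
  cat("Survey layout:", nrow(x$detectors), "detectors (",
      detector_type(x$detectors), "),", x$n_occasions, "occasion(s)\n")
  invisible(x)
}

#' Build a habitat mask
#'
#' Creates the rectangular grid of candidate animal locations over which all
#' spatial integrals are evaluated by midpoint quadrature: the grid covers
#' the detector bounding box extended by `buffer` on all sides, at step
#' `spacing`, and each point stands for a square cell of area `spacing^2`.
#'
#' The buffer should be large enough that the probability of detecting an
#' animal living at the mask edge is negligible; [fit_unisecr()] warns when
#' the fitted model suggests it is not.
#'
#' @param detectors a [detector_array()].
#' @param buffer buffer distance in metres (`> spacing`).
#' @param spacing grid step in metres.
#' @param min_points minimum acceptable number of mask points; the default
#'   of 100 guards against masks too coarse for reliable quadrature.
#' @return An object of class `unisecr_mask`: an `M x 2` matrix of point
#'   coordinates with attributes `spacing`, `cell_area` (m^2) and `buffer`.
#' @examples
#' traps <- detector_array(c(0, 500, 1000), c(0, 0, 0))
#' mask <- build_mask(traps, buffer = 6000, spacing = 250)
#' @export
build_mask <- function(detectors, buffer, spacing, min_points = 100L) {
  stopifnot(inherits(detectors, "detector_array"))
  if (!is.finite(buffer) || buffer <= 0) stop("buffer must be > 0")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (spacing >= buffer) stop("spacing must be smaller than buffer")
  gx <- seq(min(detectors[, 1]) - buffer, max(detectors[, 1]) + buffer, by = spacing)
  gy <- seq(min(detectors[, 2]) - buffer, max(detectors[, 2]) + buffer, by = spacing)
  pts <- cbind(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
  if (nrow(pts) < min_points) {
    stop("mask has only ", nrow(pts), " points (< ", min_points,
         "); reduce spacing (or increase buffer) for adequate quadrature")
  }
  structure(pts, spacing = spacing, cell_area = spacing^2, buffer = buffer,
            nx = length(gx), ny = length(gy),
            class = c("unisecr_mask", "matrix", "array"))
}

#' @export
print.unisecr_mask <- function(x, ...) {
  cat("Habitat mask:", nrow(x), "points, spacing", attr(x, "spacing"),
      "m, cell area", attr(x, "cell_area"), "m^2, buffer",
      attr(x, "buffer"), "m\n")
  invisible(x)
}

mask_cell_area <- function(mask) attr(mask, "cell_area")

# Indices of mask points lying on the rectangular boundary (buffer diagnostic).
mask_edge_index <- function(mask) {
  rx <- range(mask[, 1]); ry <- range(mask[, 2])
  which(mask[, 1] %in% rx | mask[, 2] %in% ry)
}

#' Detector-to-point distances
#'
#' Euclidean distance from every detector to every point,
#' `d_k(x) = sqrt((z_k1 - x_1)^2 + (z_k2 - x_2)^2)`.
#'
#' @param detectors a [detector_array()] (or any `K x 2` matrix).
#' @param points an `n x 2` matrix (or length-2 vector) of point coordinates.
#' @return A `K x n` matrix of distances in metres.
#' @export
distances <- function(detectors, points) {
  points <- as_points(points)
  stopifnot_finite(points, "point coordinates")
  dx <- outer(unname(detectors[, 1]), points[, 1], "-")
  dy <- outer(unname(detectors[, 2]), points[, 2], "-")
  out <- sqrt(dx * dx + dy * dy)
  dimnames(out) <- NULL
  out
}

#' Detector-to-point bearings
#'
#' Full-circle angle of each point as seen from each detector, in radians,
#' measured counterclockwise from the +x axis (the internal mathematical
#' convention), in `[0, 2*pi)`. Use [deg_north_to_rad()] /
#' [rad_to_deg_north()] to convert compass bearings (degrees clockwise from
#' north).
#'
#' @inheritParams distances
#' @return A `K x n` matrix of angles in radians.
#' @export
bearings <- function(detectors, points) {
  points <- as_points(points)
  stopifnot_finite(points, "point coordinates")
  dx <- outer(detectors[, 1], points[, 1], function(z, p) p - z)
  dy <- outer(detectors[, 2], points[, 2], function(z, p) p - z)
  if (any(dx == 0 & dy == 0)) {
    stop("bearing undefined: point coincident with a detector")
  }
  out <- atan2(dy, dx) %% (2 * pi)
  dimnames(out) <- NULL
  out
}

# Quadrature-safe bearing matrix: a mask point exactly on a detector gets an
# arbitrary angle of 0 (a measure-zero cell; the bearing density is bounded).
bearings_safe <- function(detectors, points) {
  points <- as_points(points)
  dx <- outer(detectors[, 1], points[, 1], function(z, p) p - z)
  dy <- outer(detectors[, 2], points[, 2], function(z, p) p - z)
  out <- atan2(dy, dx) %% (2 * pi)
  out[dx == 0 & dy == 0] <- 0
  dimnames(out) <- NULL
  out
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  as.matrix(points[, 1:2, drop = FALSE])
}

#' Compass-bearing conversions
#'
#' Convert between compass bearings (degrees clockwise from north) and the
#' internal angle convention (radians counterclockwise from the +x axis).
#'
#' @param deg angles in degrees clockwise from north.
#' @param rad angles in radians counterclockwise from +x.
#' @return Converted angles; both functions return values wrapped to one
#'   full circle.
#' @export
deg_north_to_rad <- function(deg) (pi / 2 - deg * pi / 180) %% (2 * pi)

#' @rdname deg_north_to_rad
#' @export
rad_to_deg_north <- function(rad) ((pi / 2 - rad) * 180 / pi) %% 360
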