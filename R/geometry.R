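#' Embryo coordinate frame
#'
#' Describes the position and orientation of an ellipsoidal embryo within an
#' image, together with its axis lengths. The canonical frame used by all
#' downstream metrics has its origin at the embryo centre, the long axis along
#' x and the short axis along y, with the spindle-containing pole at negative
#' x at the first frame of a recording.
#'
#' @param long_axis_um Length of the embryo long axis in micrometres.
#' @param short_axis_um Length of the short axis in micrometres. Must not
#'   exceed `long_axis_um`.
#' @param origin Numeric length-2: embryo centre in image coordinates (um).
#' @param orientation_deg Rotation (degrees, counter-clockwise) that the long
#'   axis makes with the image x axis.
#' @return An object of class `embryo_frame`.
#' @examples
#' embryo_frame(50, 25)
#' @export
embryo_frame <- function(long_axis_um, short_axis_um,
                         origin = c(0, 0), orientation_deg = 0) {
  if (!is.numeric(long_axis_um) || !is.numeric(short_axis_um) ||
      length(long_axis_um) != 1L || length(short_axis_um) != 1L)
    stop("axis lengths must be single numbers")
  if (!(short_axis_um > 0) || long_axis_um < short_axis_um)
    stop("invalid embryo dimensions: need long_axis_um >= short_axis_um > 0")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be numeric length 2")
  structure(
    list(long_axis_um = long_axis_um, short_axis_um = short_axis_um,
         origin = as.numeric(origin),
         orientation_deg = as.numeric(orientation_deg)),
    class = "embryo_frame")
}

#' @export
print.embryo_frame <- function(x, ...) {
  cat(sprintf("<embryo_frame> %g um x %g um, centre (%g, %g), orientation %g deg\n",
              x$long_axis_um, x$short_axis_um, x$origin[1], x$origin[2],
              x$orientation_deg))
  invisible(x)
}

#' Ellipsoid semi-axes
#'
#' @param a_um,b_um,c_um Semi-axes in micrometres; all must be positive.
#' @return An object of class `ellipsoid_dims`.
#' @examples
#' ellipsoid_dims(25, 12.5, 12.5)  # canonical C. elegans zygote
#' @export
ellipsoid_dims <- function(a_um, b_um, c_um) {
  ax <- c(a = a_um, b = b_um, c = c_um)
  if (!is.numeric(ax) || length(ax) != 3L || anyNA(ax) || any(ax <= 0))
    stop("invalid ellipsoid dimensions: all semi-axes must be positive")
  structure(as.list(ax), names = c("a_um", "b_um", "c_um"),
            class = "ellipsoid_dims")
}

#' Volume of an ellipsoid
#'
#' Computes (4/3) * pi * a * b * c from the semi-axes. For equal semi-axes
#' this reduces to the sphere formula.
#'
#' @param dims An [ellipsoid_dims()] object (or numeric length-3 of semi-axes
#'   in um).
#' @return Volume in cubic micrometres.
#' @examples
#' ellipsoid_volume(ellipsoid_dims(25, 12.5, 12.5))
#' @export
ellipsoid_volume <- function(dims) {
  dims <- as_ellipsoid_dims(dims)
  4 / 3 * pi * dims$a_um * dims$b_um * dims$c_um
}

as_ellipsoid_dims <- function(x) {
  if (inherits(x, "ellipsoid_dims")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(ellipsoid_dims(x[1], x[2], x[3]))
  stop("expected ellipsoid_dims or numeric length 3")
}

#' Ratio of two ellipsoid (or sphere) volumes
#'
#' Used to compare zygote sizes across species, e.g. a spherical mouse or
#' human zygote against the ellipsoidal C. elegans zygote. The raw ratio is
#' returned together with its value rounded half-up to the nearest integer,
#' the form in which such comparisons are usually quoted.
#'
#' @param numerator,denominator [ellipsoid_dims()] objects.
#' @return A list of class `volume_ratio` with elements `raw` and `nearest`.
#' @examples
#' # 80-um-diameter mouse zygote vs 50 x 25 x 25 um C. elegans zygote
#' volume_ratio(ellipsoid_dims(40, 40, 40), ellipsoid_dims(25, 12.5, 12.5))
#' @export
volume_ratio <- function(numerator, denominator) {
  vn <- ellipsoid_volume(numerator)
  vd <- ellipsoid_volume(denominator)
  if (vd <= 0) stop("invalid dimensions: denominator volume must be positive")
  r <- vn / vd
  structure(list(raw = r, nearest = round_half_up(r)), class = "volume_ratio")
}

#' @export
print.volume_ratio <- function(x, ...) {
  cat(sprintf("volume ratio: %.4g (nearest integer: %d)\n", x$raw,
              as.integer(x$nearest)))
  invisible(x)
}

# round half away from zero (x >= 0 in all uses here)
round_half_up <- function(x) floor(x + 0.5)

#' Rotate a track into the canonical embryo frame
#'
#' Applies the rigid transform (rotation plus translation, no scaling) that
#' maps image coordinates onto the canonical embryo frame: origin at the
#' embryo centre, long axis along x. If the spindle starting position would
#' land on the positive-x half, the frame is additionally rotated by 180
#' degrees so that the spindle-containing pole is on the left (x <= 0), the
#' convention under which every recording is analysed.
#'
#' @param track_points Numeric matrix (n x 2) or data frame with columns
#'   `x_um`, `y_um`, in image coordinates (um).
#' @param spindle_start Numeric length-2: spindle centre at the first frame,
#'   image coordinates (um).
#' @param embryo An [embryo_frame()].
#' @return Matrix (n x 2) of transformed points; pairwise distances are
#'   preserved exactly up to floating point.
#' @export
normalize_orientation <- function(track_points, spindle_start, embryo) {
  stopifnot(inherits(embryo, "embryo_frame"))
  pts <- as_point_matrix(track_points)
  sp <- as.numeric(spindle_start)
  if (length(sp) != 2L) stop("spindle_start must be numeric length 2")
  th <- -embryo$orientation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xf <- function(p) sweep(p, 2, embryo$origin) %*% t(rot)
  sp_c <- drop(xf(matrix(sp, 1)))
  out <- xf(pts)
  if (sp_c[1] > 0) out <- -out  # 180 degree rotation: spindle pole to the left
  colnames(out) <- c("x_um", "y_um")
  out
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) {
    if (all(c("x_um", "y_um") %in% names(p))) p <- cbind(p$x_um, p$y_um)
    else p <- as.matrix(p[, 1:2])
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L || !is.numeric(p)) stop("points must be an n x 2 numeric matrix")
  p
}

#' Embryo-length inclusion filter for ER-ring tracking
#'
#' Embryos measuring 35 um or less along the long axis are considered tilted
#' relative to the focal plane and are excluded from tracking; only embryos
#' strictly longer than 35 um pass.
#'
#' @param measured_length_um Measured long-axis length (um); must be
#'   non-negative.
#' @param min_length_um Inclusion threshold, default 35 um (strict).
#' @return `TRUE` (usable) or `FALSE` (excluded).
#' @examples
#' qc_embryo_length(50)   # TRUE
#' qc_embryo_length(35)   # FALSE: boundary fails
#' @export
qc_embryo_length <- function(measured_length_um, min_length_um = 35) {
  if (!is.numeric(measured_length_um) || anyNA(measured_length_um))
    stop("invalid measurement: length must be numeric")
  if (any(measured_length_um < 0))
    stop("invalid measurement: negative embryo length")
  measured_length_um > min_length_um
}

# TRUE for points (n x 3 or n x 2 matrix, um, embryo-centred) inside the
# ellipsoid, with an optional safety margin subtracted from each semi-axis.
inside_ellipsoid <- function(p, dims, margin_um = 0) {
  dims <- as_ellipsoid_dims(dims)
  p <- as.matrix(p)
  a <- dims$a_um - margin_um; b <- dims$b_um - margin_um
  cc <- dims$c_um - margin_um
  z2 <- if (ncol(p) >= 3) (p[, 3] / cc)^2 else 0
  (p[, 1] / a)^2 + (p[, 2] / b)^2 + z2 <= 1
}
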