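#' Time-lapse trajectory of a tracked object
#'
#' An ordered series of 2-D positions for one tracked object (the sperm ER
#' ring or the meiotic spindle), one row per acquired frame. Frames need not
#' be consecutive (gaps from missed frames are allowed) but must be strictly
#' increasing.
#'
#' @param frame Integer frame indices (0-based), strictly increasing.
#' @param x_um,y_um Positions in micrometres (canonical embryo frame).
#' @param frame_interval_s Time between consecutive frame indices (s),
#'   default 5.
#' @param embryo_id Optional identifier.
#' @param object `"sperm_ring"` or `"spindle"`.
#' @return A data frame of class `trajectory` with columns `frame`, `x_um`,
#'   `y_um` and attributes `frame_interval_s`, `embryo_id`, `object`.
#' @export
trajectory <- function(frame, x_um, y_um, frame_interval_s = 5,
                       embryo_id = NA_character_,
                       object = c("sperm_ring", "spindle")) {
  object <- match.arg(object)
  frame <- as.integer(frame)
  if (length(frame) < 1L) stop("a trajectory needs at least one point")
  if (length(x_um) != length(frame) || length(y_um) != length(frame))
    stop("frame, x_um, y_um must have equal length")
  if (is.unsorted(frame, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  structure(data.frame(frame = frame, x_um = as.numeric(x_um),
                       y_um = as.numeric(y_um)),
            frame_interval_s = frame_interval_s,
            embryo_id = embryo_id, object = object,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d frames (%g s interval)%s\n",
              attr(x, "object"), nrow(x), attr(x, "frame_interval_s"),
              if (is.na(attr(x, "embryo_id"))) "" else
                paste0(", embryo ", attr(x, "embryo_id"))))
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., col = "steelblue") {
  graphics::plot(x$x_um, x$y_um, type = "l", col = col, asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::points(x$x_um[1], x$y_um[1], pch = 16, col = col)
  invisible(x)
}

as_trajectory <- function(x, frame_interval_s = 5) {
  if (inherits(x, "trajectory")) return(x)
  if (is.data.frame(x) && all(c("frame", "x_um", "y_um") %in% names(x)))
    return(trajectory(x$frame, x$x_um, x$y_um,
                      frame_interval_s = frame_interval_s))
  stop("cannot interpret input as a trajectory")
}

#' Phase windows of a recording
#'
#' Frame windows delimiting the quantified meiotic phases (metaphase and
#' anaphase of meiosis I and II). Windows are inclusive of both endpoint
#' frames, ordered, and non-overlapping; a boundary frame belongs to the
#' earlier phase only if windows abut exactly (the splitter takes windows as
#' given, so annotations should not overlap).
#'
#' @param phase Character vector over `MI`, `AI`, `MII`, `AII`.
#' @param first_frame,last_frame Integer window bounds, inclusive.
#' @param complete Logical: was the phase completely filmed? Incompletely
#'   filmed phases and phases at which cell-cycle arrest occurred are
#'   excluded from quantification; mark them `FALSE`.
#' @return Data frame of class `phase_windows`.
#' @export
phase_windows <- function(phase, first_frame, last_frame,
                          complete = TRUE) {
  if (!all(phase %in% phase_order)) stop("unknown phase label")
  first_frame <- as.integer(first_frame); last_frame <- as.integer(last_frame)
  if (any(first_frame > last_frame)) stop("first_frame must be <= last_frame")
  n <- length(phase)
  complete <- rep_len(complete, n)
  if (n > 1L) {
    o <- order(first_frame)
    if (any(first_frame[o][-1] <= last_frame[o][-n]))
      stop("phase windows must not overlap")
  }
  structure(data.frame(phase = phase, first_frame = first_frame,
                       last_frame = last_frame, complete = complete),
            class = c("phase_windows", "data.frame"))
}

#' Split a trajectory into per-phase sub-tracks
#'
#' Each sub-track contains exactly the points whose frame index falls inside
#' the (inclusive) phase window. A sub-track is flagged incomplete when its
#' window is annotated incomplete or extends beyond the filmed frame range;
#' incomplete sub-tracks are retained but excluded by [track_metrics()].
#'
#' @param track A [trajectory()].
#' @param windows A [phase_windows()] data frame.
#' @return Named list of trajectories (possibly zero-row), each with
#'   attributes `phase` and `complete`.
#' @export
split_by_phase <- function(track, windows) {
  track <- as_trajectory(track)
  if (!is.data.frame(windows)) stop("windows must be a data frame")
  if (is.null(windows$complete)) windows$complete <- TRUE
  out <- vector("list", nrow(windows))
  names(out) <- windows$phase
  for (i in seq_len(nrow(windows))) {
    sel <- track$frame >= windows$first_frame[i] &
      track$frame <= windows$last_frame[i]
    sub <- track[sel, , drop = FALSE]
    covered <- nrow(sub) > 0L &&
      windows$first_frame[i] >= min(track$frame) &&
      windows$last_frame[i] <= max(track$frame)
    attr(sub, "phase") <- windows$phase[i]
    attr(sub, "complete") <- isTRUE(windows$complete[i]) && covered
    attr(sub, "frame_interval_s") <- attr(track, "frame_interval_s")
    attr(sub, "embryo_id") <- attr(track, "embryo_id")
    attr(sub, "object") <- attr(track, "object")
    class(sub) <- c("trajectory", "data.frame")
    out[[i]] <- sub
  }
  out
}

check_points <- function(sub, min_n = 1L) {
  if (nrow(sub) < min_n) stop("no-data error: sub-track has fewer than ",
                              min_n, " points")
  invisible(TRUE)
}

#' Maximum per-axis displacement of a sub-track
#'
#' Maximum minus minimum coordinate along each embryo axis, the measure of
#' how far the sperm contents range along the long (x) and short (y) axes
#' within one phase.
#'
#' @param sub_track A [trajectory()] (or data frame with `x_um`, `y_um`).
#' @return Named numeric: `max_x_disp_um`, `max_y_disp_um`.
#' @export
max_axis_displacement <- function(sub_track) {
  sub_track <- as_trajectory(sub_track)
  check_points(sub_track)
  c(max_x_disp_um = diff(range(sub_track$x_um)),
    max_y_disp_um = diff(range(sub_track$y_um)))
}

#' Net displacement of a sub-track
#'
#' Euclidean distance between the first and last point of a phase's track.
#'
#' @inheritParams max_axis_displacement
#' @return Distance in micrometres.
#' @export
net_displacement <- function(sub_track) {
  sub_track <- as_trajectory(sub_track)
  check_points(sub_track)
  n <- nrow(sub_track)
  sqrt((sub_track$x_um[n] - sub_track$x_um[1])^2 +
         (sub_track$y_um[n] - sub_track$y_um[1])^2)
}

#' Path length (distance traveled) of a sub-track
#'
#' Sum of consecutive point-to-point Euclidean distances: the total length of
#' the path the sperm ring traveled during the phase.
#'
#' @inheritParams max_axis_displacement
#' @return Distance in micrometres (0 for a single point).
#' @export
path_length <- function(sub_track) {
  sub_track <- as_trajectory(sub_track)
  check_points(sub_track)
  if (nrow(sub_track) < 2L) return(0)
  sum(sqrt(diff(sub_track$x_um)^2 + diff(sub_track$y_um)^2))
}

#' Maximum moving-average velocity of a sub-track
#'
#' Frame-to-frame speeds are computed as step distance divided by the actual
#' time gap (frame difference times the frame interval, so tracking gaps are
#' handled); trailing moving averages over `window` consecutive speeds are
#' formed and the maximum returned. With k speeds there are k - window + 1
#' averages; phases yielding fewer than `window` speeds return `NA` with an
#' `insufficient_data` attribute rather than an error.
#'
#' @inheritParams max_axis_displacement
#' @param window Number of consecutive speeds per moving average (default 3).
#' @return Speed in um/s, or `NA` when the phase has too few points.
#' @export
max_avg_velocity <- function(sub_track, window = 3L) {
  sub_track <- as_trajectory(sub_track)
  check_points(sub_track)
  dt <- attr(sub_track, "frame_interval_s") %||% 5
  n <- nrow(sub_track)
  if (n < window + 1L)
    return(structure(NA_real_, insufficient_data = TRUE))
  step <- sqrt(diff(sub_track$x_um)^2 + diff(sub_track$y_um)^2)
  gap_s <- diff(sub_track$frame) * dt
  v <- step / gap_s
  k <- length(v)
  avg <- vapply(seq_len(k - window + 1L),
                function(i) mean(v[i:(i + window - 1L)]), numeric(1))
  max(avg)
}

#' Duration of a phase window
#'
#' (last frame - first frame) times the frame interval.
#'
#' @param window One row of a [phase_windows()] frame (or a list with
#'   `first_frame`, `last_frame`).
#' @param frame_interval_s Seconds per frame, default 5.
#' @return Duration in seconds.
#' @examples
#' phase_duration(list(first_frame = 10, last_frame = 70))  # 300 s
#' @export
phase_duration <- function(window, frame_interval_s = 5) {
  (window$last_frame - window$first_frame) * frame_interval_s
}

#' All track metrics for one embryo, per phase
#'
#' Splits a trajectory by phase windows and computes, for each completely
#' filmed phase, the maximum x/y displacement, net displacement, path length,
#' maximum 3-point moving-average velocity and phase duration. Incomplete
#' phases are skipped.
#'
#' @param track A [trajectory()].
#' @param windows A [phase_windows()] frame.
#' @param velocity_window Speeds per moving average (default 3).
#' @return Data frame, one row per quantified phase.
#' @export
track_metrics <- function(track, windows, velocity_window = 3L) {
  track <- as_trajectory(track)
  subs <- split_by_phase(track, windows)
  dt <- attr(track, "frame_interval_s") %||% 5
  rows <- lapply(seq_along(subs), function(i) {
    sub <- subs[[i]]
    if (!isTRUE(attr(sub, "complete")) || nrow(sub) == 0L) return(NULL)
    ax <- max_axis_displacement(sub)
    data.frame(embryo_id = attr(track, "embryo_id"),
               phase = attr(sub, "phase"),
               max_x_disp_um = ax[["max_x_disp_um"]],
               max_y_disp_um = ax[["max_y_disp_um"]],
               net_displacement_um = net_displacement(sub),
               path_length_um = path_length(sub),
               max_avg_velocity_um_s = as.numeric(max_avg_velocity(sub, velocity_window)),
               duration_s = phase_duration(windows[i, ], dt))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
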