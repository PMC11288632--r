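#' Capture-classification parameters
#'
#' A capture event is called when the sperm contents come within
#' `threshold_um` (centre to centre) of the meiotic spindle and then stop
#' moving relative to it. "Stopped moving" is operationalised as some run of
#' `stuck_window_frames` consecutive frames whose cumulative relative
#' displacement is below `stuck_disp_um`; with the 5-s frame interval the
#' defaults ask for less than 1 um of relative motion over 30 s.
#'
#' @param threshold_um Centre-to-centre capture threshold (um), default 5.5.
#' @param stuck_window_frames Frames per stuck test window (>= 2), default 6.
#' @param stuck_disp_um Maximum cumulative relative displacement in a stuck
#'   window (um), default 1.
#' @param max_gap_frames Below-threshold episodes interrupted by tracking
#'   gaps longer than this many frames are split (default 3).
#' @return A list of class `capture_config`.
#' @export
capture_config <- function(threshold_um = 5.5, stuck_window_frames = 6L,
                           stuck_disp_um = 1.0, max_gap_frames = 3L) {
  if (threshold_um <= 0) stop("threshold_um must be positive")
  if (stuck_window_frames < 2L) stop("stuck_window_frames must be >= 2")
  structure(list(threshold_um = threshold_um,
                 stuck_window_frames = as.integer(stuck_window_frames),
                 stuck_disp_um = stuck_disp_um,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "capture_config")
}

#' Per-frame sperm-spindle centre distance
#'
#' Euclidean distance between the two tracked centres at every frame the two
#' tracks share (inner join on frame index). Distances are evaluated on the
#' 2-D projected centres, matching single-focal-plane time-lapse calls.
#'
#' @param sperm_track,spindle_track [trajectory()] objects.
#' @return Data frame `frame`, `distance_um`, `dx_um`, `dy_um` (relative
#'   position components).
#' @export
center_distance_series <- function(sperm_track, spindle_track) {
  a <- as_trajectory(sperm_track); b <- as_trajectory(spindle_track)
  m <- merge(as.data.frame(a), as.data.frame(b), by = "frame",
             suffixes = c("_sperm", "_spindle"))
  if (nrow(m) == 0L) stop("alignment error: tracks share no frames")
  m <- m[order(m$frame), ]
  dx <- m$x_um_sperm - m$x_um_spindle
  dy <- m$y_um_sperm - m$y_um_spindle
  data.frame(frame = m$frame, distance_um = sqrt(dx^2 + dy^2),
             dx_um = dx, dy_um = dy)
}

#' Classify a sperm/spindle approach
#'
#' Identifies below-threshold episodes in the distance series (split at
#' tracking gaps longer than `max_gap_frames`) and classifies the recording:
#' `none` when the distance never drops below the threshold; an episode is
#' *stable* when it persists to the end of the series and contains a stuck
#' window (see [capture_config()]); an episode that ends with the distance
#' rising back above threshold is *transient*. The final label summarises the
#' episode sequence: `stable`, `transient`, `transient_then_stable` or
#' `none`.
#'
#' @param series Output of [center_distance_series()] (or a numeric distance
#'   vector, taken as consecutive frames).
#' @param config A [capture_config()].
#' @param embryo_id Optional identifier.
#' @return A list of class `capture_event`: `embryo_id`, `min_distance_um`,
#'   `approach_frame` (first below-threshold frame, `NA` when none),
#'   `classification`, `n_threshold_crossings` (downward crossings =
#'   below-threshold episodes), `config`.
#' @export
classify_capture <- function(series, config = capture_config(),
                             embryo_id = NA_character_) {
  if (is.numeric(series))
    series <- data.frame(frame = seq_along(series) - 1L,
                         distance_um = series,
                         dx_um = series, dy_um = 0)
  n <- nrow(series)
  if (n < config$stuck_window_frames)
    return(structure(list(embryo_id = embryo_id,
                          min_distance_um = suppressWarnings(min(series$distance_um)),
                          approach_frame = NA_integer_,
                          classification = "insufficient_data",
                          n_threshold_crossings = 0L, config = config),
                     class = "capture_event"))
  below <- series$distance_um < config$threshold_um
  episodes <- episode_runs(below, series$frame, config$max_gap_frames)
  min_d <- min(series$distance_um)
  if (length(episodes) == 0L)
    return(structure(list(embryo_id = embryo_id, min_distance_um = min_d,
                          approach_frame = NA_integer_,
                          classification = "none",
                          n_threshold_crossings = 0L, config = config),
                     class = "capture_event"))
  labels <- vapply(episodes, function(ep) {
    persists <- ep[length(ep)] == n
    stuck <- has_stuck_window(series$dx_um[ep], series$dy_um[ep],
                              config$stuck_window_frames, config$stuck_disp_um)
    if (persists && stuck) "stable" else "transient"
  }, character(1))
  last <- labels[length(labels)]
  classification <-
    if (last == "stable" && length(labels) > 1L) "transient_then_stable"
    else last
  structure(list(embryo_id = embryo_id, min_distance_um = min_d,
                 approach_frame = series$frame[episodes[[1]][1]],
                 classification = classification,
                 n_threshold_crossings = length(episodes), config = config),
            class = "capture_event")
}

#' @export
print.capture_event <- function(x, ...) {
  cat(sprintf("<capture_event> %s: min distance %.2f um, %s (%d below-threshold episode%s)\n",
              ifelse(is.na(x$embryo_id), "embryo", x$embryo_id),
              x$min_distance_um, x$classification,
              x$n_threshold_crossings,
              ifelse(x$n_threshold_crossings == 1L, "", "s")))
  invisible(x)
}

# indices (into the series) of below-threshold runs, split at frame gaps
episode_runs <- function(below, frames, max_gap) {
  idx <- which(below)
  if (length(idx) == 0L) return(list())
  brk <- c(0L, which(diff(idx) > 1L | diff(frames[idx]) > max_gap + 1L),
           length(idx))
  lapply(seq_len(length(brk) - 1L),
         function(i) idx[(brk[i] + 1L):brk[i + 1L]])
}

# TRUE if some run of `win` consecutive frames has cumulative relative path
# length below `tol`
has_stuck_window <- function(dx, dy, win, tol) {
  if (length(dx) < win) return(FALSE)
  step <- sqrt(diff(dx)^2 + diff(dy)^2)
  k <- win - 1L # steps per window of `win` frames
  if (length(step) < k) return(FALSE)
  cs <- cumsum(c(0, step))
  any(cs[(k + 1L):length(cs)] - cs[seq_len(length(cs) - k)] < tol)
}

#' Capture/no-capture contingency table across treatment groups
#'
#' Tallies classified events into a 2 x k table of (captured, not captured)
#' per treatment, ready for Fisher's exact test. `stable` and
#' `transient_then_stable` count as captured.
#'
#' @param events_by_group Named list; each element a list of `capture_event`
#'   objects (or a character vector of classifications).
#' @return Integer matrix with rows `captured`, `not_captured` and one
#'   column per group. Empty groups are retained as zero columns with a
#'   warning.
#' @export
capture_contingency <- function(events_by_group) {
  stopifnot(is.list(events_by_group), length(events_by_group) >= 1L)
  cols <- lapply(events_by_group, function(g) {
    cls <- if (is.character(g)) g
    else vapply(g, function(e) e$classification, character(1))
    if (length(cls) == 0L) {
      warning("empty group retained as zero column")
      return(c(captured = 0L, not_captured = 0L))
    }
    cap <- cls %in% c("stable", "transient_then_stable")
    c(captured = sum(cap), not_captured = sum(!cap))
  })
  tab <- do.call(cbind, cols)
  colnames(tab) <- names(events_by_group)
  tab
}
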