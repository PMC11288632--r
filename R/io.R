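#' Multi-channel calibrated image stack
#'
#' Container for a 3-D multi-channel intensity array with its physical
#' calibration. Voxels are stored as a 4-D array ordered (y, x, z, channel);
#' pixel coordinates are 0-based and physical positions in micrometres are
#' `index * pixel_size_um` (laterally) and `index * z_step_um` (axially).
#'
#' @param voxels 4-D numeric array (y, x, z, channel), intensities >= 0.
#' @param channel_names Character vector, one name per channel.
#' @param pixel_size_um Lateral pixel size (um).
#' @param z_step_um Axial step (um).
#' @param frame_interval_s Frame interval (s) for time-lapse use.
#' @param origin_um Optional length-3 embryo centre in image coordinates.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_names, pixel_size_um, z_step_um = 1,
                        frame_interval_s = 5, origin_um = NULL) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L) stop("voxels must be a (y, x, z, channel) array")
  if (dim(voxels)[4] != length(channel_names))
    stop("channel_names length must match channel dimension")
  if (min(voxels) < 0) stop("intensities must be >= 0")
  if (pixel_size_um <= 0 || z_step_um <= 0)
    stop("calibration values must be positive")
  structure(list(voxels = voxels, channel_names = channel_names,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 frame_interval_s = frame_interval_s, origin_um = origin_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d planes, channels: %s\n  pixel %g um, z-step %g um\n",
              d[2], d[1], d[3], paste(x$channel_names, collapse = ", "),
              x$pixel_size_um, x$z_step_um))
  invisible(x)
}

channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) stop("unknown channel: ", channel)
    ci
  } else as.integer(channel)
}

#' Extract one channel volume or plane from a stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or 1-based index.
#' @param z 0-based plane index (for `get_plane`).
#' @return `get_channel`: 3-D array (y, x, z); `get_plane`: matrix (y, x).
#' @export
get_channel <- function(stack, channel = 1L) {
  stack$voxels[, , , channel_index(stack, channel), drop = FALSE] |>
    array(dim = dim(stack$voxels)[1:3])
}

#' @rdname get_channel
#' @export
get_plane <- function(stack, channel = 1L, z = 0L) {
  stack$voxels[, , z + 1L, channel_index(stack, channel)]
}

#' Write / read a stack as multi-page TIFF with a YAML sidecar
#'
#' The stack is written as a 16-bit multi-page TIFF (pages ordered
#' channel-major: all planes of channel 1, then channel 2, ...) plus a YAML
#' sidecar `<path>.yml` recording dimensions, channel names and calibration,
#' so the round trip is lossless for integer-valued stacks (the camera model
#' in [simulate_zstack()] produces integer counts). Intensities must lie in
#' [0, 65535].
#'
#' @param stack An [image_stack()] with integer-valued voxels.
#' @param path Output TIFF path.
#' @return `write_stack`: the path, invisibly. `read_stack`: an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (max(v) > 65535) stop("intensities exceed 16-bit range")
  if (any(v != round(v))) stop("stack must be integer-valued for lossless storage")
  d <- dim(v)
  pages <- list()
  for (ch in seq_len(d[4])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- v[, , z, ch] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(ny = d[1], nx = d[2], nz = d[3], n_channels = d[4],
                  channel_names = as.list(stack$channel_names),
                  pixel_size_um = stack$pixel_size_um,
                  z_step_um = stack$z_step_um,
                  frame_interval_s = stack$frame_interval_s,
                  origin_um = as.list(stack$origin_um %||% numeric(0)))
  yaml::write_yaml(sidecar, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_stack
#' @param calibration Optional list with `pixel_size_um`, `z_step_um`,
#'   `frame_interval_s` used when no sidecar is present (sidecar values take
#'   precedence).
#' @export
read_stack <- function(path, calibration = NULL) {
  if (!file.exists(path)) stop("read error: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("read error for ", path, ": ", conditionMessage(e)))
  side_path <- paste0(path, ".yml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else NULL
  if (is.null(side)) {
    if (is.null(calibration))
      stop("missing calibration: no sidecar for ", path,
           " and no calibration supplied")
    side <- list(ny = nrow(pages[[1]]), nx = ncol(pages[[1]]),
                 nz = length(pages), n_channels = 1L,
                 channel_names = list("ch1"),
                 pixel_size_um = calibration$pixel_size_um,
                 z_step_um = calibration$z_step_um %||% 1,
                 frame_interval_s = calibration$frame_interval_s %||% 5,
                 origin_um = list())
  }
  nz <- side$nz; nc <- side$n_channels
  v <- array(0, dim = c(side$ny, side$nx, nz, nc))
  i <- 1L
  for (ch in seq_len(nc)) for (z in seq_len(nz)) {
    v[, , z, ch] <- round(pages[[i]] * 65535)
    i <- i + 1L
  }
  image_stack(v, channel_names = unlist(side$channel_names),
              pixel_size_um = side$pixel_size_um, z_step_um = side$z_step_um,
              frame_interval_s = side$frame_interval_s,
              origin_um = if (length(side$origin_um)) unlist(side$origin_um))
}

#' Read trajectories from a track CSV
#'
#' Accepts the native format (columns `track_id`, `frame`, `x`, `y` or
#' `x_um`/`y_um`, optional `embryo_id`, `object`) as well as point lists
#' exported from interactive trackers with columns `TID`/`PID` and pixel
#' coordinates. Pixel inputs are converted to micrometres with the supplied
#' calibration; rows are sorted by frame within track.
#'
#' @param path CSV path.
#' @param calibration List with `pixel_size_um` (and optionally
#'   `frame_interval_s`); required when `units = "px"`.
#' @param units `"um"` or `"px"`.
#' @return Named list of [trajectory()] objects, one per track id.
#' @export
read_tracks <- function(path, calibration = NULL, units = c("um", "px")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, comment.char = "#")
  names(df) <- tolower(names(df))
  if ("tid" %in% names(df) && !"track_id" %in% names(df)) df$track_id <- df$tid
  if ("t" %in% names(df) && !"frame" %in% names(df)) df$frame <- df$t
  if ("x_um" %in% names(df)) { df$x <- df$x_um; df$y <- df$y_um; units <- "um" }
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("format error: track CSV needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("track_id", "frame")]))
    stop("format error: duplicate (track, frame) rows")
  if (units == "px") {
    if (is.null(calibration$pixel_size_um))
      stop("pixel-unit tracks need calibration$pixel_size_um")
    df$x <- df$x * calibration$pixel_size_um
    df$y <- df$y * calibration$pixel_size_um
  }
  dt <- calibration$frame_interval_s %||% 5
  out <- lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$frame), ]
    trajectory(g$frame, g$x, g$y, frame_interval_s = dt,
               embryo_id = as.character(g$embryo_id[1] %||% NA),
               object = if (!is.null(g$object) &&
                            g$object[1] %in% c("sperm_ring", "spindle"))
                 g$object[1] else "sperm_ring")
  })
  out
}

#' Write trajectories to a track CSV
#'
#' @param tracks Named list of [trajectory()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    data.frame(track_id = id,
               embryo_id = attr(tr, "embryo_id"),
               object = attr(tr, "object"),
               frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML mirrors [scene_config()] plus run-level blocks (`groups`,
#' `output_dir`, `seed`, `stages`). Unknown scene fields are rejected by the
#' `scene_config` validator.
#'
#' @param path YAML path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scene_args <- y$scene %||% list()
  if (!is.null(scene_args$embryo))
    scene_args$embryo <- do.call(ellipsoid_dims, scene_args$embryo)
  if (!is.null(scene_args$phase_schedule))
    scene_args$phase_schedule <- unlist(scene_args$phase_schedule)
  structure(list(scene = scene_args,
                 groups = y$groups %||%
                   list(list(name = "control", depletion_mode = "control",
                             n_embryos = 5L)),
                 output_dir = y$output_dir %||% "meioquant_out",
                 seed = as.integer(y$seed %||% 1L),
                 stages = y$stages %||% c("simulate", "scatter", "track",
                                          "capture", "stats")),
            class = "run_config")
}

#' Run the synthetic-cohort pipeline end to end
#'
#' Simulates the configured treatment cohorts, quantifies mitochondrial
#' scatter (from generator ground truth), computes per-phase track metrics,
#' classifies capture events, runs the gated group comparisons, and writes
#' one CSV/TSV per stage into `output_dir`. Every output carries the run
#' seed and the MD5 hash of the resolved configuration, and reruns with the
#' same config and seed are byte-identical.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with
#'   the same fields.
#' @param output_dir Overrides the config's output directory.
#' @return Invisibly, a list with the per-stage data frames and file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- config
  out_dir <- output_dir %||% cfg$output_dir %||% "meioquant_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  cfg_hash <- config_hash(cfg)
  stages <- cfg$stages %||% c("simulate", "scatter", "track", "capture", "stats")
  groups <- cfg$groups
  stamp <- function(df) { df$seed <- seed; df$config_md5 <- cfg_hash; df }
  results <- list()

  # simulate: one scene per embryo per group
  scenes <- list()
  for (g in groups) {
    for (i in seq_len(g$n_embryos)) {
      args <- cfg$scene %||% list()
      args$depletion_mode <- g$depletion_mode
      args$seed <- seed + 1000L * match(g$name, vapply(groups, `[[`, "", "name")) + i
      sc <- do.call(scene_config, args)
      scenes[[paste(g$name, i, sep = "_")]] <-
        list(group = g$name, id = paste(g$name, i, sep = "_"), config = sc)
    }
  }

  if ("scatter" %in% stages) {
    rows <- lapply(scenes, function(s) {
      prof <- scatter_from_ground_truth(sample_mito_cloud(s$config),
                                        dna_position = s$config$dna_position_um,
                                        phase = "AII", embryo_id = s$id)
      data.frame(embryo_id = s$id, group = s$group, phase = prof$phase,
                 n_weighted = prof$n_weighted, mean_um = prof$mean_um,
                 sd_um = prof$sd_um)
    })
    scat <- stamp(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    utils::write.csv(scat, file.path(out_dir, "scatter_profiles.csv"),
                     row.names = FALSE)
    results$scatter <- scat
  }

  tracks <- lapply(scenes, function(s) sample_streaming_trajectory(s$config))

  if ("track" %in% stages) {
    rows <- lapply(names(scenes), function(id) {
      tr <- tracks[[id]]
      wm <- phase_windows(tr$phase_windows$phase, tr$phase_windows$first_frame,
                          tr$phase_windows$last_frame)
      tm <- track_metrics(tr$sperm_track, wm)
      if (is.null(tm) || nrow(tm) == 0L) return(NULL)
      tm$embryo_id <- id; tm$group <- scenes[[id]]$group
      tm
    })
    tm <- stamp(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    utils::write.csv(tm, file.path(out_dir, "track_metrics.csv"),
                     row.names = FALSE)
    results$track <- tm
  }

  if ("capture" %in% stages) {
    rows <- lapply(names(scenes), function(id) {
      tr <- tracks[[id]]
      ev <- classify_capture(center_distance_series(tr$sperm_track,
                                                    tr$spindle_track),
                             embryo_id = id)
      data.frame(embryo_id = id, group = scenes[[id]]$group,
                 min_distance_um = ev$min_distance_um,
                 classification = ev$classification,
                 n_episodes = ev$n_threshold_crossings,
                 threshold_um = ev$config$threshold_um,
                 stuck_window_frames = ev$config$stuck_window_frames,
                 stuck_disp_um = ev$config$stuck_disp_um)
    })
    cap <- stamp(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    utils::write.csv(cap, file.path(out_dir, "capture_events.csv"),
                     row.names = FALSE)
    results$capture <- cap
  }

  if ("stats" %in% stages && length(groups) >= 2L && "scatter" %in% stages) {
    by_group <- split(results$scatter$mean_um, results$scatter$group)
    rep_df <- stamp(stats_report(list(scatter_mean_um = by_group)))
    utils::write.table(rep_df, file.path(out_dir, "stats_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$stats <- rep_df
  }

  results$paths <- list.files(out_dir, full.names = TRUE)
  invisible(results)
}

# MD5 of the canonically serialised configuration (provenance stamp)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  keep <- cfg[setdiff(names(cfg), "output_dir")]
  yaml::write_yaml(keep, tmp)
  unname(tools::md5sum(tmp))
}
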