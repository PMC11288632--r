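#' Detect mitochondrial puncta in a z-stack channel
#'
#' Automates the manual punctum-marking step: each z-plane of the selected
#' channel is Gaussian-smoothed, 3-D local maxima (26-neighbourhood) above an
#' absolute intensity floor are collected, and maxima closer than one ROI
#' diameter (3-D, calibrated) are merged into the brighter one. Detections
#' outside the embryo ellipsoid are discarded, so labelled sperm lying
#' outside the embryo do not contaminate the scatter statistic.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index (default `"mito"`).
#' @param intensity_floor Absolute floor below which maxima are ignored.
#'   Default: background estimate (channel median) plus 10 robust noise SDs.
#' @param smooth_sigma_um Lateral smoothing width (um), default 0.2.
#' @param merge_radius_um Merge radius (um), default 1.17 (one punctum ROI
#'   diameter).
#' @param embryo Optional [ellipsoid_dims()]; with the stack's `origin_um`
#'   this defines the embryo mask used to reject outside detections.
#' @return Data frame `x_um`, `y_um`, `z_um` (image coordinates), `peak`
#'   (smoothed peak intensity), sorted brightest first.
#' @export
detect_puncta <- function(stack, channel = "mito", intensity_floor = NULL,
                          smooth_sigma_um = 0.2, merge_radius_um = 1.17,
                          embryo = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  vol <- get_channel(stack, channel)
  if (all(vol == vol[1]))
    stop("no-signal error: channel is constant")
  px <- stack$pixel_size_um; zs <- stack$z_step_um
  sm <- smooth_channel(vol, smooth_sigma_um / px)
  if (is.null(intensity_floor)) {
    # background is the typical voxel (signal is sparse); require peaks well
    # clear of the residual noise floor after smoothing, and never below a
    # small fraction of the dynamic range (guards noise-free images against
    # floating-point dust from the FFT-based blur)
    bg <- stats::median(sm)
    noise <- stats::mad(as.numeric(sm))
    intensity_floor <- bg + max(10 * noise, 1e-3 * (max(sm) - bg))
  }
  cand <- local_maxima_3d(sm, intensity_floor)
  if (nrow(cand) == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), peak = numeric(0)))
  pos <- cbind(x_um = (cand$x - 1) * px, y_um = (cand$y - 1) * px,
               z_um = (cand$z - 1) * zs)
  keep_mask <- rep(TRUE, nrow(pos))
  if (!is.null(embryo)) {
    ctr <- stack$origin_um %||% c(0, 0, 0)
    # tolerance for voxel discretisation: a peak half a z-step or one pixel
    # outside the ellipsoid still belongs to an in-embryo punctum
    tol <- -(zs / 2 + px)
    keep_mask <- inside_ellipsoid(sweep(pos, 2, ctr), embryo, margin_um = tol)
  }
  pos <- pos[keep_mask, , drop = FALSE]
  peak <- cand$value[keep_mask]
  o <- order(peak, decreasing = TRUE)
  pos <- pos[o, , drop = FALSE]; peak <- peak[o]
  # greedy merge: keep a maximum only if farther than merge radius from all
  # brighter kept maxima
  keep <- integer(0)
  for (i in seq_along(peak)) {
    if (length(keep) == 0L) { keep <- i; next }
    d2 <- (pos[keep, 1] - pos[i, 1])^2 + (pos[keep, 2] - pos[i, 2])^2 +
      (pos[keep, 3] - pos[i, 3])^2
    if (all(d2 >= merge_radius_um^2)) keep <- c(keep, i)
  }
  data.frame(x_um = pos[keep, 1], y_um = pos[keep, 2], z_um = pos[keep, 3],
             peak = peak[keep])
}

# per-plane lateral Gaussian smoothing
smooth_channel <- function(vol, sigma_px) {
  out <- vol
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- EBImage::gblur(vol[, , k], sigma = sigma_px)
  out
}

# strict-or-equal 3-D local maxima above floor; returns 1-based indices.
# a voxel is a maximum if >= all 26 neighbours and > floor.
local_maxima_3d <- function(vol, floor_value) {
  d <- dim(vol)
  is_max <- vol > floor_value
  shift_ok <- function(arr, dy, dx, dz) {
    ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
    ys2 <- pmin(pmax(ys + dy, 1L), d[1])
    xs2 <- pmin(pmax(xs + dx, 1L), d[2])
    zs2 <- pmin(pmax(zs + dz, 1L), d[3])
    arr >= arr[ys2, xs2, zs2, drop = FALSE]
  }
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    is_max <- is_max & shift_ok(vol, dy, dx, dz)
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(y = idx[, 1], x = idx[, 2], z = idx[, 3],
             value = vol[idx])
}

#' Integer multiplicity of an amorphous mitochondrial mass
#'
#' An amorphous mass is brighter than a single punctum because it packs more
#' mitochondria into the same ROI. Its background-corrected ROI mean is
#' divided by the average corrected mean of all distinct puncta in the same
#' embryo and rounded (half-up) to give the number of times its distance to
#' the sperm DNA is recorded; a measured fluorescent region represents at
#' least one mitochondrion, so the minimum is 1. Distinct puncta always have
#' multiplicity 1.
#'
#' @param mass_corrected_mean Background-corrected ROI mean(s) of the mass
#'   measurement(s).
#' @param punctum_mean_of_means Average of the corrected means of all
#'   distinct puncta in the embryo; must be positive.
#' @return Integer multiplicity (vectorised over the first argument).
#' @examples
#' punctum_multiplicity(2.0 * 50, 50)   # 2: distance recorded twice
#' punctum_multiplicity(3.05 * 50, 50)  # 3
#' @export
punctum_multiplicity <- function(mass_corrected_mean, punctum_mean_of_means) {
  if (!is.finite(punctum_mean_of_means) || punctum_mean_of_means <= 0)
    stop("degenerate-embryo error: average punctum intensity must be positive")
  ratio <- pmax(mass_corrected_mean, 0) / punctum_mean_of_means
  as.integer(pmax(1L, round_half_up(ratio)))
}

#' Euclidean distance from a punctum to the sperm DNA
#'
#' 3-D Euclidean distance in micrometres; when punctum and DNA lie in
#' different z-planes the axial offset is the plane difference times the
#' z-step, combined with the in-plane distance by the Pythagorean theorem.
#'
#' @param punctum_position_um,dna_position_um Length-3 positions (um) in the
#'   same calibrated frame, or n x 3 matrices.
#' @return Distance(s) in micrometres.
#' @examples
#' distance_to_dna(c(3, 4, 0), c(0, 0, 0))  # 5
#' @export
distance_to_dna <- function(punctum_position_um, dna_position_um) {
  if (is.null(dna_position_um) || anyNA(dna_position_um))
    stop("annotation error: missing DNA position")
  p <- matrix(as.numeric(unlist(punctum_position_um)), ncol = 3)
  d <- as.numeric(dna_position_um)
  sqrt((p[, 1] - d[1])^2 + (p[, 2] - d[2])^2 + (p[, 3] - d[3])^2)
}

#' Per-embryo scatter profile of paternal mitochondria
#'
#' Builds the multiplicity-weighted distribution of punctum-to-DNA distances
#' for one embryo and phase: each punctum or mass measurement contributes its
#' distance `multiplicity` times, and the mean and sample standard deviation
#' of the weighted list summarise how scattered the paternal mitochondria are
#' around the sperm DNA. Metaphase I embryos are excluded: so soon after
#' fertilisation there has been no time for scattering to develop.
#'
#' @param puncta Data frame with columns `x_um`, `y_um`, `z_um` and
#'   optionally `multiplicity` (default 1).
#' @param dna_position Length-3 DNA centroid (um), same frame as the puncta.
#' @param phase One of `"AI"`, `"MII"`, `"AII"` (`"MI"` is an error).
#' @param embryo_id Optional identifier carried into the result.
#' @return A list of class `scatter_profile`: `embryo_id`, `phase`,
#'   `distances_um` (weighted list), `mean_um`, `sd_um` (`NA` flagged
#'   degenerate when only one weighted distance), `n_weighted`.
#' @export
scatter_profile <- function(puncta, dna_position, phase,
                            embryo_id = NA_character_) {
  if (identical(phase, "MI"))
    stop("excluded-phase error: metaphase I embryos are not quantified")
  if (!phase %in% c("AI", "MII", "AII")) stop("unknown phase: ", phase)
  if (is.null(puncta) || nrow(puncta) == 0L)
    stop("no-data error: no puncta to quantify")
  mult <- puncta$multiplicity %||% rep(1L, nrow(puncta))
  if (any(mult < 1)) stop("multiplicity must be >= 1")
  d <- distance_to_dna(cbind(puncta$x_um, puncta$y_um, puncta$z_um),
                       dna_position)
  w <- rep(d, times = mult)
  structure(list(embryo_id = embryo_id, phase = phase, distances_um = w,
                 mean_um = mean(w),
                 sd_um = if (length(w) > 1L) stats::sd(w) else NA_real_,
                 n_weighted = length(w)),
            class = "scatter_profile")
}

#' @export
print.scatter_profile <- function(x, ...) {
  cat(sprintf("<scatter_profile> %s %s: n = %d weighted distances, mean %.3g um, SD %s um\n",
              ifelse(is.na(x$embryo_id), "", x$embryo_id), x$phase,
              x$n_weighted, x$mean_um,
              ifelse(is.na(x$sd_um), "NA (degenerate)", sprintf("%.3g", x$sd_um))))
  invisible(x)
}

#' Scatter profile from simulator ground truth
#'
#' Convenience route for synthetic cohorts: uses the generator's true punctum
#' positions and multiplicities directly, bypassing detection and intensity
#' measurement.
#'
#' @param truth A `ground_truth` list from [simulate_zstack()] or
#'   [sample_mito_cloud()] output (a puncta data frame is also accepted).
#' @param dna_position DNA centroid; defaults to the truth's.
#' @param phase Quantified phase (default `"AII"`).
#' @param embryo_id Optional identifier.
#' @return A `scatter_profile`.
#' @export
scatter_from_ground_truth <- function(truth, dna_position = NULL,
                                      phase = "AII",
                                      embryo_id = NA_character_) {
  if (inherits(truth, "ground_truth")) {
    puncta <- truth$puncta
    if (is.null(dna_position)) dna_position <- truth$dna_position_um
  } else puncta <- truth
  if (is.null(dna_position)) stop("annotation error: missing DNA position")
  scatter_profile(puncta, dna_position, phase, embryo_id)
}

#' Image-based scatter quantification for one embryo
#'
#' The automated analogue of the manual workflow: detect puncta on the
#' mitochondria channel, measure each with a punctum-sized circular ROI on
#' its z-plane, background-correct using an ROI auto-placed at the
#' lowest-intensity in-embryo location, classify detections much brighter
#' than the cohort (corrected mean above `mass_cutoff` times the median) as
#' amorphous masses, tile each mass's footprint with non-overlapping ROIs,
#' convert mass intensities to integer multiplicities, and assemble the
#' weighted distance profile.
#'
#' @param stack An [image_stack()].
#' @param dna_position_um DNA centroid in image coordinates (um).
#' @param phase Quantified phase.
#' @param channel Mitochondria channel (default `"mito"`).
#' @param roi_diameter_um Measurement ROI diameter (um), default 1.17.
#' @param mass_cutoff A detection is treated as a mass when its corrected
#'   ROI mean exceeds `mass_cutoff` times the median corrected mean of all
#'   detections (default 1.75).
#' @param embryo Optional [ellipsoid_dims()] for in-embryo masking.
#' @param embryo_id Identifier for the output.
#' @param ... Passed to [detect_puncta()].
#' @return A list: `profile` (a `scatter_profile`) and `measurements` (per
#'   detection: position, raw/corrected mean, is_mass, multiplicity).
#' @export
quantify_scatter <- function(stack, dna_position_um, phase,
                             channel = "mito", roi_diameter_um = 1.17,
                             mass_cutoff = 1.75, embryo = NULL,
                             embryo_id = NA_character_, ...) {
  det <- detect_puncta(stack, channel = channel, embryo = embryo, ...)
  if (nrow(det) == 0L) stop("no-data error: no puncta detected")
  px <- stack$pixel_size_um
  dia_px <- roi_diameter_px(roi_diameter_um, px)
  vol <- get_channel(stack, channel)
  nz <- dim(vol)[3]

  # background ROI: lowest-mean disk among a coarse grid of candidate spots
  bg <- background_roi_mean(vol, dia_px, px, embryo, stack$origin_um)

  z_idx <- pmin(pmax(round(det$z_um / stack$z_step_um), 0L), nz - 1L)
  raw <- corrected <- numeric(nrow(det))
  for (i in seq_len(nrow(det))) {
    roi <- roi_spec("disk", center = c(det$x_um[i] / px, det$y_um[i] / px),
                    diameter_px = dia_px, z_index = z_idx[i])
    raw[i] <- measure_roi_mean(vol[, , z_idx[i] + 1L], roi)$mean_intensity
    corrected[i] <- raw[i] - bg
  }

  # a mass is much brighter than a distinct punctum; the cohort median of
  # corrected means is a robust single-punctum reference
  sm <- smooth_channel(vol, 0.2 / px)
  noise <- stats::mad(as.numeric(sm))
  med <- stats::median(corrected)
  if (med <= 0) med <- max(corrected)
  is_mass <- corrected > mass_cutoff * med
  if (all(is_mass)) is_mass[which.min(corrected)] <- FALSE # need a punctum reference
  punc_mean <- mean(pmax(corrected[!is_mass], 0))

  # distinct puncta contribute one ROI each; masses are tiled with
  # non-overlapping punctum-sized ROIs across their footprint and every tile
  # contributes its own intensity-derived multiplicity at its own position
  rows <- list()
  for (i in seq_len(nrow(det))) {
    if (!is_mass[i]) {
      rows[[length(rows) + 1L]] <-
        data.frame(x_um = det$x_um[i], y_um = det$y_um[i], z_um = det$z_um[i],
                   raw_mean = raw[i], corrected_mean = corrected[i],
                   is_mass = FALSE, multiplicity = 1L)
    } else {
      tiles <- tile_mass_rois(vol, sm, det[i, ], z_idx[i], dia_px, bg, px, noise)
      tiles$multiplicity <- punctum_multiplicity(tiles$corrected_mean, punc_mean)
      tiles$z_um <- z_idx[i] * stack$z_step_um
      tiles$is_mass <- TRUE
      rows[[length(rows) + 1L]] <-
        tiles[, c("x_um", "y_um", "z_um", "raw_mean", "corrected_mean",
                  "is_mass", "multiplicity")]
    }
  }
  meas <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  prof <- scatter_profile(meas, dna_position_um, phase, embryo_id)
  list(profile = prof, measurements = meas, background_mean = bg)
}

# non-overlapping punctum-sized ROIs covering a mass's above-threshold
# footprint on its detection plane (the measure-move-measure procedure);
# footprint from the smoothed plane, ROI means from the raw plane
tile_mass_rois <- function(vol, sm, det_row, z_idx, dia_px, bg, px, noise) {
  d <- dim(vol)
  plane <- vol[, , z_idx + 1L]
  lab <- EBImage::bwlabel(sm[, , z_idx + 1L] >
                            mass_threshold(bg, det_row$peak, noise))
  xi <- min(max(round(det_row$x_um / px) + 1L, 1L), d[2])
  yi <- min(max(round(det_row$y_um / px) + 1L, 1L), d[1])
  id <- lab[yi, xi]
  mask <- lab == id
  idx <- which(mask, arr.ind = TRUE)
  step <- dia_px
  # grid anchored at the detection centre so the brightest tile is central
  gx <- unique(round(xi + step * (ceiling((min(idx[, 2]) - xi) / step):
                                    floor((max(idx[, 2]) - xi) / step))))
  gy <- unique(round(yi + step * (ceiling((min(idx[, 1]) - yi) / step):
                                    floor((max(idx[, 1]) - yi) / step))))
  out <- list()
  r <- dia_px / 2
  for (x0 in gx) for (y0 in gy) {
    if (x0 < r + 1 || y0 < r + 1 || x0 > d[2] - r || y0 > d[1] - r) next
    if (!mask[y0, x0]) next
    roi <- roi_spec("disk", center = c(x0 - 1L, y0 - 1L), diameter_px = dia_px)
    m <- measure_roi_mean(plane, roi)$mean_intensity
    out[[length(out) + 1L]] <- data.frame(x_um = (x0 - 1L) * px,
                                          y_um = (y0 - 1L) * px,
                                          raw_mean = m,
                                          corrected_mean = m - bg)
  }
  if (length(out) == 0L) # footprint thinner than one ROI: measure the centre
    out[[1L]] <- data.frame(
      x_um = det_row$x_um, y_um = det_row$y_um,
      raw_mean = measure_roi_mean(plane, roi_spec(
        "disk", center = c(xi - 1L, yi - 1L),
        diameter_px = dia_px))$mean_intensity,
      corrected_mean = NA_real_)
  res <- do.call(rbind, out)
  res$corrected_mean <- res$raw_mean - bg
  res
}

# footprint threshold: a quarter of the way from background to the peak, but
# never within 8 robust noise SDs of background
mass_threshold <- function(bg, peak, noise) {
  max(bg + 0.25 * (peak - bg), bg + 8 * noise)
}

# mean of the dimmest candidate background disk (coarse grid, in-embryo)
background_roi_mean <- function(vol, dia_px, px, embryo, origin_um) {
  d <- dim(vol)
  r <- ceiling(dia_px / 2) + 1L
  xs <- seq(r, d[2] - r, length.out = min(12, max(1, d[2] - 2 * r)))
  ys <- seq(r, d[1] - r, length.out = min(12, max(1, d[1] - 2 * r)))
  zmid <- ceiling(d[3] / 2)
  best <- Inf
  for (x0 in round(xs)) for (y0 in round(ys)) {
    if (!is.null(embryo)) {
      p <- c((x0 - 1) * px, (y0 - 1) * px, 0) - (origin_um %||% c(0, 0, 0)) * c(1, 1, 0)
      if (!inside_ellipsoid(matrix(c(p[1], p[2], 0), 1), embryo, margin_um = 1))
        next
    }
    roi <- roi_spec("disk", center = c(x0 - 1, y0 - 1), diameter_px = dia_px)
    m <- tryCatch(measure_roi_mean(vol[, , zmid], roi)$mean_intensity,
                  error = function(e) Inf)
    if (m < best) best <- m
  }
  if (!is.finite(best)) stop("no-data error: could not place background ROI")
  best
}

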