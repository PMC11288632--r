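#' Scene configuration for the synthetic zygote generator
#'
#' Bundles every parameter of the simulator: embryo geometry, imaging
#' calibration, the paternal-mitochondria cloud, rendering, the cytoplasmic
#' streaming regime, depletion mode, capture scenario and the meiotic phase
#' schedule. Defaults reproduce the canonical imaging conditions: a
#' 50 x 25 x 25 um ellipsoidal embryo, 65-nm pixels, 1-um z-steps and 5-s
#' frame intervals.
#'
#' @param embryo [ellipsoid_dims()]: embryo semi-axes (um).
#' @param pixel_size_um Lateral pixel size (um), default 0.065.
#' @param z_step_um Axial step between planes (um), default 1.
#' @param frame_interval_s Time between frames (s), default 5.
#' @param n_puncta Number of distinct mitochondrial puncta (>= 1).
#' @param n_masses Number of amorphous mitochondrial masses (>= 0).
#' @param punctum_intensity_mean,punctum_intensity_cv Mean and coefficient of
#'   variation of the integrated intensity of a single punctum (arbitrary
#'   units).
#' @param mass_intensity_factor Mean multiplicity of a mass, i.e. how many
#'   punctum-equivalents it contains on average (>= 1).
#' @param cloud_sigma_um Isotropic standard deviation (um) of mitochondria
#'   positions about the sperm DNA.
#' @param psf_sigma_um,psf_sigma_z_um Lateral and axial Gaussian blur widths
#'   (um) applied to every rendered focus.
#' @param background_level,noise_sd Additive background and Gaussian noise
#'   (intensity units) of the camera model.
#' @param streaming_mode One of `"jostle"`, `"short_axis"`, `"long_axis"`:
#'   jostling is undirected random motion, the other two are rotational
#'   streaming regimes named for the embryo axis about which the cytoplasm
#'   rotates.
#' @param streaming_amplitude_um_s Characteristic streaming speed of the
#'   sperm contents (um/s) under control conditions.
#' @param depletion_mode One of `"control"`, `"mei1_like"`, `"klp7_like"`,
#'   `"atx2_like"`, `"double_klp7_atx2"`; see [apply_depletion_mode()].
#' @param capture_scenario One of `"none"`, `"stable"`, `"transient"`;
#'   see [simulate_capture_scenario()].
#' @param phase_schedule Named numeric vector of phase durations in seconds,
#'   over a contiguous subsequence of `MI`, `AI`, `MII`, `AII`.
#' @param dna_position_um Length-3 sperm-DNA centroid in the canonical
#'   embryo frame (um).
#' @param seed Integer seed; every generator call is deterministic given the
#'   same config.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(embryo = ellipsoid_dims(25, 12.5, 12.5),
                         pixel_size_um = 0.065,
                         z_step_um = 1.0,
                         frame_interval_s = 5.0,
                         n_puncta = 30L,
                         n_masses = 3L,
                         punctum_intensity_mean = 2000,
                         punctum_intensity_cv = 0.25,
                         mass_intensity_factor = 3,
                         cloud_sigma_um = 1.0,
                         psf_sigma_um = 0.3,
                         psf_sigma_z_um = 0.75,
                         background_level = 100,
                         noise_sd = 5,
                         streaming_mode = c("jostle", "short_axis", "long_axis"),
                         streaming_amplitude_um_s = 0.05,
                         depletion_mode = c("control", "mei1_like", "klp7_like",
                                            "atx2_like", "double_klp7_atx2"),
                         capture_scenario = c("none", "stable", "transient"),
                         phase_schedule = c(MI = 480, AI = 300, MII = 480, AII = 300),
                         dna_position_um = c(15, 0, 0),
                         seed = 1L) {
  streaming_mode <- match.arg(streaming_mode)
  depletion_mode <- match.arg(depletion_mode)
  capture_scenario <- match.arg(capture_scenario)
  embryo <- as_ellipsoid_dims(embryo)
  if (pixel_size_um <= 0 || z_step_um <= 0 || frame_interval_s <= 0)
    stop("config error: calibration values must be positive")
  if (n_puncta < 1L) stop("config error: n_puncta must be >= 1")
  if (n_masses < 0L) stop("config error: n_masses must be >= 0")
  if (mass_intensity_factor < 1) stop("config error: mass_intensity_factor must be >= 1")
  if (cloud_sigma_um <= 0 || psf_sigma_um <= 0 || psf_sigma_z_um <= 0)
    stop("config error: scale parameters must be positive")
  if (streaming_amplitude_um_s < 0)
    stop("config error: streaming amplitude must be non-negative")
  validate_phase_schedule(phase_schedule)
  if (length(dna_position_um) != 3L)
    stop("config error: dna_position_um must have length 3")
  if (!inside_ellipsoid(matrix(dna_position_um, 1), embryo))
    stop("config error: DNA position outside the embryo")
  cfg <- list(embryo = embryo, pixel_size_um = pixel_size_um,
              z_step_um = z_step_um, frame_interval_s = frame_interval_s,
              n_puncta = as.integer(n_puncta), n_masses = as.integer(n_masses),
              punctum_intensity_mean = punctum_intensity_mean,
              punctum_intensity_cv = punctum_intensity_cv,
              mass_intensity_factor = mass_intensity_factor,
              cloud_sigma_um = cloud_sigma_um,
              psf_sigma_um = psf_sigma_um, psf_sigma_z_um = psf_sigma_z_um,
              background_level = background_level, noise_sd = noise_sd,
              streaming_mode = streaming_mode,
              streaming_amplitude_um_s = streaming_amplitude_um_s,
              depletion_mode = depletion_mode,
              capture_scenario = capture_scenario,
              phase_schedule = phase_schedule,
              dna_position_um = as.numeric(dna_position_um),
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

phase_order <- c("MI", "AI", "MII", "AII")

validate_phase_schedule <- function(sched) {
  if (length(sched) == 0L) stop("config error: empty phase schedule")
  ph <- names(sched)
  if (is.null(ph) || !all(ph %in% phase_order))
    stop("config error: phase names must be among MI, AI, MII, AII")
  idx <- match(ph, phase_order)
  if (any(diff(idx) != 1L) && length(idx) > 1L)
    stop("config error: phases must be a contiguous subsequence of MI, AI, MII, AII")
  if (any(sched <= 0)) stop("config error: phase durations must be positive")
  invisible(TRUE)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<scene_config> embryo %g x %g x %g um semi-axes; %d puncta + %d masses",
    " (cloud sigma %g um)\n  streaming: %s @ %g um/s; depletion: %s;",
    " capture: %s; seed %d\n"),
    x$embryo$a_um, x$embryo$b_um, x$embryo$c_um, x$n_puncta, x$n_masses,
    x$cloud_sigma_um, x$streaming_mode, x$streaming_amplitude_um_s,
    x$depletion_mode, x$capture_scenario, x$seed))
  invisible(x)
}

#' Effective parameter multipliers for a depletion mode
#'
#' Depletion phenotypes are modelled as multiplicative changes to two scene
#' parameters: katanin- or kinesin-13-like depletions (`mei1_like`,
#' `klp7_like`) raise the streaming amplitude, an ataxin-2-like depletion
#' (`atx2_like`) disperses the mitochondrial cloud (larger cloud sigma), and
#' the double depletion compounds the kinesin-13 and ataxin-2 effects.
#' `klp7_like` additionally maintains its elevated streaming amplitude into
#' meiosis II (see [sample_streaming_trajectory()]).
#'
#' @param mode A depletion mode name or a [scene_config()].
#' @return Named numeric vector: `streaming` and `cloud` multipliers.
#' @examples
#' apply_depletion_mode("control")     # c(streaming = 1, cloud = 1)
#' apply_depletion_mode("atx2_like")
#' @export
apply_depletion_mode <- function(mode) {
  if (inherits(mode, "scene_config")) mode <- mode$depletion_mode
  tab <- list(control          = c(streaming = 1.0, cloud = 1.0),
              mei1_like        = c(streaming = 3.0, cloud = 1.0),
              klp7_like        = c(streaming = 2.5, cloud = 1.0),
              atx2_like        = c(streaming = 1.0, cloud = 3.0),
              double_klp7_atx2 = c(streaming = 2.5, cloud = 3.0))
  if (!is.character(mode) || length(mode) != 1L || is.na(match(mode, names(tab))))
    stop("config error: unknown depletion mode '", paste(mode, collapse = ","), "'")
  tab[[mode]]
}

# phase-dependent streaming attenuation: streaming normally subsides after
# meiosis I; klp7-like depletion keeps it elevated through meiosis II.
phase_amplitude_factor <- function(phase, depletion_mode) {
  late <- phase %in% c("MII", "AII")
  keep_late <- depletion_mode %in% c("klp7_like", "double_klp7_atx2")
  ifelse(late & !keep_late, 0.4, 1.0)
}

# frames and per-frame phase labels implied by the schedule
schedule_frames <- function(cfg) {
  dur <- cfg$phase_schedule
  dt <- cfg$frame_interval_s
  n_per <- pmax(1L, round(dur / dt))
  phase <- rep(names(dur), n_per)
  n <- length(phase)
  first <- cumsum(c(0L, n_per[-length(n_per)]))
  windows <- data.frame(phase = names(dur), first_frame = first,
                        last_frame = first + n_per - 1L)
  list(n_frames = n, phase = phase, windows = windows)
}

#' Sample the paternal-mitochondria cloud
#'
#' Draws punctum and mass positions from an isotropic 3-D Gaussian centred on
#' the sperm DNA (standard deviation `cloud_sigma_um` scaled by the depletion
#' mode's cloud multiplier), rejecting draws that fall outside the embryo
#' ellipsoid. Masses are k-fold clusters: each carries an integer ground-truth
#' multiplicity k >= 2 with mean `mass_intensity_factor`, and is rendered (and
#' measured) about k times brighter than a single punctum.
#'
#' @param config A [scene_config()].
#' @return A data frame with columns `x_um`, `y_um`, `z_um` (embryo-centred),
#'   `intensity` (integrated, punctum-equivalent scaled), `multiplicity`
#'   (integer >= 1) and `is_mass`.
#' @export
sample_mito_cloud <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  mult <- apply_depletion_mode(config)
  sigma <- config$cloud_sigma_um * mult[["cloud"]]
  n_tot <- config$n_puncta + config$n_masses
  pos <- place_in_embryo(n_tot, config$dna_position_um, sigma, config$embryo)
  is_mass <- rep(c(FALSE, TRUE), c(config$n_puncta, config$n_masses))
  k <- rep(1L, n_tot)
  if (config$n_masses > 0)
    k[is_mass] <- pmax(2L, 1L + stats::rpois(config$n_masses,
                                             config$mass_intensity_factor - 1))
  base <- stats::rnorm(n_tot, config$punctum_intensity_mean,
                       config$punctum_intensity_cv * config$punctum_intensity_mean)
  base <- pmax(base, 0.05 * config$punctum_intensity_mean)
  data.frame(x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
             intensity = base * k, multiplicity = k, is_mass = is_mass)
}

# rejection-sample n points from N(centre, sigma^2 I3) inside the embryo
place_in_embryo <- function(n, centre, sigma, dims, max_attempts = 10000L) {
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- centre + stats::rnorm(3, 0, sigma)
      if (inside_ellipsoid(matrix(p, 1), dims)) { out[i, ] <- p; ok <- TRUE; break }
    }
    if (!ok) stop("placement error: could not place point inside embryo after ",
                  max_attempts, " attempts (cloud sigma too large?)")
  }
  out
}

#' Simulate a multi-channel z-stack with ground truth
#'
#' Renders a three-channel (`mito`, `dna`, `tubulin`) z-stack of a fixed
#' meiotic embryo: every mitochondrial focus is a 3-D Gaussian of lateral
#' width `psf_sigma_um` and axial width `psf_sigma_z_um` whose voxel sum
#' equals its integrated intensity; masses are k-fold clusters of overlapping
#' Gaussians so their summed local intensity is about k times the punctum
#' mean. The sperm DNA and the spindle are rendered as single blobs in their
#' own channels. Additive background and Gaussian read noise complete the
#' camera model; with `quantize = TRUE` (default) voxel values are rounded to
#' non-negative integer counts, as a camera would record.
#'
#' @param config A [scene_config()].
#' @param quantize Round voxel values to integer counts (default `TRUE`).
#'   Disable to compare rendered intensities against analytic integrals.
#' @return A list with elements `stack` (an `image_stack`, see
#'   [image_stack()]) and `truth` (a `ground_truth` list: `dna_position_um`,
#'   `puncta`, `spindle_track`, `sperm_track`, `phase_windows`,
#'   `capture_frame`).
#' @export
simulate_zstack <- function(config, quantize = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  puncta <- sample_mito_cloud(config)  # seeds the RNG
  dims <- config$embryo
  px <- config$pixel_size_um; zs <- config$z_step_um
  nx <- ceiling(2 * dims$a_um / px); ny <- ceiling(2 * dims$b_um / px)
  nz <- floor(2 * dims$c_um / zs) + 1L
  centre <- c(dims$a_um, dims$b_um, dims$c_um)  # embryo centre in image um
  vox <- array(0, dim = c(ny, nx, nz, 3))

  add_gaussian <- function(ch, pos_um, total, sx, sz) {
    # pos_um embryo-centred -> image coordinates
    p <- pos_um + centre
    cx <- p[1] / px; cy <- p[2] / px; cz <- p[3] / zs  # 0-based voxel coords
    wx <- ceiling(4 * sx / px); wz <- ceiling(4 * sz / zs)
    ix <- max(0L, floor(cx - wx)):min(nx - 1L, ceiling(cx + wx))
    iy <- max(0L, floor(cy - wx)):min(ny - 1L, ceiling(cy + wx))
    iz <- max(0L, floor(cz - wz)):min(nz - 1L, ceiling(cz + wz))
    if (!length(ix) || !length(iy) || !length(iz)) return(invisible())
    gx <- stats::dnorm(ix * px, p[1], sx) * px
    gy <- stats::dnorm(iy * px, p[2], sx) * px
    gz <- stats::dnorm(iz * zs, p[3], sz) * zs
    patch <- outer(gy, gx) # y rows, x cols
    for (k in seq_along(iz))
      vox[iy + 1L, ix + 1L, iz[k] + 1L, ch] <<-
        vox[iy + 1L, ix + 1L, iz[k] + 1L, ch] + total * gz[k] * patch
    invisible()
  }

  # mitochondria channel: puncta as single Gaussians, masses as k-fold
  # clusters of punctum-equivalents jittered by 0.1 um
  for (i in seq_len(nrow(puncta))) {
    p <- c(puncta$x_um[i], puncta$y_um[i], puncta$z_um[i])
    k <- puncta$multiplicity[i]
    unit <- puncta$intensity[i] / k
    if (k == 1L) {
      add_gaussian(1L, p, unit, config$psf_sigma_um, config$psf_sigma_z_um)
    } else {
      # amorphous mass: k punctum-equivalents spread over ~0.5 um so the
      # footprint is visibly larger than a single punctum
      for (j in seq_len(k)) {
        jit <- stats::rnorm(3, 0, c(0.5, 0.5, 0.25))
        add_gaussian(1L, p + jit, unit, config$psf_sigma_um, config$psf_sigma_z_um)
      }
    }
  }
  # DNA channel: compact blob at the sperm DNA
  add_gaussian(2L, config$dna_position_um,
               20 * config$punctum_intensity_mean, 0.4, config$psf_sigma_z_um)
  # tubulin channel: spindle blob near the left pole
  spindle_pos <- c(-0.8 * dims$a_um, 0, 0)
  add_gaussian(3L, spindle_pos, 60 * config$punctum_intensity_mean,
               1.2, config$psf_sigma_z_um)

  vox <- vox + config$background_level
  if (config$noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, config$noise_sd)
  vox <- pmax(vox, 0)
  if (quantize) vox <- round(vox)
  dim(vox) <- c(ny, nx, nz, 3)

  stack <- image_stack(vox, channel_names = c("mito", "dna", "tubulin"),
                       pixel_size_um = px, z_step_um = zs,
                       frame_interval_s = config$frame_interval_s,
                       origin_um = centre)
  truth <- structure(list(dna_position_um = config$dna_position_um,
                          puncta = puncta,
                          spindle_track = NULL, sperm_track = NULL,
                          phase_windows = NULL, capture_frame = NA_integer_),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Simulate sperm-content and spindle trajectories under a streaming regime
#'
#' Generates paired 2-D tracks sampled at the frame interval over the phase
#' schedule. The sperm track follows a regime-dependent deterministic path
#' plus seeded jitter: a zero-mean random walk for `jostle`, a circular arc
#' (predominantly y motion) for `short_axis`, and an x-directed excursion for
#' `long_axis`. The streaming amplitude is scaled by the depletion mode's
#' streaming multiplier and, except for kinesin-13-like depletions, is
#' attenuated after meiosis I. The spindle track is nearly stationary near
#' the left pole. All points are kept inside the embryo ellipse.
#'
#' @param config A [scene_config()].
#' @return A list with `sperm_track` and `spindle_track` ([trajectory()]
#'   objects), `phase_windows` (data frame `phase`, `first_frame`,
#'   `last_frame`) and `capture_frame` (NA unless a capture scenario was
#'   programmed; see [simulate_capture_scenario()]).
#' @export
sample_streaming_trajectory <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (config$capture_scenario != "none")
    return(simulate_capture_scenario(config))
  set.seed(config$seed + 1L)
  sim_tracks(config, keep_away_um = NA)
}

# core kinematics shared by the plain and capture-aware generators.
# keep_away_um: if finite, sperm steps that would bring it closer than this
# to the spindle are rejected (used for programmed "none" capture cohorts).
sim_tracks <- function(config, keep_away_um = NA) {
  sched <- schedule_frames(config)
  n <- sched$n_frames
  dt <- config$frame_interval_s
  dims <- config$embryo
  mult <- apply_depletion_mode(config)[["streaming"]]
  amp <- config$streaming_amplitude_um_s * mult
  phf <- phase_amplitude_factor(sched$phase, config$depletion_mode)

  spindle0 <- c(-0.8 * dims$a_um, 0)
  spindle <- cbind(spindle0[1] + cumsum(stats::rnorm(n, 0, 0.01)),
                   spindle0[2] + cumsum(stats::rnorm(n, 0, 0.01)))

  start <- c(0.6 * dims$a_um, 0)
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- start
  jitter_sd <- 0.02

  if (config$streaming_mode == "jostle") {
    # isotropic random walk; per-frame step length ~ Rayleigh with mean amp*dt
    e_step <- amp * dt
    ray_sigma <- e_step / sqrt(pi / 2)
    for (i in 2:n) {
      step_ok <- FALSE
      for (try in 1:200) {
        r <- if (ray_sigma > 0) ray_sigma * sqrt(-2 * log(stats::runif(1))) else 0
        th <- stats::runif(1, 0, 2 * pi)
        cand <- pos[i - 1, ] + phf[i] * r * c(cos(th), sin(th))
        if (inside_ellipsoid(matrix(cand, 1), dims, margin_um = 1) &&
            (is.na(keep_away_um) ||
             sqrt(sum((cand - spindle[i, ])^2)) >= keep_away_um)) {
          pos[i, ] <- cand; step_ok <- TRUE; break
        }
      }
      if (!step_ok) pos[i, ] <- pos[i - 1, ]
    }
  } else {
    tt <- (seq_len(n) - 1L) * dt
    if (config$streaming_mode == "short_axis") {
      # rotation about the short axis seen as a circular arc, motion mostly in y
      radius <- min(0.25 * dims$b_um * mult, 0.8 * dims$b_um)
      omega <- if (radius > 0) amp / radius else 0
      base <- cbind(start[1] + radius * (cos(omega * tt) - 1),
                    start[2] + radius * sin(omega * tt))
    } else { # long_axis: x-directed excursion toward the spindle pole and back
      exc <- min(0.45 * dims$a_um * mult, 1.3 * dims$a_um)
      period <- max(2 * exc * pi / max(amp, 1e-9), 4 * dt)
      base <- cbind(start[1] - exc * (1 - cos(2 * pi * tt / period)) / 2,
                    start[2])
    }
    jit <- cbind(cumsum(stats::rnorm(n, 0, jitter_sd)),
                 cumsum(stats::rnorm(n, 0, jitter_sd)))
    scalefac <- ifelse(phf < 1, phf, 1)
    dev <- (base - matrix(start, n, 2, byrow = TRUE)) * scalefac
    pos <- matrix(start, n, 2, byrow = TRUE) + dev + jit
    # clamp into the embryo
    bad <- !inside_ellipsoid(pos, dims, margin_um = 1)
    if (any(bad)) {
      sc <- sqrt((pos[bad, 1] / (dims$a_um - 1))^2 + (pos[bad, 2] / (dims$b_um - 1))^2)
      pos[bad, ] <- pos[bad, , drop = FALSE] / sc * 0.999
    }
  }

  frames <- seq_len(n) - 1L
  list(sperm_track = trajectory(frames, pos[, 1], pos[, 2],
                                frame_interval_s = dt, object = "sperm_ring"),
       spindle_track = trajectory(frames, spindle[, 1], spindle[, 2],
                                  frame_interval_s = dt, object = "spindle"),
       phase_windows = sched$windows,
       capture_frame = NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a programmed sperm/spindle capture scenario
#'
#' Produces paired tracks in which the sperm-spindle centre-to-centre
#' distance follows a programmed profile: `"stable"` approaches below the
#' 5.5-um capture threshold once and then stays essentially motionless
#' relative to the spindle; `"transient"` dips below the threshold, departs,
#' then re-approaches and sticks (two below-threshold episodes);
#' `"none"` streams with the configured regime but is constrained never to
#' come closer than 8 um to the spindle.
#'
#' @param config A [scene_config()]; `capture_scenario` selects the profile.
#' @param threshold_um Capture threshold used to programme the approach
#'   (default 5.5 um).
#' @return Same structure as [sample_streaming_trajectory()];
#'   `capture_frame` is the first frame of the final below-threshold episode
#'   (NA for `"none"`).
#' @export
simulate_capture_scenario <- function(config, threshold_um = 5.5) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed + 1L)
  if (config$capture_scenario == "none")
    return(sim_tracks(config, keep_away_um = 8))

  sched <- schedule_frames(config)
  n <- max(sched$n_frames, 40L)
  dt <- config$frame_interval_s
  dims <- config$embryo
  spindle0 <- c(-0.8 * dims$a_um, 0)
  spindle <- cbind(spindle0[1] + cumsum(stats::rnorm(n, 0, 0.005)),
                   spindle0[2] + cumsum(stats::rnorm(n, 0, 0.005)))

  d_far <- min(0.45 * 2 * dims$a_um, 18)
  d_capt <- 0.75 * threshold_um
  if (d_capt >= d_far)
    stop("config error: capture geometry impossible inside embryo")
  u <- function(k, k0, k1) pmin(1, pmax(0, (k - k0) / max(1, k1 - k0)))
  k <- seq_len(n)
  if (config$capture_scenario == "stable") {
    cap_start <- floor(n * 0.4)
    d <- d_far + (d_capt - d_far) * u(k, 1, cap_start)
  } else { # transient: below, back above, then final stable approach
    k1 <- floor(n * 0.25); k2 <- floor(n * 0.45); k3 <- floor(n * 0.7)
    d_mid <- max(1.5 * threshold_um, 8.5)
    d <- ifelse(k <= k1, d_far + (d_capt - d_far) * u(k, 1, k1),
         ifelse(k <= k2, d_capt + (d_mid - d_capt) * u(k, k1, k2),
         ifelse(k <= k3, d_mid + (d_capt - d_mid) * u(k, k2, k3), d_capt)))
    cap_start <- k3
  }
  # once captured, relative motion freezes (tiny residual jitter)
  stuck <- k >= cap_start
  jit <- 0.003 * cumsum(stats::rnorm(n))
  d[stuck] <- d[cap_start] + jit[stuck] - jit[cap_start]
  ang <- 0.15 * sin(2 * pi * k / n) # slow bearing drift during approach
  ang[stuck] <- ang[cap_start]
  sperm <- spindle + cbind(d * cos(ang), d * sin(ang))

  frames <- k - 1L
  capture_frame <- frames[min(which(d < threshold_um & stuck | k == cap_start))]
  list(sperm_track = trajectory(frames, sperm[, 1], sperm[, 2],
                                frame_interval_s = dt, object = "sperm_ring"),
       spindle_track = trajectory(frames, spindle[, 1], spindle[, 2],
                                  frame_interval_s = dt, object = "spindle"),
       phase_windows = sched$windows,
       capture_frame = as.integer(capture_frame))
}
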