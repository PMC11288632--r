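test_that("generators are deterministic under a fixed seed", {
  cfg <- small_scene(seed = 3, n_masses = 1, noise_sd = 2, background_level = 50)
  a <- simulate_zstack(cfg)
  b <- simulate_zstack(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$puncta, b$truth$puncta)

  cfg2 <- scene_config(seed = 5, streaming_mode = "jostle")
  t1 <- sample_streaming_trajectory(cfg2)
  t2 <- sample_streaming_trajectory(cfg2)
  expect_identical(as.data.frame(t1$sperm_track), as.data.frame(t2$sperm_track))
  expect_identical(as.data.frame(t1$spindle_track), as.data.frame(t2$spindle_track))
})

test_that("ground truth counts and in-embryo placement hold", {
  cfg <- scene_config(n_puncta = 20, n_masses = 0, seed = 2)
  cloud <- sample_mito_cloud(cfg)
  expect_equal(nrow(cloud), 20)
  expect_true(all(cloud$multiplicity == 1L))
  p <- cbind(cloud$x_um, cloud$y_um, cloud$z_um)
  e <- cfg$embryo
  expect_true(all((p[, 1] / e$a_um)^2 + (p[, 2] / e$b_um)^2 +
                    (p[, 3] / e$c_um)^2 <= 1))

  tr <- sample_streaming_trajectory(scene_config(seed = 9,
                                                 streaming_mode = "short_axis"))
  pts <- cbind(tr$sperm_track$x_um, tr$sperm_track$y_um)
  expect_true(all((pts[, 1] / 25)^2 + (pts[, 2] / 12.5)^2 <= 1 + 1e-9))
})

test_that("an impossible cloud placement errors out", {
  cfg <- scene_config(seed = 1)
  expect_error(
    meioquant:::place_in_embryo(1, c(25.5, 0, 0), 1e-6,
                                cfg$embryo, max_attempts = 50),
    "placement")
})

test_that("rendered punctum intensity matches the analytic Gaussian integral", {
  cfg <- scene_config(embryo = ellipsoid_dims(6, 4, 4), pixel_size_um = 0.1,
                      n_puncta = 1, n_masses = 0, cloud_sigma_um = 0.5,
                      punctum_intensity_cv = 0, noise_sd = 0,
                      background_level = 0, dna_position_um = c(0, 0, 0),
                      seed = 4)
  sim <- simulate_zstack(cfg, quantize = FALSE)
  total <- sum(get_channel(sim$stack, "mito"))
  expect_equal(total, sim$truth$puncta$intensity[1], tolerance = 0.01)
})

test_that("depletion modes map to the documented multipliers", {
  expect_equal(apply_depletion_mode("control"), c(streaming = 1, cloud = 1))
  atx <- apply_depletion_mode("atx2_like")
  expect_equal(atx[["streaming"]], 1.0)
  expect_gt(atx[["cloud"]], 1)
  dbl <- apply_depletion_mode("double_klp7_atx2")
  expect_gt(dbl[["streaming"]], 1)
  expect_gt(dbl[["cloud"]], 1)
  expect_gt(apply_depletion_mode("mei1_like")[["streaming"]], 1)
  expect_error(apply_depletion_mode("unknown_mode"), "config error")
})

test_that("zero-amplitude jostling leaves the sperm track stationary", {
  cfg <- scene_config(streaming_amplitude_um_s = 0, seed = 6)
  tr <- sample_streaming_trajectory(cfg)
  expect_equal(diff(range(tr$sperm_track$x_um)), 0)
  expect_equal(diff(range(tr$sperm_track$y_um)), 0)
})

test_that("depletion raises long-axis excursion for the same seed", {
  base <- list(streaming_mode = "long_axis", seed = 12)
  ctrl <- do.call(scene_config, c(base, list(depletion_mode = "control")))
  mei <- do.call(scene_config, c(base, list(depletion_mode = "mei1_like")))
  d_ctrl <- diff(range(sample_streaming_trajectory(ctrl)$sperm_track$x_um))
  d_mei <- diff(range(sample_streaming_trajectory(mei)$sperm_track$x_um))
  expect_gt(d_mei, d_ctrl)
})

test_that("jostle step lengths match the configured expectation at large n", {
  cfg <- scene_config(streaming_mode = "jostle",
                      streaming_amplitude_um_s = 0.02,
                      phase_schedule = c(MI = 50000), seed = 21)
  tr <- sample_streaming_trajectory(cfg)$sperm_track
  step <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expected <- 0.02 * 5 # amplitude x frame interval
  se <- stats::sd(step) / sqrt(length(step))
  expect_lt(abs(mean(step) - expected), 3 * se)
})

test_that("programmed capture scenarios have the promised distance geometry", {
  st <- simulate_capture_scenario(scene_config(capture_scenario = "stable",
                                               seed = 31))
  ds <- center_distance_series(st$sperm_track, st$spindle_track)
  expect_lt(min(ds$distance_um), 5.5)
  expect_false(is.na(st$capture_frame))

  no <- simulate_capture_scenario(scene_config(capture_scenario = "none",
                                               seed = 32))
  dn <- center_distance_series(no$sperm_track, no$spindle_track)
  expect_gte(min(dn$distance_um), 8)

  tw <- simulate_capture_scenario(scene_config(capture_scenario = "transient",
                                               seed = 33))
  dt <- center_distance_series(tw$sperm_track, tw$spindle_track)
  below <- dt$distance_um < 5.5
  downward <- sum(diff(c(FALSE, below)) == 1)
  expect_equal(downward, 2)
})
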