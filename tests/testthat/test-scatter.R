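test_that("noise-free well-separated puncta are each detected once", {
  cfg <- small_scene(seed = 7, cloud_sigma_um = 2)
  sim <- simulate_zstack(cfg, quantize = FALSE)
  det <- detect_puncta(sim$stack, embryo = cfg$embryo)
  truth <- sim$truth$puncta
  # all truth puncta are > 1 ROI diameter apart for this seed
  tp <- cbind(truth$x_um, truth$y_um, truth$z_um)
  expect_gt(min(dist(tp)), 1.17)
  expect_equal(nrow(det), nrow(truth))
  ctr <- sim$stack$origin_um
  dp <- sweep(cbind(det$x_um, det$y_um, det$z_um), 2, ctr)
  for (i in seq_len(nrow(tp))) {
    err <- min(sqrt(colSums((t(dp) - tp[i, ])^2)))
    expect_lt(err, sqrt(2 * 0.13^2 + 1^2)) # within one voxel diagonal
  }
})

test_that("a blank channel yields no detections or a no-signal error", {
  v <- array(0, dim = c(30, 30, 3, 1))
  st <- image_stack(v, "mito", pixel_size_um = 0.13)
  expect_error(detect_puncta(st), "no-signal")
  v2 <- v; v2[15, 15, 2, 1] <- 10
  st2 <- image_stack(v2, "mito", pixel_size_um = 0.13)
  expect_equal(nrow(detect_puncta(st2, intensity_floor = 20)), 0)
})

test_that("two puncta closer than one ROI diameter merge into the brighter", {
  v <- array(0, dim = c(40, 40, 1, 1))
  g <- function(cx, cy, amp)
    outer(0:39, 0:39, function(y, x) amp * exp(-((x - cx)^2 + (y - cy)^2) / 8))
  v[, , 1, 1] <- g(18, 20, 100) + g(22, 20, 60) # 4 px = 0.52 um apart
  st <- image_stack(v, "mito", pixel_size_um = 0.13)
  det <- detect_puncta(st, intensity_floor = 10, merge_radius_um = 1.17)
  expect_equal(nrow(det), 1)
  expect_equal(det$x_um, 18 * 0.13, tolerance = 0.13)
})

test_that("multiplicity follows the rounded intensity ratio with floor 1", {
  expect_equal(punctum_multiplicity(2.0 * 80, 80), 2L)
  expect_equal(punctum_multiplicity(80, 80), 1L)
  expect_equal(punctum_multiplicity(3.05 * 80, 80), 3L)
  expect_equal(punctum_multiplicity(2.5 * 80, 80), 3L) # half rounds up
  expect_equal(punctum_multiplicity(0.2 * 80, 80), 1L) # floor at 1
  expect_equal(punctum_multiplicity(-5, 80), 1L)
  expect_error(punctum_multiplicity(100, 0), "degenerate")
  # scaling the whole channel leaves multiplicities unchanged
  means <- c(60, 150, 400)
  expect_equal(punctum_multiplicity(means, 80),
               punctum_multiplicity(means * 13, 80 * 13))
})

test_that("punctum-DNA distance is 3-D Euclidean with z-step handling", {
  expect_equal(distance_to_dna(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(distance_to_dna(c(4, 0, 3), c(0, 0, 0)), 5) # 3 z-steps of 1 um
  expect_error(distance_to_dna(c(1, 2, 3), NULL), "annotation")
  set.seed(19)
  a <- matrix(rnorm(3000), ncol = 3)
  b <- rnorm(3)
  d <- distance_to_dna(a, b)
  ref <- apply(a, 1, function(p) sqrt(sum((p - b)^2)))
  expect_equal(d, ref, tolerance = 1e-12)
})

test_that("scatter profile weights distances by multiplicity", {
  puncta <- data.frame(x_um = c(2, 2, 4), y_um = 0, z_um = 0,
                       multiplicity = c(1L, 1L, 2L))
  prof <- scatter_profile(puncta, c(0, 0, 0), "AII", embryo_id = "e1")
  expect_equal(sort(prof$distances_um), c(2, 2, 4, 4))
  expect_equal(prof$mean_um, 3.0)
  expect_equal(prof$sd_um, sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(prof$n_weighted, sum(puncta$multiplicity))
  # single punctum: degenerate SD
  one <- scatter_profile(data.frame(x_um = 1, y_um = 0, z_um = 0), c(0, 0, 0),
                         "MII")
  expect_equal(one$mean_um, 1)
  expect_true(is.na(one$sd_um))
  # metaphase I excluded; empty input rejected
  expect_error(scatter_profile(puncta, c(0, 0, 0), "MI"), "excluded-phase")
  expect_error(scatter_profile(puncta[0, ], c(0, 0, 0), "AII"), "no-data")
})

test_that("count conservation and rigid invariance of the profile", {
  set.seed(10)
  for (i in 1:20) {
    cfg <- scene_config(n_puncta = sample(5:25, 1), n_masses = sample(0:4, 1),
                        seed = i)
    cloud <- sample_mito_cloud(cfg)
    prof <- scatter_from_ground_truth(cloud, cfg$dna_position_um)
    expect_equal(prof$n_weighted, sum(cloud$multiplicity))
    # translate everything rigidly: distances unchanged
    shift <- rnorm(3)
    cloud2 <- cloud
    cloud2$x_um <- cloud$x_um + shift[1]
    cloud2$y_um <- cloud$y_um + shift[2]
    cloud2$z_um <- cloud$z_um + shift[3]
    prof2 <- scatter_from_ground_truth(cloud2, cfg$dna_position_um + shift)
    expect_equal(prof2$distances_um, prof$distances_um, tolerance = 1e-9)
  }
})

test_that("image-based quantification recovers the ground-truth profile", {
  cfg <- small_scene(seed = 7, cloud_sigma_um = 2, noise_sd = 2,
                     background_level = 50)
  sim <- simulate_zstack(cfg)
  ctr <- sim$stack$origin_um
  q <- quantify_scatter(sim$stack, dna_position_um = cfg$dna_position_um + ctr,
                        phase = "AII", embryo = cfg$embryo)
  ref <- scatter_from_ground_truth(sim$truth)
  expect_equal(q$profile$n_weighted, ref$n_weighted)
  expect_equal(q$profile$mean_um, ref$mean_um, tolerance = 0.15)
})
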