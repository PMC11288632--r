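test_that("ROI mean over a uniform image is the constant", {
  img <- matrix(7, 40, 40)
  m <- measure_roi_mean(img, roi_spec("disk", center = c(20, 20)))
  expect_equal(m$mean_intensity, 7.0)
  poly <- roi_spec("polygon", vertices = cbind(c(5, 30, 30, 5), c(5, 5, 30, 30)))
  expect_equal(measure_roi_mean(img, poly)$mean_intensity, 7.0)
})

test_that("disk membership follows the strict pixel-centre rule", {
  set.seed(8)
  img <- matrix(rnorm(100), 10, 10)
  cx <- 4; cy <- 6; r <- 1 # 2-px diameter
  roi <- roi_spec("disk", center = c(cx, cy), diameter_px = 2)
  # brute-force enumeration of pixel centres strictly inside the circle
  vals <- c()
  for (x in 0:9) for (y in 0:9)
    if ((x - cx)^2 + (y - cy)^2 < r^2) vals <- c(vals, img[y + 1, x + 1])
  expect_equal(measure_roi_mean(img, roi)$mean_intensity, mean(vals))
  # larger random disks against the same oracle
  for (i in 1:20) {
    cx <- runif(1, 8, 25); cy <- runif(1, 8, 25); d <- sample(3:9, 1)
    img2 <- matrix(rnorm(40 * 40), 40, 40)
    vals <- c()
    for (x in 0:39) for (y in 0:39)
      if ((x - cx)^2 + (y - cy)^2 < (d / 2)^2) vals <- c(vals, img2[y + 1, x + 1])
    m <- measure_roi_mean(img2, roi_spec("disk", center = c(cx, cy),
                                         diameter_px = d))
    expect_equal(m$mean_intensity, mean(vals))
    expect_equal(m$n_pixels, length(vals))
  }
})

test_that("out-of-bounds and partially overlapping ROIs error", {
  img <- matrix(0, 20, 20)
  expect_error(measure_roi_mean(img, roi_spec("disk", center = c(100, 100))),
               "outside")
  expect_error(measure_roi_mean(img, roi_spec("disk", center = c(1, 1),
                                              diameter_px = 10)),
               "outside|bounds")
})

test_that("a centred ROI reads more signal than an offset one", {
  # Gaussian spot at (25, 25)
  g <- outer(0:49, 0:49, function(y, x) exp(-((x - 25)^2 + (y - 25)^2) / 18))
  centred <- measure_roi_mean(g, roi_spec("disk", center = c(25, 25)))
  offset <- measure_roi_mean(g, roi_spec("disk", center = c(35, 25)))
  expect_gt(centred$mean_intensity, offset$mean_intensity)
})

test_that("background correction subtracts and centres noise at zero", {
  expect_equal(background_correct(50, 10), 40)
  expect_equal(background_correct(10, 10), 0)
  m <- measure_roi_mean(matrix(5, 30, 30), roi_spec("disk", center = c(15, 15)))
  expect_equal(background_correct(m, m), 0)
  set.seed(123)
  diffs <- replicate(1000, {
    a <- mean(rnorm(50, 100, 5)); b <- mean(rnorm(50, 100, 5))
    background_correct(a, b)
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("chromosome/cytoplasm ratio behaves and is scale invariant", {
  expect_equal(chromosome_to_cytoplasm_ratio(200, 100), 2.0)
  expect_equal(chromosome_to_cytoplasm_ratio(55, 55), 1.0)
  expect_error(chromosome_to_cytoplasm_ratio(10, 0), "positive")
  set.seed(4)
  img <- matrix(runif(900, 10, 20), 30, 30)
  r1 <- chromosome_to_cytoplasm_ratio(
    measure_roi_mean(img, roi_spec("disk", center = c(10, 10), diameter_px = 8)),
    measure_roi_mean(img, roi_spec("disk", center = c(20, 20), diameter_px = 8)))
  r2 <- chromosome_to_cytoplasm_ratio(
    measure_roi_mean(img * 3.7, roi_spec("disk", center = c(10, 10), diameter_px = 8)),
    measure_roi_mean(img * 3.7, roi_spec("disk", center = c(20, 20), diameter_px = 8)))
  expect_equal(r1, r2)
})

test_that("ratios separate chromosome-label-on from label-off scenes", {
  # anaphase-like: marker coats the chromosome surface (bright chrom ROI);
  # metaphase-like: chromosomal ROI reads cytoplasm only
  set.seed(77)
  ratio_for <- function(label_on) {
    img <- matrix(rnorm(60 * 60, 100, 4), 60, 60)
    if (label_on)
      img[25:35, 25:35] <- img[25:35, 25:35] + 150
    chrom <- measure_roi_mean(img, roi_spec("disk", center = c(30, 30),
                                            diameter_px = 8))
    cyto <- measure_roi_mean(img, roi_spec("disk", center = c(48, 48),
                                           diameter_px = 8))
    chromosome_to_cytoplasm_ratio(chrom, cyto)
  }
  ana <- replicate(20, ratio_for(TRUE))
  meta <- replicate(20, ratio_for(FALSE))
  p <- stats::wilcox.test(ana, meta, alternative = "greater")$p.value
  expect_lt(p, 0.05)
})

test_that("oocyte depletion intensity subtracts off-specimen signal", {
  img <- matrix(20, 50, 50)
  img[10:30, 10:30] <- 120 # the oocyte
  cyto <- roi_spec("disk", center = c(20, 20), diameter_px = 8)
  off <- roi_spec("disk", center = c(42, 42), diameter_px = 8)
  expect_equal(oocyte_depletion_intensity(img, cyto, off), 100)
  expect_error(oocyte_depletion_intensity(img, cyto, cyto), "overlap")
  # identical regions -> zero
  img2 <- matrix(20, 50, 50)
  expect_equal(oocyte_depletion_intensity(img2, cyto, off), 0)
  # 10x depleted signal reads ~0.1x control
  set.seed(5)
  control <- img + matrix(rnorm(2500, 0, 1), 50, 50)
  depleted <- matrix(20, 50, 50); depleted[10:30, 10:30] <- 20 + 10
  depleted <- depleted + matrix(rnorm(2500, 0, 1), 50, 50)
  ic <- oocyte_depletion_intensity(control, cyto, off)
  id <- oocyte_depletion_intensity(depleted, cyto, off)
  expect_equal(id / ic, 0.1, tolerance = 0.05)
})
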