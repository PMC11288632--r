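#' Region-of-interest specification
#'
#' A circular (disk) or polygonal ROI on one image plane. The default disk
#' diameter of 18 pixels corresponds to about 1.17 um at the 65-nm pixel
#' size, sized to cover one mitochondrial punctum; use [roi_diameter_px()] to
#' convert a physical diameter for other calibrations.
#'
#' @param shape `"disk"` or `"polygon"`.
#' @param center Disk centre, length-2 numeric `(x, y)` in 0-based pixel
#'   coordinates.
#' @param diameter_px Disk diameter in pixels (>= 1), default 18.
#' @param vertices Polygon vertices, an n x 2 matrix `(x, y)` in 0-based
#'   pixel coordinates.
#' @param z_index 0-based plane index for stacks.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(shape = c("disk", "polygon"), center = NULL,
                     diameter_px = 18, vertices = NULL, z_index = 0L) {
  shape <- match.arg(shape)
  if (shape == "disk") {
    if (is.null(center) || length(center) != 2L)
      stop("disk ROI needs a length-2 center")
    if (diameter_px < 1) stop("diameter_px must be >= 1")
  } else {
    if (is.null(vertices) || ncol(as.matrix(vertices)) != 2L ||
        nrow(as.matrix(vertices)) < 3L)
      stop("polygon ROI needs an n x 2 vertex matrix, n >= 3")
    vertices <- as.matrix(vertices)
  }
  structure(list(shape = shape, center = as.numeric(center),
                 diameter_px = diameter_px, vertices = vertices,
                 z_index = as.integer(z_index)),
            class = "roi_spec")
}

#' Convert a physical ROI diameter to pixels
#'
#' @param diameter_um Diameter in micrometres (default 1.17 um, the
#'   punctum-sized ROI).
#' @param pixel_size_um Lateral pixel size (um).
#' @return Diameter in pixels (rounded to nearest integer, minimum 1).
#' @export
roi_diameter_px <- function(diameter_um = 1.17, pixel_size_um = 0.065) {
  max(1, round(diameter_um / pixel_size_um))
}

# 0-based (x, y) integer pixel centres belonging to the ROI
roi_pixels <- function(roi, dim_yx) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  if (roi$shape == "disk") {
    r <- roi$diameter_px / 2
    cx <- roi$center[1]; cy <- roi$center[2]
    xs <- floor(cx - r):ceiling(cx + r)
    ys <- floor(cy - r):ceiling(cy + r)
    g <- expand.grid(x = xs, y = ys)
    # a pixel belongs to the disk iff its centre lies strictly within radius
    g <- g[(g$x - cx)^2 + (g$y - cy)^2 < r^2, , drop = FALSE]
  } else {
    v <- roi$vertices
    xs <- floor(min(v[, 1])):ceiling(max(v[, 1]))
    ys <- floor(min(v[, 2])):ceiling(max(v[, 2]))
    g <- expand.grid(x = xs, y = ys)
    bnd <- rbind(v, v[1, ])
    keep <- mgcv::in.out(bnd, as.matrix(g))
    g <- g[keep, , drop = FALSE]
  }
  if (nrow(g) == 0L) stop("invalid ROI: contains no pixel centers")
  inside <- g$x >= 0 & g$x < nx & g$y >= 0 & g$y < ny
  if (!any(inside)) stop("out-of-bounds error: ROI fully outside image")
  if (!all(inside)) stop("ROI partially outside image bounds")
  g
}

#' Mean intensity over an ROI
#'
#' Arithmetic mean over the pixels whose centres fall inside the disk or
#' polygon. The ROI must lie entirely within the image; partial overlap is an
#' error rather than a silent truncation.
#'
#' @param plane Numeric matrix (rows = y, columns = x) or an `image_stack`
#'   (with `channel`/`z` selecting the plane).
#' @param roi An [roi_spec()].
#' @param channel Channel name or index when `plane` is a stack.
#' @return A list of class `roi_measurement`: `mean_intensity`, `n_pixels`,
#'   and the `roi` used.
#' @export
measure_roi_mean <- function(plane, roi, channel = 1L) {
  if (inherits(plane, "image_stack"))
    plane <- get_plane(plane, channel = channel, z = roi$z_index)
  if (!is.matrix(plane)) stop("plane must be a matrix")
  px <- roi_pixels(roi, dim(plane))
  vals <- plane[cbind(px$y + 1L, px$x + 1L)]
  structure(list(mean_intensity = mean(vals), n_pixels = nrow(px), roi = roi),
            class = "roi_measurement")
}

#' @export
print.roi_measurement <- function(x, ...) {
  cat(sprintf("<roi_measurement> mean %.4g over %d px\n",
              x$mean_intensity, x$n_pixels))
  invisible(x)
}

#' Background-correct an ROI measurement
#'
#' Subtracts the mean of a background ROI (a region of cytoplasm without
#' signal) from a measurement taken on the same channel. Negative corrected
#' values are retained; clipping to zero is deferred to consumers for which a
#' negative intensity is meaningless (multiplicity computation).
#'
#' @param measurement,background_measurement `roi_measurement` objects or
#'   plain numeric means.
#' @return Corrected mean intensity (numeric).
#' @export
background_correct <- function(measurement, background_measurement) {
  m <- if (inherits(measurement, "roi_measurement"))
    measurement$mean_intensity else as.numeric(measurement)
  b <- if (inherits(background_measurement, "roi_measurement"))
    background_measurement$mean_intensity else as.numeric(background_measurement)
  m - b
}

#' Chromosome-to-cytoplasm fluorescence ratio
#'
#' Ratio of a chromosomal ROI mean to a cytoplasmic ROI mean on the same
#' plane, the normalisation used to score recruitment of a nuclear-envelope
#' marker to the chromosome surface.
#'
#' @param chrom_roi_mean,cyto_roi_mean `roi_measurement` objects or numeric
#'   means; the cytoplasmic mean must be positive.
#' @return Dimensionless ratio.
#' @export
chromosome_to_cytoplasm_ratio <- function(chrom_roi_mean, cyto_roi_mean) {
  ch <- if (inherits(chrom_roi_mean, "roi_measurement"))
    chrom_roi_mean$mean_intensity else as.numeric(chrom_roi_mean)
  cy <- if (inherits(cyto_roi_mean, "roi_measurement"))
    cyto_roi_mean$mean_intensity else as.numeric(cyto_roi_mean)
  if (!is.finite(cy) || cy <= 0)
    stop("division error: cytoplasmic mean must be positive")
  ch / cy
}

#' Depletion-series cytoplasmic intensity
#'
#' Mean cytoplasmic fluorescence corrected by the mean of an off-specimen
#' region (an area containing no part of the worm), the measurement used to
#' compare tagged-protein levels across depletion treatments. The two ROIs
#' must not overlap.
#'
#' @param plane Image matrix or `image_stack`.
#' @param cytoplasm_roi,off_specimen_roi [roi_spec()] objects on `plane`.
#' @param channel Channel when `plane` is a stack.
#' @return Corrected cytoplasmic mean (numeric).
#' @export
oocyte_depletion_intensity <- function(plane, cytoplasm_roi, off_specimen_roi,
                                       channel = 1L) {
  if (inherits(plane, "image_stack"))
    plane <- get_plane(plane, channel = channel, z = cytoplasm_roi$z_index)
  p1 <- roi_pixels(cytoplasm_roi, dim(plane))
  p2 <- roi_pixels(off_specimen_roi, dim(plane))
  if (nrow(merge(p1, p2)) > 0L)
    stop("invalid ROI: cytoplasm and off-specimen ROIs overlap")
  m1 <- mean(plane[cbind(p1$y + 1L, p1$x + 1L)])
  m2 <- mean(plane[cbind(p2$y + 1L, p2$x + 1L)])
  m1 - m2
}
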