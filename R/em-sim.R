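#' Electron-microscopy field container
#'
#' A 2-D grayscale image with its physical pixel size and a binary
#' nucleolar region-of-interest mask (interior of the annotated outline).
#'
#' @param image numeric matrix, grayscale intensities.
#' @param pixel_size nm per pixel, > 0.
#' @param roi_mask logical matrix, same shape as `image`; `TRUE` inside
#'   the nucleolar outline.
#' @param image_id label carried into density results.
#' @return an object of class `em_field`.
#' @export
em_field <- function(image, pixel_size, roi_mask, image_id = "img1") {
  if (!is.matrix(image)) stop_param("image must be a matrix")
  if (!identical(dim(image), dim(roi_mask)))
    stop_param("roi_mask must have the same shape as image")
  if (!is_num1(pixel_size) || pixel_size <= 0)
    stop_param("pixel_size must be > 0")
  structure(list(image = image, pixel_size = pixel_size,
                 roi_mask = roi_mask != 0, image_id = image_id),
            class = "em_field")
}

#' @export
print.em_field <- function(x, ...) {
  cat(sprintf("<em_field> %s: %dx%d px at %.3g nm/px, ROI %.3g nm^2\n",
              x$image_id, nrow(x$image), ncol(x$image), x$pixel_size,
              sum(x$roi_mask) * x$pixel_size^2))
  invisible(x)
}

#' Parameters for the immunogold EM simulator
#'
#' Dark anti-aliased disks of two fixed diameters (12 nm and 6 nm,
#' emulating two distinguishable gold labels) are placed on a textured
#' background, inside and outside an elliptical nucleolar outline.
#'
#' @param image_shape integer vector `c(nx, ny)` in pixels.
#' @param pixel_size nm per pixel.
#' @param roi list `(cx, cy, rx, ry)`: ellipse center and semi-axes in
#'   pixels (1-based centers). Default: centered ellipse covering ~38% of
#'   each dimension.
#' @param n_large,n_small particle counts of the 12 nm and 6 nm classes
#'   placed inside the ROI.
#' @param n_outside_large,n_outside_small counts placed outside the ROI.
#' @param background_level,background_noise_sd background gray level and
#'   i.i.d. Gaussian texture sd.
#' @param particle_contrast how much darker than background a particle
#'   center is (grayscale units).
#' @param min_separation minimum center-to-center distance in nm between
#'   particles of the same size class.
#' @param seed integer seed; identical seeds reproduce placement.
#' @param image_id label.
#' @return an object of class `em_sim_params`.
#' @export
em_sim_params <- function(image_shape = c(512, 512), pixel_size = 2,
                          roi = NULL, n_large = 30, n_small = 60,
                          n_outside_large = 10, n_outside_small = 20,
                          background_level = 0.6, background_noise_sd = 0.05,
                          particle_contrast = 0.35, min_separation = 15,
                          seed = 1, image_id = "sim_em") {
  if (is.null(roi))
    roi <- list(cx = image_shape[1] / 2, cy = image_shape[2] / 2,
                rx = 0.38 * image_shape[1], ry = 0.38 * image_shape[2])
  if (!is_num1(pixel_size) || pixel_size <= 0) stop_param("pixel_size must be > 0")
  if (roi$cx - roi$rx < 1 || roi$cx + roi$rx > image_shape[1] ||
      roi$cy - roi$ry < 1 || roi$cy + roi$ry > image_shape[2])
    stop_param("ROI ellipse must fit within the image")
  counts <- c(n_large, n_small, n_outside_large, n_outside_small)
  if (any(counts < 0)) stop_param("particle counts must be >= 0")
  if (min_separation < 0) stop_param("min_separation must be >= 0")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, roi = roi,
                 n_large = n_large, n_small = n_small,
                 n_outside_large = n_outside_large,
                 n_outside_small = n_outside_small,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 particle_contrast = particle_contrast,
                 min_separation = min_separation,
                 seed = seed, image_id = image_id),
            class = "em_sim_params")
}

# diameters of the two gold size classes, nm
GOLD_DIAMETERS <- c("12nm" = 12, "6nm" = 6)

ellipse_mask <- function(shape, roi) {
  dx <- (seq_len(shape[1]) - roi$cx) / roi$rx
  dy <- (seq_len(shape[2]) - roi$cy) / roi$ry
  outer(dx^2, dy^2, "+") <= 1
}

# add an anti-aliased dark disk; coverage ramps linearly over a 1 px edge
render_disk <- function(img, cx, cy, r_px, contrast) {
  xs <- max(1, floor(cx - r_px - 2)):min(nrow(img), ceiling(cx + r_px + 2))
  ys <- max(1, floor(cy - r_px - 2)):min(ncol(img), ceiling(cy + r_px + 2))
  d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  img[xs, ys] <- img[xs, ys] - contrast * pmin(pmax(r_px - d + 0.5, 0), 1)
  img
}

#' Simulate an immunogold EM image with ground truth
#'
#' Renders dark anti-aliased disks of the two gold size classes on a noisy
#' background, returning the field (image + pixel size + elliptical ROI
#' mask) and the ground-truth particle table. Particle centers respect
#' `min_separation` within each size class; an unplaceable request raises
#' a placement-failure error rather than silently truncating.
#'
#' @param params an [em_sim_params()] object.
#' @return list with `field` (an [em_field()]) and `truth` (data.frame
#'   `x_px`, `y_px` (0-based pixel centers), `size_class`, `in_roi`).
#' @export
simulate_em_image <- function(params) {
  stopifnot(inherits(params, "em_sim_params"))
  p <- params
  shape <- p$image_shape
  mask <- ellipse_mask(shape, p$roi)
  r_large <- (GOLD_DIAMETERS["12nm"] / 2) / p$pixel_size
  r_small <- (GOLD_DIAMETERS["6nm"] / 2) / p$pixel_size
  min_sep_px <- p$min_separation / p$pixel_size

  with_seed(p$seed, {
    img <- matrix(p$background_level +
                    rnorm(prod(shape), 0, p$background_noise_sd),
                  shape[1], shape[2])
    sets <- list(
      list(n = p$n_large, inside = TRUE, class = "12nm", r = r_large),
      list(n = p$n_outside_large, inside = FALSE, class = "12nm", r = r_large),
      list(n = p$n_small, inside = TRUE, class = "6nm", r = r_small),
      list(n = p$n_outside_small, inside = FALSE, class = "6nm", r = r_small))
    truth <- list()
    placed <- list("12nm" = matrix(numeric(0), ncol = 2),
                   "6nm" = matrix(numeric(0), ncol = 2))
    for (s in sets) {
      if (s$n == 0) next
      # keep same-class separation across inside/outside batches
      prior <- placed[[s$class]]
      pts <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (nrow(pts) < s$n) {
        if (tries > 5000 * max(s$n, 1))
          stop_param("placement failure: could not place ", s$n, " ", s$class,
                     " particles at min_separation ", p$min_separation, " nm")
        x <- runif(1, 1 + s$r + 1, shape[1] - s$r - 1)
        y <- runif(1, 1 + s$r + 1, shape[2] - s$r - 1)
        tries <- tries + 1
        if (mask[round(x), round(y)] != s$inside) next
        all_pts <- rbind(prior, pts)
        if (nrow(all_pts) > 0 &&
            min((all_pts[, 1] - x)^2 + (all_pts[, 2] - y)^2) < min_sep_px^2)
          next
        pts <- rbind(pts, c(x, y))
      }
      placed[[s$class]] <- rbind(prior, pts)
      for (i in seq_len(nrow(pts)))
        img <- render_disk(img, pts[i, 1], pts[i, 2], s$r, p$particle_contrast)
      truth[[length(truth) + 1]] <- data.frame(
        x_px = pts[, 1] - 1, y_px = pts[, 2] - 1,
        size_class = s$class, in_roi = s$inside)
    }
    img <- pmax(img, 0)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(x_px = numeric(0), y_px = numeric(0),
                 size_class = character(0), in_roi = logical(0))
    list(field = em_field(img, p$pixel_size, mask, p$image_id),
         truth = truth)
  })
}
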