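# Scale-normalized Laplacian-of-Gaussian kernel, sign-adjusted so dark
# blobs give a positive response. Sampled sigma^2 * laplacian(Gaussian):
#   (r^2 - 2 sigma^2) / (2 pi sigma^4) * exp(-r^2 / 2 sigma^2)
# The sampled kernel is re-centered to exact zero sum so a constant
# background contributes nothing.
log_kernel <- function(sigma) {
  h <- max(2L, ceiling(4 * sigma))
  xs <- -h:h
  r2 <- outer(xs^2, xs^2, "+")
  k <- (r2 - 2 * sigma^2) / (2 * pi * sigma^4) * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

# LoG response matrix for a blob diameter given in pixels
log_response <- function(image, diameter_px) {
  sigma <- diameter_px / (2 * sqrt(2))
  as.matrix(EBImage::filter2(image, log_kernel(sigma)))
}

# Deterministic local maxima of a response matrix: a pixel is a maximum if
# it is >= all 8 neighbours and strictly > the neighbours that precede it
# in column-major order (ties break toward the earliest pixel). Returns
# integer (row, col) indices.
local_maxima <- function(resp) {
  n <- nrow(resp); m <- ncol(resp)
  pad <- matrix(-Inf, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- resp
  ok <- matrix(TRUE, n, m)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2:(n + 1)) + dx, (2:(m + 1)) + dy]
    earlier <- dy < 0 || (dy == 0 && dx < 0)
    ok <- ok & if (earlier) resp > nb else resp >= nb
  }
  which(ok, arr.ind = TRUE)
}

#' Single-scale LoG blob detection
#'
#' Applies a scale-normalized Laplacian-of-Gaussian filter with
#' `sigma_px = (diameter_nm / pixel_size) / (2 sqrt 2)` (the standard
#' blob-radius relation, so the response peaks on blobs of the requested
#' diameter), sign-adjusted so dark blobs give positive response, and
#' returns local maxima above a threshold at integer pixel coordinates,
#' sorted by descending response.
#'
#' The default threshold is a robust background estimate,
#' `median + k_mad * mad` of the response (with a small absolute floor of
#' 1e-8 above the median to absorb FFT rounding on noise-free images).
#'
#' @param image numeric matrix.
#' @param diameter_nm blob diameter; must be at least `2 * pixel_size` to
#'   be resolvable.
#' @param pixel_size nm per pixel.
#' @param threshold absolute response threshold; overrides the robust
#'   default when given.
#' @param k_mad multiplier for the MAD-based default threshold.
#' @return data.frame `x_px`, `y_px` (0-based pixel centers), `response`,
#'   sorted by descending response.
#' @export
log_detect <- function(image, diameter_nm, pixel_size, threshold = NULL,
                       k_mad = 5) {
  if (diameter_nm < 2 * pixel_size)
    stop_param("diameter ", diameter_nm, " nm is below the resolvable limit ",
               "of 2 px (", 2 * pixel_size, " nm)")
  resp <- log_response(image, diameter_nm / pixel_size)
  if (is.null(threshold))
    threshold <- median(resp) + max(k_mad * mad(resp), 1e-8)
  idx <- local_maxima(resp)
  keep <- resp[idx] > threshold
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(x_px = idx[, 1] - 1, y_px = idx[, 2] - 1,
                    response = resp[idx])
  out[order(-out$response, out$x_px, out$y_px), , drop = FALSE]
}

#' Remove candidates near anchor particles
#'
#' Drops every candidate whose center lies strictly within `radius_nm` of
#' any anchor center (open boundary: a candidate exactly at `radius_nm`
#' is retained). Order is preserved; empty anchors return the candidates
#' unchanged.
#'
#' @param candidates data.frame with `x_px`, `y_px` columns.
#' @param anchors data.frame with `x_px`, `y_px` columns.
#' @param radius_nm exclusion radius, > 0.
#' @param pixel_size nm per pixel.
#' @return filtered copy of `candidates`.
#' @export
exclude_around <- function(candidates, anchors, radius_nm, pixel_size) {
  if (!is_num1(radius_nm) || radius_nm <= 0)
    stop_param("radius_nm must be > 0")
  if (nrow(anchors) == 0 || nrow(candidates) == 0) return(candidates)
  r2 <- (radius_nm / pixel_size)^2
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    d2 <- (anchors$x_px - candidates$x_px[i])^2 +
      (anchors$y_px - candidates$y_px[i])^2
    all(d2 >= r2)
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

# greedy non-maximum suppression: highest response wins; detections closer
# than min_dist_px (strictly) to an accepted one are dropped
suppress_duplicates <- function(cand, min_dist_px) {
  if (nrow(cand) <= 1) return(cand)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {  # cand is sorted by descending response
    acc <- which(keep)
    if (length(acc) == 0 ||
        min((cand$x_px[acc] - cand$x_px[i])^2 +
              (cand$y_px[acc] - cand$y_px[i])^2) >= min_dist_px^2)
      keep[i] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

#' Default exclusion radius around accepted 12 nm particles
#'
#' 1.5 times the 12 nm particle radius plus the 6 nm particle radius
#' (= 12 nm): a 6 nm candidate closer than this to a larger particle is
#' treated as a ringing artifact of the large particle.
#'
#' @return radius in nm.
#' @export
default_exclusion_radius <- function() 1.5 * (12 / 2) + 6 / 2

#' Two-pass immunogold particle detection
#'
#' Detects the larger 12 nm particles first, suppresses same-class
#' duplicates within one particle diameter (highest response wins),
#' excludes a configurable radius around each accepted 12 nm particle,
#' then searches a second time at the 6 nm scale on the remaining
#' candidates. Detections everywhere in the image are returned and
#' labeled `in_roi` from the field's mask (densities later use the
#' in-ROI subset only, but outside detections remain inspectable).
#'
#' Class assignment additionally requires scale dominance: a candidate is
#' accepted at a given size class only if its scale-normalized LoG
#' response at that class's scale is at least its response at the other
#' class's scale (characteristic-scale selection). This prevents the 12 nm
#' pass from firing on 6 nm particles and vice versa without any
#' class-specific threshold tuning.
#'
#' @param field an [em_field()].
#' @param thresholds optional named list/vector with absolute response
#'   thresholds per class (`"12nm"`, `"6nm"`); defaults to the robust
#'   per-class estimate of [log_detect()].
#' @param exclusion_radius_nm radius wiped around accepted 12 nm
#'   particles before the 6 nm pass; default [default_exclusion_radius()].
#' @param k_mad MAD multiplier for the default thresholds.
#' @return a `particle_set`: data.frame `x_px`, `y_px` (0-based),
#'   `size_class`, `response`, `in_roi`, with the field's `pixel_size` and
#'   `image_id` as attributes.
#' @export
detect_two_pass <- function(field, thresholds = NULL,
                            exclusion_radius_nm = default_exclusion_radius(),
                            k_mad = 5) {
  stopifnot(inherits(field, "em_field"))
  px <- field$pixel_size
  d12_px <- GOLD_DIAMETERS["12nm"] / px
  d6_px <- GOLD_DIAMETERS["6nm"] / px
  if (GOLD_DIAMETERS["6nm"] < 2 * px)
    stop_param("6 nm particles are below the resolvable limit at ",
               px, " nm/px")
  r12 <- log_response(field$image, d12_px)
  r6 <- log_response(field$image, d6_px)

  thr <- function(class, resp) {
    if (!is.null(thresholds) && class %in% names(thresholds))
      return(thresholds[[class]])
    median(resp) + max(k_mad * mad(resp), 1e-8)
  }
  maxima_at <- function(resp, other, threshold, strict_other) {
    idx <- local_maxima(resp)
    v <- resp[idx]
    keep <- v > threshold &
      (if (strict_other) v > other[idx] else v >= other[idx])
    idx <- idx[keep, , drop = FALSE]
    out <- data.frame(x_px = idx[, 1] - 1, y_px = idx[, 2] - 1,
                      response = resp[idx])
    out[order(-out$response, out$x_px, out$y_px), , drop = FALSE]
  }

  # pass 1: large particles (ties in scale dominance go to the large class)
  cand12 <- maxima_at(r12, r6, thr("12nm", r12), strict_other = FALSE)
  acc12 <- suppress_duplicates(cand12, d12_px)

  # pass 2: small particles on the remainder
  cand6 <- maxima_at(r6, r12, thr("6nm", r6), strict_other = TRUE)
  cand6 <- exclude_around(cand6, acc12, exclusion_radius_nm, px)
  acc6 <- suppress_duplicates(cand6, d6_px)

  add_class <- function(df, cls) {
    df$size_class <- rep(cls, nrow(df))
    df
  }
  out <- rbind(add_class(acc12, "12nm"), add_class(acc6, "6nm"))
  out$in_roi <- if (nrow(out)) {
    field$roi_mask[cbind(round(out$x_px) + 1, round(out$y_px) + 1)]
  } else logical(0)
  rownames(out) <- NULL
  structure(out, pixel_size = px, image_id = field$image_id,
            class = c("particle_set", "data.frame"))
}

#' Immunogold particle density inside the nucleolar outline
#'
#' Counts in-ROI detections per size class and divides by the ROI area,
#' `roi_area_nm2 = (mask pixel count) * pixel_size^2`, giving
#' particles/nm^2 for each class.
#'
#' @param field an [em_field()] with a non-empty ROI.
#' @param particles a `particle_set` from [detect_two_pass()].
#' @param condition label carried into comparisons.
#' @return an object of class `density_result`: `image_id`, `count_12`,
#'   `count_6`, `roi_area_nm2`, `density_12`, `density_6`, `condition`.
#' @export
particle_density <- function(field, particles, condition = "control") {
  stopifnot(inherits(field, "em_field"))
  area <- sum(field$roi_mask) * field$pixel_size^2
  if (area <= 0) stop_param("empty ROI: density undefined")
  n12 <- sum(particles$size_class == "12nm" & particles$in_roi)
  n6 <- sum(particles$size_class == "6nm" & particles$in_roi)
  structure(list(image_id = field$image_id, count_12 = n12, count_6 = n6,
                 roi_area_nm2 = area,
                 density_12 = n12 / area, density_6 = n6 / area,
                 condition = condition),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> %s (%s): 12nm %d (%.3g/nm^2), 6nm %d (%.3g/nm^2) in %.3g nm^2\n",
              x$image_id, x$condition, x$count_12, x$density_12,
              x$count_6, x$density_6, x$roi_area_nm2))
  invisible(x)
}

#' Compare per-image particle densities between two groups
#'
#' Per size class, a two-sided two-sample t test on the per-image
#' densities, reported with mean +/- SEM per group.
#'
#' @param a,b lists of `density_result` objects (n >= 2 per group).
#' @param var_equal pooled-variance t test if `TRUE`.
#' @return named list (one `density_comparison` per size class) with
#'   per-group `mean`, `sem`, `n` and the test's `t` and `p`.
#' @export
compare_densities <- function(a, b, var_equal = TRUE) {
  chk <- function(g) {
    if (length(g) < 2) stop_param("need n >= 2 images per group")
    if (!all(vapply(g, inherits, logical(1), "density_result")))
      stop_param("groups must contain density_result objects")
  }
  chk(a); chk(b)
  one <- function(fld) {
    xa <- vapply(a, function(d) d[[fld]], numeric(1))
    xb <- vapply(b, function(d) d[[fld]], numeric(1))
    # degenerate zero-variance groups (identical fields): equal means are
    # trivially non-significant, unequal ones trivially significant
    if (sd(xa) == 0 && sd(xb) == 0) {
      eq <- isTRUE(all.equal(mean(xa), mean(xb)))
      tt <- list(statistic = if (eq) 0 else Inf, p.value = if (eq) 1 else 0)
    } else {
      tt <- t.test(xa, xb, var.equal = var_equal)
    }
    list(mean_a = mean(xa), sem_a = sd(xa) / sqrt(length(xa)), n_a = length(xa),
         mean_b = mean(xb), sem_b = sd(xb) / sqrt(length(xb)), n_b = length(xb),
         t = unname(tt$statistic), p = unname(tt$p.value))
  }
  list("12nm" = one("density_12"), "6nm" = one("density_6"))
}
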