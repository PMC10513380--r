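# 2-D perimeter estimation: trace each component's 8-connected boundary
# (EBImage::ocontour), sum chain steps with the Vossepoel-Smeulders
# weights (0.948 axial, 1.340 diagonal) that debias digital chain length
# against smooth curves, and add pi: the traced polygon runs through
# boundary-pixel centers, i.e. the true outline eroded by half a pixel,
# and offsetting a closed convex contour outward by 0.5 px adds exactly
# 2*pi*0.5. Accurate to ~1-2% for disks and ellipses of radius >~ 5 px at
# any orientation. The 3-D analog counts exposed voxel faces, which
# overestimate an isotropic smooth surface by 3/2: surface ~ faces * 2/3.

# per-label contour perimeters of a label matrix
label_perimeters <- function(lab, n_labels) {
  ct <- EBImage::ocontour(EBImage::Image(lab))
  out <- rep(NA_real_, n_labels)
  for (i in seq_along(ct)) {
    v <- ct[[i]]
    n <- nrow(v)
    if (n < 2) { out[i] <- 4 * 0.948; next }  # single boundary pixel
    d <- v - v[c(2:n, 1), , drop = FALSE]
    steps2 <- rowSums(d^2)
    out[i] <- sum(ifelse(steps2 > 1.5, 1.340, 0.948)) + pi
  }
  out
}

# vectorized measurements of all labels in a 2-D label matrix
measure_labeled <- function(lab, pixel_size_um = 1, min_size_px = 4) {
  n_labels <- max(lab)
  if (n_labels == 0)
    return(data.frame(component_id = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      sphericity = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0)))
  areas <- tabulate(lab, nbins = n_labels)
  perim_px <- label_perimeters(lab, n_labels)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[idx]
  present <- sort(unique(l))
  cx <- rowsum(as.numeric(idx[, 1]), l)[, 1] / areas[present]
  cy <- rowsum(as.numeric(idx[, 2]), l)[, 1] / areas[present]
  sph <- ifelse(areas >= 2, pmin(4 * pi * areas / perim_px^2, 1.05), NA_real_)
  out <- data.frame(component_id = present,
                    area_px = areas[present],
                    area_um2 = areas[present] * pixel_size_um^2,
                    perimeter_um = perim_px[present] * pixel_size_um,
                    sphericity = sph[present],
                    centroid_x_px = cx - 1, centroid_y_px = cy - 1)
  out <- out[out$area_px >= min_size_px, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment nucleolar components in one channel of one cell
#'
#' Thresholds the channel within the cell (nucleus) mask — Otsu by
#' default, overridable with a fixed threshold — labels connected
#' foreground components, removes components below the minimum size, and
#' measures area, perimeter, sphericity (2-D circularity) and centroid
#' for each. Deterministic. A channel with no signal inside the mask
#' (Otsu contrast below `min_contrast`) yields an empty component table,
#' not an error.
#'
#' @param image numeric matrix (one channel, one frame).
#' @param cell_mask logical matrix, same shape; the nucleus region.
#' @param pixel_size_um microns per pixel.
#' @param min_size_px minimum component size in pixels (default 4).
#' @param min_contrast minimum Otsu-threshold-to-minimum separation for
#'   the mask to count as containing signal, grayscale units.
#' @param threshold optional fixed absolute threshold overriding Otsu.
#' @return data.frame with one row per component: `component_id`,
#'   `area_px`, `area_um2`, `perimeter_um`, `sphericity`,
#'   `centroid_x_px`, `centroid_y_px` (0-based).
#' @export
segment_components <- function(image, cell_mask, pixel_size_um = 1,
                               min_size_px = 4, min_contrast = 0.1,
                               threshold = NULL) {
  if (!any(cell_mask)) stop_param("empty cell mask")
  v <- image[cell_mask]
  if (is.null(threshold)) {
    thr <- otsu_threshold(v)
    if (thr - min(v) < min_contrast)
      return(measure_labeled(matrix(0L, 1, 1), pixel_size_um, min_size_px))
  } else thr <- threshold
  fg <- image > thr & cell_mask
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  measure_labeled(lab, pixel_size_um, min_size_px)
}

#' Area/volume, perimeter/surface and sphericity of one component
#'
#' For a 2-D mask, reports area, Crofton-corrected perimeter, and
#' circularity \eqn{4\pi A / P^2} (reported as "sphericity" for
#' consistency with the 3-D metric). For a 3-D mask, reports volume,
#' face-count surface area (corrected by 2/3), and sphericity
#' \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / S}. Values are clipped at 1.05 to
#' absorb discretization overshoot. Single-pixel components are flagged
#' degenerate with undefined sphericity.
#'
#' @param mask logical/0-1 matrix (2-D) or 3-D array.
#' @param pixel_size_um physical size of a pixel/voxel edge.
#' @return list with `area_or_volume`, `perimeter_or_surface`,
#'   `sphericity`, `ndim`, `degenerate`.
#' @export
measure_shape <- function(mask, pixel_size_um = 1) {
  dims <- length(dim(mask))
  if (!dims %in% 2:3) stop_param("mask must be a 2-D matrix or 3-D array")
  vol_px <- sum(mask != 0)
  if (vol_px == 0) stop_param("empty component")
  if (vol_px == 1)
    return(list(area_or_volume = pixel_size_um^dims,
                perimeter_or_surface = NA_real_, sphericity = NA_real_,
                ndim = dims, degenerate = TRUE))
  if (dims == 2) {
    lab <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
    perim <- label_perimeters(lab, 1)
    sph <- min(4 * pi * vol_px / perim^2, 1.05)
    list(area_or_volume = vol_px * pixel_size_um^2,
         perimeter_or_surface = perim * pixel_size_um,
         sphericity = sph, ndim = 2L, degenerate = FALSE)
  } else {
    a <- array(as.integer(mask != 0), dim(mask))
    dp <- dim(a) + 2
    pad <- array(0L, dp)
    pad[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] <- a
    faces <- 0
    for (ax in 1:3) {
      d <- apply(pad, setdiff(1:3, ax), diff)
      faces <- faces + sum(abs(d))
    }
    surf <- faces * 2 / 3
    sph <- min(pi^(1 / 3) * (6 * vol_px)^(2 / 3) / surf, 1.05)
    list(area_or_volume = vol_px * pixel_size_um^3,
         perimeter_or_surface = surf * pixel_size_um^2,
         sphericity = sph, ndim = 3L, degenerate = FALSE)
  }
}

#' Link cell detections across frames into tracks
#'
#' Greedy nearest-centroid linking between consecutive frames: candidate
#' links are sorted by distance and accepted one-to-one while the
#' displacement stays below `max_disp_um` per frame. Detections left
#' unlinked start new tracks; a cell that would have to jump beyond the
#' gate terminates its track rather than swapping identity.
#'
#' A detection can also re-join a track whose cell was missed for up to
#' `max_gap` frames (e.g. a transient segmentation dropout), with the
#' displacement gate scaled by the number of frames skipped.
#'
#' @param detections data.frame with columns `frame`, `x_px`, `y_px` and
#'   optionally `det_id` (per-frame label).
#' @param pixel_size_um microns per pixel.
#' @param max_disp_um maximum displacement per frame, microns
#'   (default 10).
#' @param max_gap frames a track may be undetected and still continue.
#' @return the detections data.frame with a `track_id` column added.
#' @export
track_cells <- function(detections, pixel_size_um = 1, max_disp_um = 10,
                        max_gap = 1) {
  if (!all(c("frame", "x_px", "y_px") %in% names(detections)))
    stop_param("detections must have frame, x_px, y_px columns")
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  if (nrow(det) == 0) return(det)
  frames <- sort(unique(det$frame))
  gate_px <- max_disp_um / pixel_size_um
  # active tracks: id, last position, last frame
  first <- which(det$frame == frames[1])
  det$track_id[first] <- seq_along(first)
  active <- data.frame(id = seq_along(first), x = det$x_px[first],
                       y = det$y_px[first], last = frames[1])
  next_id <- length(first) + 1L
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]
    cand <- which(active$last >= f - 1 - max_gap)
    cur <- which(det$frame == f)
    if (length(cand) && length(cur)) {
      dmat <- outer(active$x[cand], det$x_px[cur], "-")^2 +
        outer(active$y[cand], det$y_px[cur], "-")^2
      allow <- outer((f - active$last[cand]) * gate_px, rep(1, length(cur)))
      ord <- order(dmat)
      used_t <- logical(length(cand)); used_c <- logical(length(cur))
      for (k in ord) {
        i <- (k - 1) %% length(cand) + 1
        j <- (k - 1) %/% length(cand) + 1
        if (sqrt(dmat[k]) > allow[i, j]) next
        if (used_t[i] || used_c[j]) next
        used_t[i] <- TRUE; used_c[j] <- TRUE
        id <- active$id[cand[i]]
        det$track_id[cur[j]] <- id
        active[active$id == id, c("x", "y", "last")] <-
          list(det$x_px[cur[j]], det$y_px[cur[j]], f)
      }
    }
    new <- cur[is.na(det$track_id[cur])]
    if (length(new)) {
      det$track_id[new] <- next_id + seq_along(new) - 1L
      active <- rbind(active, data.frame(id = det$track_id[new],
                                         x = det$x_px[new],
                                         y = det$y_px[new], last = f))
      next_id <- next_id + length(new)
    }
  }
  det
}

# Crude nucleus segmenter: Otsu on the Gaussian-blurred summed channels,
# fill holes, size floor. Blurring (sigma ~ nucleolar component radius)
# merges the bright intranuclear components with the dimmer nuclear
# background so the threshold separates nucleus from cytoplasm instead of
# latching onto the components.
segment_nuclei <- function(frame_sum, min_size_px = 100, blur_sigma = 4) {
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(frame_sum),
                                          sigma = blur_sigma))
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(fg)))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab)
  drop <- which(sizes < min_size_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Measure nucleolar components across a time-lapse movie
#'
#' Full morphometry pass over a 3-channel movie: per frame, nuclei are
#' segmented (Otsu on the summed channels), tracked across frames by
#' nearest-centroid linking, and within each nucleus every channel is
#' segmented into components ([segment_components()]). Per cell and frame
#' the UBF and FBL puncta counts, total NPM1 area and the area-weighted
#' mean NPM1 sphericity are assembled into a time series.
#'
#' @param movie a `timelapse_movie` (see [simulate_timelapse()]), or any
#'   list with `frames` (x, y, channel, frame array), `channels`,
#'   `pixel_size_um`.
#' @param max_disp_um tracking gate, microns per frame.
#' @param min_size_px component size floor, pixels.
#' @param nucleus_min_px nucleus size floor, pixels.
#' @return list with `series` (data.frame `track_id`, `frame`, `n_ubf`,
#'   `n_fbl`, `n_npm1`, `npm1_area_um2`, `npm1_sphericity`,
#'   `npm1_max_area_frac`), `components` (per-component table), and
#'   `tracks` (nucleus detections with track ids).
#' @export
analyze_timelapse <- function(movie, max_disp_um = 10, min_size_px = 4,
                              nucleus_min_px = 100) {
  fr <- movie$frames
  if (is.null(fr) || dim(fr)[4] == 0)
    return(list(series = data.frame(), components = data.frame(),
                tracks = data.frame()))
  px <- movie$pixel_size_um
  n_frames <- dim(fr)[4]
  chan <- match(c("UBF", "FBL", "NPM1"), movie$channels)

  labs <- vector("list", n_frames)
  dets <- list()
  for (f in seq_len(n_frames)) {
    lab <- segment_nuclei(fr[, , chan[1], f] + fr[, , chan[2], f] +
                            fr[, , chan[3], f], nucleus_min_px)
    labs[[f]] <- lab
    nl <- max(lab)
    if (nl > 0) {
      areas <- tabulate(lab, nbins = nl)
      idx <- which(lab > 0, arr.ind = TRUE)
      l <- lab[idx]
      present <- sort(unique(l))
      cx <- rowsum(as.numeric(idx[, 1]), l)[, 1] / areas[present]
      cy <- rowsum(as.numeric(idx[, 2]), l)[, 1] / areas[present]
      dets[[f]] <- data.frame(frame = f, det_id = present,
                              x_px = cx - 1, y_px = cy - 1)
    }
  }
  dets <- do.call(rbind, dets)
  tracks <- track_cells(dets, pixel_size_um = px, max_disp_um = max_disp_um)

  series <- list()
  comps <- list()
  for (r in seq_len(nrow(tracks))) {
    f <- tracks$frame[r]
    id <- tracks$det_id[r]
    lab <- labs[[f]]
    sel <- which(lab == id, arr.ind = TRUE)
    x0 <- max(1, min(sel[, 1]) - 2); x1 <- min(nrow(lab), max(sel[, 1]) + 2)
    y0 <- max(1, min(sel[, 2]) - 2); y1 <- min(ncol(lab), max(sel[, 2]) + 2)
    mask <- lab[x0:x1, y0:y1] == id
    row <- list(track_id = tracks$track_id[r], frame = f)
    for (ci in 1:3) {
      ch_name <- c("ubf", "fbl", "npm1")[ci]
      tab <- segment_components(fr[x0:x1, y0:y1, chan[ci], f], mask,
                                pixel_size_um = px, min_size_px = min_size_px)
      if (ch_name == "npm1") {
        row$n_npm1 <- nrow(tab)
        row$npm1_area_um2 <- sum(tab$area_um2)
        row$npm1_sphericity <- if (nrow(tab))
          sum(tab$area_um2 * tab$sphericity, na.rm = TRUE) /
            sum(tab$area_um2[!is.na(tab$sphericity)]) else NA_real_
        row$npm1_max_area_frac <- if (nrow(tab))
          max(tab$area_um2) / sum(tab$area_um2) else NA_real_
      } else {
        row[[paste0("n_", ch_name)]] <- nrow(tab)
      }
      if (nrow(tab)) {
        tab$frame <- f; tab$track_id <- tracks$track_id[r]
        tab$channel <- c("UBF", "FBL", "NPM1")[ci]
        tab$centroid_x_px <- tab$centroid_x_px + x0 - 1
        tab$centroid_y_px <- tab$centroid_y_px + y0 - 1
        comps[[length(comps) + 1]] <- tab
      }
    }
    series[[length(series) + 1]] <- as.data.frame(row)
  }
  series <- do.call(rbind, series)
  series <- series[order(series$track_id, series$frame), , drop = FALSE]
  rownames(series) <- NULL
  list(series = series,
       components = if (length(comps)) do.call(rbind, comps) else data.frame(),
       tracks = tracks)
}

#' Per-frame population mean and 95% confidence interval
#'
#' For each frame and metric, the mean across cells with a t-based 95%
#' confidence interval (`mean +/- t[0.975, n-1] * SE`). Frames with a
#' single cell get an undefined (NA) interval and are flagged.
#'
#' @param series per-cell time series from [analyze_timelapse()] (or any
#'   data.frame with `frame` plus metric columns).
#' @param metrics character vector of metric column names.
#' @param conf confidence level.
#' @return data.frame `frame`, `metric`, `mean`, `ci_lo`, `ci_hi`, `n`,
#'   `flagged` (single-cell frames).
#' @export
summarize_population <- function(series,
                                 metrics = c("n_ubf", "n_fbl",
                                             "npm1_area_um2",
                                             "npm1_sphericity"),
                                 conf = 0.95) {
  out <- list()
  for (m in metrics) {
    for (f in sort(unique(series$frame))) {
      v <- series[[m]][series$frame == f]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0) next
      mu <- mean(v)
      if (n >= 2) {
        hw <- qt(1 - (1 - conf) / 2, n - 1) * sd(v) / sqrt(n)
        out[[length(out) + 1]] <- data.frame(
          frame = f, metric = m, mean = mu, ci_lo = mu - hw, ci_hi = mu + hw,
          n = n, flagged = FALSE)
      } else {
        out[[length(out) + 1]] <- data.frame(
          frame = f, metric = m, mean = mu, ci_lo = NA_real_,
          ci_hi = NA_real_, n = n, flagged = TRUE)
      }
    }
  }
  do.call(rbind, out)
}

#' Classify one cell's nucleolar phenotype from its NPM1 components
#'
#' Rule-based call on the NPM1 (granular component) measurements of one
#' cell at one frame:
#'
#' * **fragmented** — at least `fragment_count_min` components and the
#'   largest holds less than `max_area_frac` of the total area (many
#'   dispersed puncta, none dominant);
#' * **condensed** — exactly one component with sphericity at least
#'   `condensed_sphericity` (single round coalesced nucleolus);
#' * **normal** — anything else;
#' * **unclassifiable** — no NPM1 signal (excluded from denominators).
#'
#' The thresholds are explicit, configurable stand-ins: published
#' fragmentation scoring of this phenotype is by eye, so no reference
#' values exist for them.
#'
#' @param n_components NPM1 component count.
#' @param max_area_frac fraction of total NPM1 area in the largest
#'   component.
#' @param sphericity area-weighted mean sphericity.
#' @param fragment_count_min,largest_frac_max,condensed_sphericity rule
#'   thresholds.
#' @return an object of class `phenotype_call`: `phenotype` plus the
#'   evidence fields.
#' @export
classify_phenotype <- function(n_components, max_area_frac, sphericity,
                               fragment_count_min = 6,
                               largest_frac_max = 0.5,
                               condensed_sphericity = 0.9) {
  phen <- if (is.na(n_components) || n_components == 0) {
    "unclassifiable"
  } else if (n_components >= fragment_count_min &&
             !is.na(max_area_frac) && max_area_frac < largest_frac_max) {
    "fragmented"
  } else if (n_components == 1 && !is.na(sphericity) &&
             sphericity >= condensed_sphericity) {
    "condensed"
  } else "normal"
  structure(list(phenotype = phen, n_components = n_components,
                 max_area_frac = max_area_frac, sphericity = sphericity),
            class = "phenotype_call")
}

#' Classify every tracked cell at its final frame
#'
#' Applies [classify_phenotype()] to each track's last measured frame
#' (post-division where a division occurred, matching end-point scoring
#' of fixed cells).
#'
#' @param series per-cell series from [analyze_timelapse()].
#' @param ... rule thresholds passed to [classify_phenotype()].
#' @return data.frame `track_id`, `frame`, `phenotype`, `n_components`,
#'   `max_area_frac`, `sphericity`.
#' @export
classify_population <- function(series, ...) {
  out <- lapply(split(series, series$track_id), function(s) {
    s <- s[order(s$frame), , drop = FALSE]
    last <- s[nrow(s), ]
    call <- classify_phenotype(last$n_npm1, last$npm1_max_area_frac,
                               last$npm1_sphericity, ...)
    data.frame(track_id = last$track_id, frame = last$frame,
               phenotype = call$phenotype, n_components = call$n_components,
               max_area_frac = call$max_area_frac,
               sphericity = call$sphericity)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percentage of fragmented cells per condition, with one-way ANOVA
#'
#' `100 * fragmented / classifiable` per condition; unclassifiable cells
#' are excluded from the denominator. When per-replicate percentages are
#' available for three or more conditions, a one-way ANOVA across
#' conditions is reported.
#'
#' @param calls data.frame with a `phenotype` column plus `condition` and
#'   optionally `replicate`.
#' @return list with `summary` (condition, n_classifiable, n_fragmented,
#'   pct_fragmented) and `anova_p` (NA unless >= 3 conditions with
#'   replicates).
#' @export
fraction_fragmented <- function(calls) {
  if (!"condition" %in% names(calls)) calls$condition <- "all"
  cl <- calls[calls$phenotype != "unclassifiable", , drop = FALSE]
  if (nrow(cl) == 0) stop_param("zero classifiable cells")
  summ <- do.call(rbind, lapply(split(cl, cl$condition), function(s) {
    data.frame(condition = s$condition[1], n_classifiable = nrow(s),
               n_fragmented = sum(s$phenotype == "fragmented"),
               pct_fragmented = 100 * mean(s$phenotype == "fragmented"))
  }))
  rownames(summ) <- NULL
  anova_p <- NA_real_
  if ("replicate" %in% names(cl) && length(unique(cl$condition)) >= 3) {
    reps <- do.call(rbind, lapply(
      split(cl, list(cl$condition, cl$replicate), drop = TRUE),
      function(s) data.frame(condition = s$condition[1],
                             replicate = s$replicate[1],
                             pct = 100 * mean(s$phenotype == "fragmented"))))
    if (length(unique(reps$replicate)) >= 2) {
      fit <- aov(pct ~ condition, data = reps)
      anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
  }
  list(summary = summ, anova_p = anova_p)
}
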