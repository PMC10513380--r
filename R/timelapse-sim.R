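#' Parameters for the nucleolar time-lapse simulator
#'
#' Generates a 3-channel 2-D+t movie (UBF, FBL, NPM1 markers for the
#' fibrillar center, dense fibrillar component and granular component) of
#' `n_cells` nuclei arranged on a tile grid, with known per-cell ground
#' truth. Three behaviours are modeled:
#'
#' * `condition = "control"`: puncta counts, NPM1 area and shape are
#'   stationary up to noise.
#' * `condition = "inhibited"` (Pol I inhibition): UBF/FBL puncta counts
#'   decay, NPM1 components merge at `condensation_rate`, total NPM1 area
#'   shrinks and components round up (sphericity ramps up) — the condensed
#'   single-nucleolus phenotype.
#' * division: at `division_frame` the nucleolar components dissolve for
#'   one frame, then either reassemble into 1-3 components (normal
#'   outcome) or scatter into `n_fragments` small dispersed puncta (failed
#'   reassembly, the fragmented phenotype).
#'
#' `fragmentation_probability` is the population-level probability that a
#' cell ends fragmented. Fragmentation only happens through a division, so
#' a cell drawn to fragment divides (at `division_frame` if set, else at
#' the movie midpoint); when every cell divides this equals the per-division
#' failure probability.
#'
#' @param n_cells number of cells.
#' @param n_frames frames in the movie (default 31: imaging every 10
#'   minutes for 5 hours).
#' @param frame_interval minutes between frames.
#' @param condition `"control"` or `"inhibited"`.
#' @param initial_counts named vector `c(ubf = , fbl = )` of starting
#'   puncta counts per nucleus.
#' @param npm1_components starting number of NPM1 (granular component)
#'   bodies per nucleus.
#' @param condensation_rate per-frame probability that two NPM1 components
#'   merge (inhibited condition only).
#' @param division_frame `NULL` (no divisions), a single frame index
#'   (every cell divides there), or an integer vector of length `n_cells`
#'   with `NA` for non-dividing cells.
#' @param fragmentation_probability probability in `[0, 1]` that a cell
#'   ends fragmented (see above).
#' @param n_fragments dispersed NPM1 puncta in a fragmented cell.
#' @param noise_sd Gaussian pixel noise, grayscale units.
#' @param pixel_size_um microns per pixel.
#' @param tile_px side of the square tile holding one cell, pixels.
#' @param render if `FALSE`, skip image rendering and return the truth
#'   only (fast path for large population statistics).
#' @param seed integer seed; identical seeds give identical movies.
#' @return an object of class `timelapse_sim_params`.
#' @export
timelapse_sim_params <- function(n_cells = 12, n_frames = 31,
                                 frame_interval = 10,
                                 condition = c("control", "inhibited"),
                                 initial_counts = c(ubf = 12, fbl = 8),
                                 npm1_components = 2,
                                 condensation_rate = 0.12,
                                 division_frame = NULL,
                                 fragmentation_probability = 0,
                                 n_fragments = 8, noise_sd = 0.02,
                                 pixel_size_um = 0.2, tile_px = 56,
                                 render = TRUE, seed = 1) {
  condition <- match.arg(condition)
  if (n_cells < 0 || n_frames < 2) stop_param("need n_cells >= 0 and n_frames >= 2")
  if (fragmentation_probability < 0 || fragmentation_probability > 1)
    stop_param("fragmentation_probability must be in [0, 1]")
  if (!is.null(division_frame)) {
    if (length(division_frame) == 1 && n_cells > 0)
      division_frame <- rep(as.integer(division_frame), n_cells)
    if (n_cells > 0 && length(division_frame) != n_cells)
      stop_param("division_frame must be NULL, scalar, or length n_cells")
    bad <- !is.na(division_frame) &
      (division_frame < 2 | division_frame > n_frames - 1)
    if (any(bad)) stop_param("division_frame must lie in [2, n_frames - 1]")
  } else if (n_cells > 0) {
    division_frame <- rep(NA_integer_, n_cells)
  }
  if (n_fragments < 6)
    stop_param("n_fragments must be >= 6 (a fragmented cell disperses into many puncta)")
  structure(list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, condition = condition,
                 initial_counts = initial_counts,
                 npm1_components = as.integer(npm1_components),
                 condensation_rate = condensation_rate,
                 division_frame = division_frame,
                 fragmentation_probability = fragmentation_probability,
                 n_fragments = as.integer(n_fragments), noise_sd = noise_sd,
                 pixel_size_um = pixel_size_um, tile_px = as.integer(tile_px),
                 render = isTRUE(render), seed = seed),
            class = "timelapse_sim_params")
}

# Ramanujan perimeter of an ellipse with semi-axes a, b
ellipse_perimeter <- function(a, b)
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))

ellipse_circularity <- function(a, b)
  4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2

# geometry constants of the rendered cell (pixels, relative to tile)
TL <- list(
  nucleus_bg = 0.12, cyto_bg = 0.04, comp_amp = 0.7, punct_amp = 0.8,
  ubf_sigma = 1.3, fbl_sigma = 1.7,
  npm1_area_um2 = 12,       # initial total granular-component area per cell
  axis_ratio0 = 0.55,       # initial NPM1 ellipse axis ratio (b/a)
  area_shrink_total = 0.6,  # inhibited: final/initial total NPM1 area
  frag_area_frac = 0.4,     # fragmented: dispersed area / initial area
  reassembled_area_frac = 0.9,
  punct_loss_ubf = 0.25, punct_loss_fbl = 0.2,  # inhibited per-frame loss prob
  drift_sd_um = 0.1)

# per-cell state evolution; returns list of per-frame component descriptions
# (NPM1 ellipses + puncta positions) and the truth rows
simulate_cell <- function(p, fate_fragmented, div_frame, nucleus_r_px) {
  nf <- p$n_frames
  px <- p$pixel_size_um
  n_ubf <- unname(p$initial_counts["ubf"])
  n_fbl <- unname(p$initial_counts["fbl"])
  area0_px <- TL$npm1_area_um2 / px^2
  shrink <- if (p$condition == "inhibited")
    TL$area_shrink_total^(1 / (nf - 1)) else 1

  place_in_disc <- function(n, rmax, min_sep, r_obj = 0) {
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(pts) < n && tries < 20000) {
      tries <- tries + 1
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * (rmax - r_obj)
      cand <- c(rad * cos(ang), rad * sin(ang))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep^2)
        pts <- rbind(pts, cand)
    }
    # fall back to relaxed separation if the disc is crowded
    while (nrow(pts) < n) {
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * (rmax - r_obj)
      pts <- rbind(pts, c(rad * cos(ang), rad * sin(ang)))
    }
    pts
  }

  # NPM1 bodies sit on a ring around the nucleus center, major axis
  # tangential, which guarantees disjoint rendered components
  place_ring <- function(nc, ring_r) {
    phi <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(nc) - 1) / nc
    list(pos = cbind(ring_r * cos(phi), ring_r * sin(phi)),
         theta = (phi + pi / 2) %% pi)
  }

  # initial NPM1 components: equal split of area0
  nc <- p$npm1_components
  comp_area <- rep(area0_px / nc, nc)
  ring <- place_ring(nc, if (nc > 1) 0.45 * nucleus_r_px else 0)
  comp_pos <- ring$pos
  comp_theta <- ring$theta
  q <- TL$axis_ratio0

  ubf_pos <- place_in_disc(n_ubf, nucleus_r_px - 4, 6)
  fbl_pos <- place_in_disc(n_fbl, nucleus_r_px - 4, 7)

  frames <- vector("list", nf)
  truth <- data.frame(frame = seq_len(nf), n_ubf = NA_integer_,
                      n_fbl = NA_integer_, n_npm1 = NA_integer_,
                      npm1_area_um2 = NA_real_, npm1_sphericity = NA_real_)
  post_div_init <- FALSE
  for (f in seq_len(nf)) {
    divided <- !is.na(div_frame) && f >= div_frame
    if (!is.na(div_frame) && f == div_frame) {
      # division: nucleolar components dissolve for one frame
      frames[[f]] <- list(npm1 = NULL, ubf = NULL, fbl = NULL)
      truth[f, 2:6] <- list(0L, 0L, 0L, 0, NA_real_)
      next
    }
    if (divided && !post_div_init) {
      post_div_init <- TRUE
      if (fate_fragmented) {
        nc <- p$n_fragments
        tot <- area0_px * TL$frag_area_frac
        w <- runif(nc, 0.8, 1.2); w <- w / sum(w)
        comp_area <- tot * w
        rr <- sqrt(max(comp_area) / pi)
        comp_pos <- place_in_disc(nc, nucleus_r_px - rr - 2, 3 * rr + 2)
        q <- 0.9
        comp_theta <- runif(nc, 0, pi)
        ubf_pos <- place_in_disc(n_ubf, nucleus_r_px - 4, 6)
        fbl_pos <- place_in_disc(n_fbl, nucleus_r_px - 4, 7)
      } else {
        nc <- sample(1:3, 1)
        tot <- area0_px * TL$reassembled_area_frac
        comp_area <- rep(tot / nc, nc)
        ring <- place_ring(nc, if (nc > 1) 0.45 * nucleus_r_px else 0)
        comp_pos <- ring$pos
        comp_theta <- ring$theta
        q <- TL$axis_ratio0
        ubf_pos <- place_in_disc(n_ubf, nucleus_r_px - 4, 6)
        fbl_pos <- place_in_disc(n_fbl, nucleus_r_px - 4, 7)
      }
    }
    if (!divided && p$condition == "inhibited" && f > 1) {
      comp_area <- comp_area * shrink
      q <- min(1, q + (1 - TL$axis_ratio0) / (nf - 1))
      if (length(comp_area) > 1 && runif(1) < p$condensation_rate) {
        i <- sample(length(comp_area), 2)
        comp_area <- c(comp_area[-i], sum(comp_area[i]))
        keep <- comp_pos[-i, , drop = FALSE]
        comp_pos <- rbind(keep, colMeans(comp_pos[i, , drop = FALSE]))
        comp_theta <- c(comp_theta[-i], runif(1, 0, pi))
      }
      if (n_ubf > 1 && runif(1) < TL$punct_loss_ubf) {
        n_ubf <- n_ubf - 1L; ubf_pos <- ubf_pos[-1, , drop = FALSE]
      }
      if (n_fbl > 1 && runif(1) < TL$punct_loss_fbl) {
        n_fbl <- n_fbl - 1L; fbl_pos <- fbl_pos[-1, , drop = FALSE]
      }
    }
    # ellipse semi-axes from area and axis ratio
    a <- sqrt(comp_area / (pi * q))
    b <- a * q
    frames[[f]] <- list(
      npm1 = data.frame(x = comp_pos[, 1], y = comp_pos[, 2],
                        a = a, b = b, theta = comp_theta),
      ubf = ubf_pos, fbl = fbl_pos)
    truth[f, "n_ubf"] <- n_ubf
    truth[f, "n_fbl"] <- n_fbl
    truth[f, "n_npm1"] <- length(a)
    truth[f, "npm1_area_um2"] <- sum(pi * a * b) * px^2
    truth[f, "npm1_sphericity"] <-
      sum(pi * a * b * ellipse_circularity(a, b)) / sum(pi * a * b)
  }
  list(frames = frames, truth = truth)
}

# smooth ellipse coverage: 1 inside, linear ~1 px edge roll-off
render_ellipse <- function(tile, cx, cy, a, b, theta, amp) {
  n <- nrow(tile)
  r_out <- max(a, b) + 2
  xs <- max(1, floor(cx - r_out)):min(n, ceiling(cx + r_out))
  ys <- max(1, floor(cy - r_out)):min(ncol(tile), ceiling(cy + r_out))
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  de <- sqrt(u^2 + v^2)
  m <- pmin(pmax((1 - de) * sqrt(a * b) + 0.5, 0), 1)
  tile[xs, ys] <- tile[xs, ys] + amp * m
  tile
}

render_spot <- function(tile, cx, cy, sigma, amp) {
  h <- ceiling(3 * sigma)
  xs <- max(1, floor(cx - h)):min(nrow(tile), ceiling(cx + h))
  ys <- max(1, floor(cy - h)):min(ncol(tile), ceiling(cy + h))
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  tile[xs, ys] <- tile[xs, ys] + amp * exp(-d2 / (2 * sigma^2))
  tile
}

#' Simulate a nucleolar time-lapse movie with ground truth
#'
#' See [timelapse_sim_params()] for the model. Returns the rendered
#' 3-channel movie and a truth record holding each cell's final phenotype
#' (`normal`, `condensed`, or `fragmented`), per-frame true component
#' counts, NPM1 area and sphericity, and nucleus center tracks.
#'
#' @param params a [timelapse_sim_params()] object.
#' @return list with `movie` (class `timelapse_movie`: `frames` array of
#'   dim `x, y, channel, frame`, channel order UBF, FBL, NPM1;
#'   `pixel_size_um`; `frame_interval_min`; `channels`) and `truth` (list
#'   with `phenotypes`, `per_frame`, `centers`). With `render = FALSE` in
#'   the parameters, `movie$frames` is `NULL`.
#' @export
simulate_timelapse <- function(params) {
  stopifnot(inherits(params, "timelapse_sim_params"))
  p <- params
  if (p$n_cells == 0) {
    movie <- structure(list(frames = array(0, c(0, 0, 3, 0)),
                            channels = c("UBF", "FBL", "NPM1"),
                            pixel_size_um = p$pixel_size_um,
                            frame_interval_min = p$frame_interval,
                            n_cells = 0L),
                       class = "timelapse_movie")
    truth <- list(phenotypes = data.frame(cell_id = integer(0),
                                          phenotype = character(0),
                                          division_frame = integer(0)),
                  per_frame = data.frame(), centers = array(0, c(0, 2, 0)))
    return(list(movie = movie, truth = truth))
  }
  with_seed(p$seed, {
    tiles_x <- ceiling(sqrt(p$n_cells))
    tiles_y <- ceiling(p$n_cells / tiles_x)
    tp <- p$tile_px
    nucleus_r <- round(0.4 * tp)
    nx <- tiles_x * tp; ny <- tiles_y * tp

    fate <- runif(p$n_cells) < p$fragmentation_probability
    div_frame <- p$division_frame
    # fragmentation only happens through division
    div_frame[fate & is.na(div_frame)] <- max(2L, p$n_frames %/% 2L)

    cells <- vector("list", p$n_cells)
    centers <- array(NA_real_, c(p$n_cells, 2, p$n_frames))
    drift_sd <- TL$drift_sd_um / p$pixel_size_um
    for (ci in seq_len(p$n_cells)) {
      cells[[ci]] <- simulate_cell(p, fate[ci], div_frame[ci], nucleus_r)
      tx <- (ci - 1) %% tiles_x
      ty <- (ci - 1) %/% tiles_x
      pos <- c(tx * tp + tp / 2, ty * tp + tp / 2)
      lim_lo <- c(tx * tp, ty * tp) + nucleus_r + 2
      lim_hi <- c(tx * tp, ty * tp) + tp - nucleus_r - 1
      for (f in seq_len(p$n_frames)) {
        if (f > 1) pos <- pmin(pmax(pos + rnorm(2, 0, drift_sd), lim_lo), lim_hi)
        centers[ci, , f] <- pos
      }
    }

    frames <- NULL
    if (p$render) {
      frames <- array(0, c(nx, ny, 3, p$n_frames))
      for (f in seq_len(p$n_frames)) {
        for (ch in 1:3) {
          img <- matrix(TL$cyto_bg, nx, ny)
          for (ci in seq_len(p$n_cells)) {
            cc <- centers[ci, , f]
            # nucleus disk background
            xs <- max(1, floor(cc[1] - nucleus_r - 1)):
              min(nx, ceiling(cc[1] + nucleus_r + 1))
            ys <- max(1, floor(cc[2] - nucleus_r - 1)):
              min(ny, ceiling(cc[2] + nucleus_r + 1))
            d <- sqrt(outer((xs - cc[1])^2, (ys - cc[2])^2, "+"))
            img[xs, ys] <- img[xs, ys] + (TL$nucleus_bg - TL$cyto_bg) *
              pmin(pmax(nucleus_r - d + 0.5, 0), 1)
            st <- cells[[ci]]$frames[[f]]
            if (ch == 3 && !is.null(st$npm1)) {
              for (k in seq_len(nrow(st$npm1)))
                img <- render_ellipse(img, cc[1] + st$npm1$x[k],
                                      cc[2] + st$npm1$y[k], st$npm1$a[k],
                                      st$npm1$b[k], st$npm1$theta[k],
                                      TL$comp_amp)
            } else if (ch == 1 && !is.null(st$ubf)) {
              for (k in seq_len(nrow(st$ubf)))
                img <- render_spot(img, cc[1] + st$ubf[k, 1],
                                   cc[2] + st$ubf[k, 2], TL$ubf_sigma,
                                   TL$punct_amp)
            } else if (ch == 2 && !is.null(st$fbl)) {
              for (k in seq_len(nrow(st$fbl)))
                img <- render_spot(img, cc[1] + st$fbl[k, 1],
                                   cc[2] + st$fbl[k, 2], TL$fbl_sigma,
                                   TL$punct_amp)
            }
          }
          if (p$noise_sd > 0)
            img <- img + rnorm(length(img), 0, p$noise_sd)
          frames[, , ch, f] <- img
        }
      }
    }

    phen <- ifelse(fate, "fragmented",
                   ifelse(p$condition == "inhibited" & is.na(div_frame),
                          "condensed", "normal"))
    per_frame <- do.call(rbind, lapply(seq_len(p$n_cells), function(ci) {
      tr <- cells[[ci]]$truth
      tr$cell_id <- ci
      tr[, c("cell_id", "frame", "n_ubf", "n_fbl", "n_npm1",
             "npm1_area_um2", "npm1_sphericity")]
    }))
    movie <- structure(list(frames = frames,
                            channels = c("UBF", "FBL", "NPM1"),
                            pixel_size_um = p$pixel_size_um,
                            frame_interval_min = p$frame_interval,
                            n_cells = p$n_cells, tile_px = tp,
                            nucleus_radius_px = nucleus_r),
                       class = "timelapse_movie")
    truth <- list(
      phenotypes = data.frame(cell_id = seq_len(p$n_cells), phenotype = phen,
                              division_frame = div_frame),
      per_frame = per_frame, centers = centers)
    list(movie = movie, truth = truth)
  })
}

#' @export
print.timelapse_movie <- function(x, ...) {
  d <- if (is.null(x$frames)) c(0, 0, 3, 0) else dim(x$frames)
  cat(sprintf("<timelapse_movie> %d cells, %d frames, %dx%d px, %.3g um/px, %g min/frame\n",
              x$n_cells, d[4], d[1], d[2], x$pixel_size_um,
              x$frame_interval_min))
  invisible(x)
}
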