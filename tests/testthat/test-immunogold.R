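test_that("EM simulator conserves requested counts and is reproducible", {
  p <- em_sim_params(n_large = 30, n_small = 60, n_outside_large = 10,
                     n_outside_small = 20, seed = 1)
  sim <- simulate_em_image(p)
  expect_equal(nrow(sim$truth), 120)
  expect_equal(sum(sim$truth$size_class == "12nm" & sim$truth$in_roi), 30)
  expect_equal(sum(sim$truth$size_class == "6nm" & !sim$truth$in_roi), 20)
  expect_identical(simulate_em_image(p), sim)

  empty <- simulate_em_image(em_sim_params(n_large = 0, n_small = 0,
                                           n_outside_large = 0,
                                           n_outside_small = 0,
                                           background_noise_sd = 0, seed = 1))
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$field$image == 0.6))
})

test_that("a 12 nm particle at 2 nm/px renders as a ~6 px disk", {
  sim <- simulate_em_image(em_sim_params(
    image_shape = c(128, 128), n_large = 1, n_small = 0,
    n_outside_large = 0, n_outside_small = 0, background_noise_sd = 0,
    seed = 2))
  dark <- sim$field$image < 0.6 - 0.5 * 0.35  # > 50% particle coverage
  expect_equal(sum(dark), pi * 3^2, tolerance = 0.15)
  rows <- range(which(rowSums(dark) > 0))
  expect_true((diff(rows) + 1) %in% 5:7)  # ~6 px, +/- 1 px rasterization
})

test_that("impossible particle packing raises a placement error", {
  expect_error(simulate_em_image(em_sim_params(
    image_shape = c(64, 64), n_large = 200, min_separation = 30, seed = 1)),
    "placement failure")
})

test_that("single-scale LoG detection localizes dark disks", {
  img <- matrix(0.6, 128, 128)
  add_disk <- function(im, cx, cy, r) {
    d <- sqrt(outer((1:128 - cx)^2, (1:128 - cy)^2, "+"))
    im - 0.35 * pmin(pmax(r - d + 0.5, 0), 1)
  }
  expect_equal(nrow(log_detect(img, 12, 2)), 0)  # blank background
  one <- add_disk(img, 51, 61, 3)  # 0-based center (50, 60)
  det <- log_detect(one, 12, 2)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x_px - 50)^2 + (det$y_px - 60)^2), 1.01)
  two <- add_disk(add_disk(img, 40, 64, 3), 76, 64, 3)  # 3 diameters apart
  expect_equal(nrow(log_detect(two, 12, 2)), 2)
  expect_error(log_detect(img, 3, 2), "resolvable")
})

test_that("exclusion zones use an open boundary and preserve order", {
  cand <- data.frame(x_px = c(10, 5, 4, 30), y_px = c(0, 0, 0, 0),
                     response = c(4, 3, 2, 1))
  none <- data.frame(x_px = numeric(0), y_px = numeric(0))
  expect_identical(exclude_around(cand, none, 10, 2), cand)
  anchors <- data.frame(x_px = 0, y_px = 0)
  # radius 10 nm at 2 nm/px = 5 px: candidate at exactly 5 px is retained,
  # candidates strictly inside (and at the anchor) are removed
  out <- exclude_around(cand, anchors, 10, 2)
  expect_equal(out$x_px, c(10, 5, 30))
  at_anchor <- data.frame(x_px = 0, y_px = 0, response = 9)
  expect_equal(nrow(exclude_around(at_anchor, anchors, 10, 2)), 0)
  expect_error(exclude_around(cand, anchors, 0, 2), "radius_nm")
})

test_that("two-pass detection reaches F1 >= 0.95 per class on synthetic fields", {
  for (seed in 1:3) {
    sim <- simulate_em_image(em_sim_params(seed = seed))
    ps <- detect_two_pass(sim$field)
    for (cls in c("12nm", "6nm")) {
      r_px <- as.numeric(sub("nm", "", cls)) / 2 / sim$field$pixel_size
      m <- match_detections(ps[ps$size_class == cls, ],
                            sim$truth[sim$truth$size_class == cls, ], r_px)
      expect_gte(f1_score(m), 0.95)
    }
    # exclusion invariant holds on every output
    p12 <- ps[ps$size_class == "12nm", ]
    p6 <- ps[ps$size_class == "6nm", ]
    if (nrow(p12) && nrow(p6)) {
      dmin <- min(sqrt(outer(p6$x_px, p12$x_px, "-")^2 +
                         outer(p6$y_px, p12$y_px, "-")^2)) *
        sim$field$pixel_size
      expect_gte(dmin, default_exclusion_radius())
    }
    # same-class minimum separation >= one diameter
    d12 <- as.matrix(dist(p12[, c("x_px", "y_px")])) * sim$field$pixel_size
    expect_gte(min(d12[upper.tri(d12)]), 12)
  }
})

test_that("a field with only 12 nm particles yields no 6 nm hits at their sites", {
  sim <- simulate_em_image(em_sim_params(n_small = 0, n_outside_small = 0,
                                         seed = 4))
  ps <- detect_two_pass(sim$field)
  p6 <- ps[ps$size_class == "6nm", ]
  if (nrow(p6)) {
    d <- sqrt(outer(p6$x_px, sim$truth$x_px, "-")^2 +
                outer(p6$y_px, sim$truth$y_px, "-")^2) * sim$field$pixel_size
    expect_gte(min(d), default_exclusion_radius())
  }
  expect_identical(detect_two_pass(sim$field), ps)  # determinism
})

test_that("detection is equivariant to integer translations", {
  sim <- simulate_em_image(em_sim_params(image_shape = c(256, 256),
                                         n_large = 8, n_small = 16,
                                         n_outside_large = 0,
                                         n_outside_small = 0, seed = 5))
  shift <- function(m, dx, dy) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - dx) %% n) + 1, ((seq_len(ncol(m)) - 1 - dy) %% ncol(m)) + 1]
  }
  f0 <- sim$field
  f1 <- em_field(shift(f0$image, 7, 11), f0$pixel_size,
                 shift(f0$roi_mask, 7, 11))
  d0 <- detect_two_pass(f0)
  d1 <- detect_two_pass(f1)
  key <- function(d) {
    o <- order(d$x_px, d$y_px)
    paste(d$x_px[o], d$y_px[o], d$size_class[o])
  }
  d0$x_px <- (d0$x_px + 7) %% 256
  d0$y_px <- (d0$y_px + 11) %% 256
  expect_identical(key(d0), key(d1))
})

test_that("density arithmetic is exact and unit-consistent", {
  mask <- matrix(TRUE, 1000, 1000)  # 1e6 px
  fld <- em_field(matrix(0.5, 1000, 1000), pixel_size = 1, roi_mask = mask)
  parts <- structure(
    data.frame(x_px = seq(10, 100, 10), y_px = seq(10, 100, 10),
               size_class = "12nm", response = 1, in_roi = TRUE),
    class = c("particle_set", "data.frame"))
  d <- particle_density(fld, parts)
  expect_equal(d$roi_area_nm2, 1e6)
  expect_equal(d$density_12, 1e-5)
  expect_equal(d$count_12 + d$count_6,
               sum(parts$in_roi))  # per-class counts conserve totals
  # zero particles
  none <- parts[0, ]
  expect_equal(particle_density(fld, none)$density_12, 0)
  # doubling pixel size quarters the density at fixed mask pixel count
  fld2 <- em_field(matrix(0.5, 1000, 1000), pixel_size = 2, roi_mask = mask)
  expect_equal(particle_density(fld2, parts)$density_12, 1e-5 / 4)
  # empty ROI errors
  fld0 <- em_field(matrix(0.5, 10, 10), 1, matrix(FALSE, 10, 10))
  expect_error(particle_density(fld0, parts), "empty ROI")
})

test_that("density comparison detects a true reduction and respects the null", {
  # per-image labeling density varies from section to section: draw the
  # per-image particle count around the group mean
  dens_for <- function(mean_large, seed) {
    set.seed(seed)
    n <- max(1, rpois(1, mean_large))
    sim <- simulate_em_image(em_sim_params(
      image_shape = c(256, 256), n_large = n, n_small = rpois(1, 18),
      n_outside_large = 2, n_outside_small = 4, seed = seed))
    particle_density(sim$field, detect_two_pass(sim$field))
  }
  control <- lapply(1:10, function(s) dens_for(12, s))
  mutant <- lapply(1:10, function(s) dens_for(5, 100 + s))  # ~40% of control
  cmp <- compare_densities(control, mutant)
  expect_lt(cmp[["12nm"]]$p, 0.05)
  expect_gt(cmp[["12nm"]]$mean_a, cmp[["12nm"]]$mean_b)
  # identical groups: t = 0, p = 1
  same <- compare_densities(control, control)
  expect_equal(same[["12nm"]]$p, 1)
  expect_error(compare_densities(control[1], mutant), "n >= 2")
})

test_that("equal-density groups are non-significant in >= 90% of repeats", {
  # type-I behaviour of the comparison on detector-derived densities: a
  # pool of equal-density synthetic fields is measured once, then group
  # labels are resampled 100 times under the null
  pool <- lapply(1:40, function(s) {
    set.seed(3000 + s)
    sim <- simulate_em_image(em_sim_params(
      image_shape = c(128, 128), n_large = max(1, rpois(1, 6)),
      n_small = max(1, rpois(1, 10)),
      n_outside_large = 1, n_outside_small = 2, seed = 3000 + s))
    particle_density(sim$field, detect_two_pass(sim$field))
  })
  set.seed(99)
  nonsig <- c("12nm" = 0, "6nm" = 0)
  for (r in 1:100) {
    idx <- sample(40, 20)
    cmp <- compare_densities(pool[idx[1:10]], pool[idx[11:20]])
    for (cls in names(nonsig))
      if (cmp[[cls]]$p >= 0.05) nonsig[cls] <- nonsig[cls] + 1
  }
  expect_gte(nonsig[["12nm"]], 90)
  expect_gte(nonsig[["6nm"]], 90)
})
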