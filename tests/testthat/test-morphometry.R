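test_that("segmentation counts match a brute-force flood fill oracle", {
  set.seed(5)
  for (r in 1:8) {
    img <- matrix(runif(400), 20, 20)
    mask <- matrix(TRUE, 20, 20)
    tab <- segment_components(img, mask, threshold = 0.7, min_size_px = 1)
    expect_equal(nrow(tab), flood_fill_count(img > 0.7))
  }
})

test_that("blank channels give empty component tables, not errors", {
  img <- matrix(0.1 + rnorm(400, 0, 0.02), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(nrow(segment_components(img, mask)), 0)
  expect_error(segment_components(img, matrix(FALSE, 20, 20)), "empty cell mask")
})

test_that("disjoint rendered blobs are counted exactly", {
  sim <- simulate_timelapse(timelapse_sim_params(n_cells = 1, n_frames = 2,
                                                 noise_sd = 0, seed = 8))
  fr <- sim$movie$frames[, , 2, 1]  # FBL channel: well-separated puncta
  mask <- fr > -Inf
  tab <- segment_components(fr, mask, threshold = 0.4)
  expect_equal(nrow(tab), sim$truth$per_frame$n_fbl[1])
})

test_that("merging conserves NPM1 area within discretization tolerance", {
  sim <- simulate_timelapse(timelapse_sim_params(
    n_cells = 4, n_frames = 8, condition = "inhibited",
    condensation_rate = 1, noise_sd = 0, seed = 9))
  ana <- analyze_timelapse(sim$movie)
  for (tid in unique(ana$series$track_id)) {
    s <- ana$series[ana$series$track_id == tid, ]
    s <- s[order(s$frame), ]
    expect_equal(s$n_npm1[1], 2)
    expect_equal(s$n_npm1[nrow(s)], 1)  # condensation_rate 1 merges at once
    # measured area shrinks only by the generator's deterministic ramp
    expected_ratio <- 0.6^((nrow(s) - 1) / (nrow(s) - 1))
    expect_equal(s$npm1_area_um2[nrow(s)] / s$npm1_area_um2[1],
                 0.6, tolerance = 0.1)
  }
})

test_that("sphericity of rasterized disks converges monotonically to 1", {
  sph <- vapply(c(5, 15, 30), function(r) measure_shape(mk_disk(r))$sphericity,
                numeric(1))
  expect_true(all(diff(abs(1 - sph)) < 0))
  expect_gte(sph[3], 0.95)
  expect_lte(sph[3], 1.05)
  # elongated limit
  line <- matrix(0, 70, 10)
  line[5:64, 5] <- 1
  expect_lt(measure_shape(line)$sphericity, 0.3)
  # degenerate single pixel
  px1 <- matrix(0, 5, 5); px1[3, 3] <- 1
  m <- measure_shape(px1)
  expect_true(m$degenerate)
  expect_true(is.na(m$sphericity))
})

test_that("3-D sphericity of rasterized balls approaches the analytic value", {
  s5 <- measure_shape(mk_ball(5))$sphericity
  s15 <- measure_shape(mk_ball(15))$sphericity
  expect_gte(s15, 0.9)
  expect_lte(s15, 1.05)
  expect_lt(abs(1 - s15), abs(1 - s5))
  # volume is exact, surface within a few percent of 4*pi*r^2
  m <- measure_shape(mk_ball(15), pixel_size_um = 2)
  expect_equal(m$area_or_volume, sum(mk_ball(15)) * 8)
  expect_equal(m$perimeter_or_surface / 4, 4 * pi * 15^2, tolerance = 0.05)
})

test_that("tracking keeps identity for stationary cells and gates jumps", {
  det <- data.frame(frame = rep(1:5, each = 1), x_px = 10 + 0.1 * (1:5),
                    y_px = 20, det_id = 1)
  tr <- track_cells(det, pixel_size_um = 1, max_disp_um = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  # displacements beyond the gate terminate tracks instead of relinking
  swap <- data.frame(frame = c(1, 1, 2, 2),
                     x_px = c(0, 100, 50, 150), y_px = 0,
                     det_id = c(1, 2, 1, 2))
  tr2 <- track_cells(swap, pixel_size_um = 1, max_disp_um = 10)
  expect_equal(length(unique(tr2$track_id)), 4)
})

test_that("a default control movie tracks every cell and matches truth counts", {
  sim <- simulate_timelapse(timelapse_sim_params(n_cells = 12, n_frames = 31,
                                                 seed = 21))
  ana <- analyze_timelapse(sim$movie)
  expect_equal(length(unique(ana$tracks$track_id)), 12)
  # match tracks to generator cells through the first-frame nucleus centers
  f1 <- ana$tracks[ana$tracks$frame == 1, ]
  truth_xy <- sim$truth$centers[, , 1]
  cell_of <- vapply(seq_len(nrow(f1)), function(i)
    which.min((truth_xy[, 1] - 1 - f1$x_px[i])^2 +
                (truth_xy[, 2] - 1 - f1$y_px[i])^2), integer(1))
  expect_equal(sort(cell_of), 1:12)
  map <- setNames(cell_of, f1$track_id)
  ser <- ana$series
  ser$cell_id <- map[as.character(ser$track_id)]
  merged <- merge(ser, sim$truth$per_frame, by = c("cell_id", "frame"),
                  suffixes = c("_meas", "_true"))
  agree <- (merged$n_ubf_meas == merged$n_ubf_true) +
    (merged$n_fbl_meas == merged$n_fbl_true) +
    (merged$n_npm1_meas == merged$n_npm1_true)
  expect_gte(mean(agree == 3), 0.9)
  # measured NPM1 area within 15% of truth on average
  rel <- abs(merged$npm1_area_um2_meas - merged$npm1_area_um2_true) /
    merged$npm1_area_um2_true
  expect_lt(mean(rel), 0.15)
})

test_that("population summaries use t-based confidence intervals", {
  set.seed(3)
  v <- rnorm(15)
  v <- (v - mean(v)) / sd(v) + 5  # unit variance exactly
  ser <- data.frame(frame = 1, n_ubf = v)
  s <- summarize_population(ser, metrics = "n_ubf")
  hw <- (s$ci_hi - s$ci_lo) / 2
  expect_equal(hw, qt(0.975, 14) / sqrt(15), tolerance = 1e-10)
  expect_equal(hw, 0.5539, tolerance = 1e-3)
  # zero variance: zero-width interval
  s0 <- summarize_population(data.frame(frame = 1, n_ubf = rep(4, 8)),
                             metrics = "n_ubf")
  expect_equal(s0$ci_lo, s0$ci_hi)
  # single-cell frames flagged with undefined interval
  s1 <- summarize_population(data.frame(frame = 1:2, n_ubf = c(1, 2)),
                             metrics = "n_ubf")
  expect_true(all(s1$flagged))
  expect_true(all(is.na(s1$ci_lo)))
})

test_that("measured inhibited dynamics reproduce the reported directions", {
  sim <- simulate_timelapse(timelapse_sim_params(
    n_cells = 8, n_frames = 15, condition = "inhibited", seed = 5))
  ana <- analyze_timelapse(sim$movie)
  s <- summarize_population(ana$series)
  first_last <- function(metric) {
    v <- s[s$metric == metric, ]
    c(v$mean[1], v$mean[nrow(v)])
  }
  expect_lt(first_last("n_ubf")[2], first_last("n_ubf")[1])
  expect_lt(first_last("n_fbl")[2], first_last("n_fbl")[1])
  expect_lt(first_last("npm1_area_um2")[2], first_last("npm1_area_um2")[1])
  expect_gt(first_last("npm1_sphericity")[2], first_last("npm1_sphericity")[1])
})

test_that("phenotype rules are applied as specified", {
  expect_equal(classify_phenotype(1, 1, 0.95)$phenotype, "condensed")
  expect_equal(classify_phenotype(10, 0.1, 0.9)$phenotype, "fragmented")
  expect_equal(classify_phenotype(3, 0.6, 0.8)$phenotype, "normal")
  expect_equal(classify_phenotype(1, 1, 0.7)$phenotype, "normal")
  expect_equal(classify_phenotype(0, NA, NA)$phenotype, "unclassifiable")
  # a dominant large component vetoes a fragmented call at high counts
  expect_equal(classify_phenotype(8, 0.8, 0.9)$phenotype, "normal")
})

test_that("classifier matches generator fate in a mixed dividing population", {
  sc <- fragmentation_scenario(n_cells = 40, fragmentation_probability = 0.3,
                               dividing = "all", seed = 31, n_frames = 11)
  truth_k <- sum(sc$truth$phenotypes$phenotype == "fragmented")
  call_k <- sum(sc$calls$phenotype == "fragmented")
  expect_lte(abs(call_k - truth_k), 1)
})

test_that("noiseless control populations yield zero fragmented calls", {
  sc <- fragmentation_scenario(n_cells = 50, fragmentation_probability = 0,
                               dividing = "none", seed = 41, n_frames = 6,
                               noise_sd = 0)
  expect_equal(sum(sc$calls$phenotype == "fragmented"), 0)
  expect_equal(nrow(sc$calls), 50)
})

test_that("fragmented fractions and the across-condition ANOVA are exact", {
  mk_calls <- function(n, k, cond, rep_id)
    data.frame(phenotype = c(rep("fragmented", k), rep("normal", n - k)),
               condition = cond, replicate = rep_id)
  none <- fraction_fragmented(mk_calls(40, 0, "ctrl", 1))
  expect_equal(none$summary$pct_fragmented, 0)
  some <- fraction_fragmented(mk_calls(40, 3, "bmh21", 1))
  expect_equal(some$summary$pct_fragmented, 7.5)
  expect_error(fraction_fragmented(
    data.frame(phenotype = rep("unclassifiable", 3), condition = "x")),
    "zero classifiable")
  # identical per-replicate percentages across conditions: ANOVA p = 1
  calls <- rbind(mk_calls(40, 4, "a", 1), mk_calls(40, 2, "a", 2),
                 mk_calls(40, 4, "b", 1), mk_calls(40, 2, "b", 2),
                 mk_calls(40, 4, "c", 1), mk_calls(40, 2, "c", 2))
  res <- fraction_fragmented(calls)
  expect_equal(res$anova_p, 1)
  expect_equal(res$summary$pct_fragmented, rep(7.5, 3))
})
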