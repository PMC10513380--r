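test_that("bleach detection finds the largest drop, earliest on ties", {
  tr <- frap_trajectory(times = 0:5, intensities = c(1, 1, 1, 0.1, 0.4, 0.7),
                        bleach_index = 1)
  expect_equal(detect_bleach_index(tr), 4L)
  mono <- frap_trajectory(times = 0:5, intensities = seq(0, 1, length.out = 6),
                          bleach_index = 1)
  expect_error(detect_bleach_index(mono), "no bleach event")
  # generator ground truth as oracle
  sim <- simulate_frap_curve(frap_sim_params(noise_sd = 0.02, seed = 3))
  expect_equal(detect_bleach_index(sim), sim$bleach_index)
})

test_that("min-max normalization is exact, idempotent and invertible", {
  tr <- frap_trajectory(times = 0:2, intensities = c(2, 10, 6), bleach_index = 1)
  nt <- normalize_trajectory(tr)
  expect_equal(nt$intensities, c(0, 1, 0.5))
  expect_equal(normalize_trajectory(nt)$intensities, nt$intensities)
  expect_lt(max(abs(denormalize_trajectory(nt)$intensities - tr$intensities)),
            1e-12)
  flat <- frap_trajectory(times = 0:2, intensities = rep(3, 3), bleach_index = 1)
  expect_error(normalize_trajectory(flat), "zero dynamic range")
})

test_that("bleach alignment pads with missing values on a common grid", {
  mk <- function(n_pre) {
    p <- frap_sim_params(n_prebleach_frames = n_pre, noise_sd = 0, seed = 1)
    normalize_trajectory(simulate_frap_curve(p))
  }
  two <- align_bleach(list(mk(5), mk(7)))
  expect_equal(two[[1]]$bleach_index, 8L)
  expect_equal(two[[2]]$bleach_index, 8L)
  expect_true(all(is.na(two[[1]]$intensities[1:2])))
  expect_false(anyNA(two[[1]]$intensities[-(1:2)]))
  single <- align_bleach(list(mk(4)))
  expect_equal(single[[1]]$intensities, mk(4)$intensities)
  expect_error(align_bleach(list()), "empty")
})

test_that("aligned ensemble mean at the bleach frame is near zero", {
  noise_sd <- 0.02
  trajs <- lapply(1:30, function(s) {
    p <- frap_sim_params(n_prebleach_frames = 3 + (s %% 5),
                         noise_sd = noise_sd, seed = s)
    normalize_trajectory(simulate_frap_curve(p))
  })
  al <- align_bleach(trajs)
  m <- mean_recovery(al)
  bi <- al[[1]]$bleach_index
  expect_equal(m$n[bi], 30)
  # min-max normalization biases the bleach frame slightly above raw noise,
  # so allow the generator-oracle band on the normalized scale
  expect_lt(abs(m$mean_intensity[bi]), 3 * noise_sd / sqrt(30) + noise_sd)
})

test_that("whole-bleach fit recovers noiseless parameters to high accuracy", {
  p <- frap_sim_params(geometry = "whole", amp2 = 0.9, tau2 = 20, noise_sd = 0)
  fit <- fit_whole_frap(normalize_trajectory(simulate_frap_curve(p)))
  expect_true(fit$converged)
  expect_equal(fit$tau, 20, tolerance = 1e-6)
  expect_equal(fit$percent_recovery, 90, tolerance = 1e-4 / 90)
})

test_that("whole-bleach fit is unbiased on a noisy ensemble", {
  taus <- vapply(1:30, function(s) {
    p <- frap_sim_params(geometry = "whole", amp2 = 0.9, tau2 = 20,
                         noise_sd = 0.02, seed = s)
    fit_whole_frap(normalize_trajectory(simulate_frap_curve(p)))$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 20) / 20, 0.05)
})

test_that("flat zero post-bleach curve is flagged degenerate", {
  tr <- frap_trajectory(times = (0:20) * 0.5,
                        intensities = c(1, 1, 1, rep(0, 18)),
                        bleach_index = 4, geometry = "whole")
  tr$normalization <- list(raw_min = 0, raw_max = 1)
  fit <- fit_whole_frap(tr)
  expect_true(fit$degenerate)
  expect_equal(fit$plateau, 0)
  expect_equal(fit$percent_recovery, 0)
})

test_that("constrained half-bleach fit recovers tau1 and echoes tau2 bit-exactly", {
  p <- frap_sim_params(tau1 = 3.33, tau2 = 25, amp1 = 0.5, amp2 = 0.4,
                       noise_sd = 0)
  nt <- normalize_trajectory(simulate_frap_curve(p))
  fit <- fit_half_frap(nt, tau2 = 25)
  expect_true(fit$converged)
  expect_equal(fit$tau1, 3.33, tolerance = 0.01 / 3.33)
  expect_identical(fit$tau2_fixed, 25)
  expect_equal(fit$amp1, 0.5, tolerance = 1e-2)
  expect_equal(fit$plateau, fit$amp1 + fit$amp2)
})

test_that("half-bleach fit reduces to whole-bleach behaviour when amp1 = 0", {
  p <- frap_sim_params(tau1 = 3, tau2 = 25, amp1 = 0, amp2 = 0.9, noise_sd = 0)
  nt <- normalize_trajectory(simulate_frap_curve(p))
  fit <- fit_half_frap(nt, tau2 = 25)
  expect_lt(fit$amp1, 1e-3)
  expect_equal(fit$amp2, 0.9, tolerance = 1e-3)
})

test_that("half fit with amp2 forced to zero reproduces the whole-bleach tau", {
  for (noise in c(0, 0.02)) {
    p <- frap_sim_params(geometry = "whole", amp2 = 0.85, tau2 = 18,
                         noise_sd = noise, seed = 4)
    tr <- simulate_frap_curve(p)
    whole <- fit_whole_frap(normalize_trajectory(tr))
    half_tr <- tr
    half_tr$geometry <- "half"
    nested <- fit_half_frap(normalize_trajectory(half_tr), tau2 = 50,
                            amp2_fixed = 0)
    expect_lt(abs(nested$tau1 - whole$tau) / whole$tau, 1e-6)
  }
})

test_that("fitted time constants are invariant to raw intensity scaling", {
  p <- frap_sim_params(tau1 = 4, tau2 = 30, amp1 = 0.45, amp2 = 0.45,
                       noise_sd = 0.02, seed = 9)
  tr <- simulate_frap_curve(p)
  scaled <- tr
  scaled$intensities <- tr$intensities * 417.3
  f1 <- fit_half_frap(normalize_trajectory(tr), tau2 = 30)
  f2 <- fit_half_frap(normalize_trajectory(scaled), tau2 = 30)
  expect_equal(f1$tau1, f2$tau1, tolerance = 1e-6)  # optimizer tolerance
})

test_that("parameter recovery stays within 10% for both mixing regimes", {
  for (tau1_true in c(3.33, 9.05)) {
    tau2_true <- 5 * tau1_true + 10
    t1 <- vapply(1:30, function(s) {
      p <- frap_sim_params(tau1 = tau1_true, tau2 = tau2_true, amp1 = 0.5,
                           amp2 = 0.4, noise_sd = 0.02, seed = 200 + s)
      fit_half_frap(normalize_trajectory(simulate_frap_curve(p)),
                    tau2 = tau2_true)$tau1
    }, numeric(1))
    expect_lt(abs(mean(t1) - tau1_true) / tau1_true, 0.1)
  }
})

test_that("percent recovery reports the fitted plateau", {
  p <- frap_sim_params(geometry = "whole", amp2 = 0.9, tau2 = 20, noise_sd = 0)
  fit <- fit_whole_frap(normalize_trajectory(simulate_frap_curve(p)))
  expect_equal(percent_recovery(fit), fit$percent_recovery)
  expect_equal(round(percent_recovery(fit)), 90)
  bad <- fit
  bad$converged <- FALSE
  expect_error(percent_recovery(bad), "diagnostics")
  # full recovery boundary
  pf <- frap_sim_params(geometry = "whole", amp2 = 1, tau2 = 10, noise_sd = 0)
  expect_equal(percent_recovery(fit_whole_frap(
    normalize_trajectory(simulate_frap_curve(pf)))), 100, tolerance = 1e-3)
})

test_that("lower-plateau ensembles show lower mean percent recovery", {
  fit_group <- function(plateau, seed0) {
    lapply(1:30, function(s) {
      p <- frap_sim_params(geometry = "whole", amp2 = plateau, tau2 = 20,
                           noise_sd = 0.02, seed = seed0 + s)
      fit_whole_frap(normalize_trajectory(simulate_frap_curve(p)))
    })
  }
  control <- fit_group(0.9, 0)
  treated <- fit_group(0.8, 500)
  mean_pr <- function(fits)
    mean(vapply(fits, function(f) f$percent_recovery, numeric(1)))
  expect_lt(mean_pr(treated), mean_pr(control))
})

test_that("group comparison matches the classical pooled-variance t test", {
  mkfit <- function(v) structure(list(tau = v, converged = TRUE),
                                 class = "whole_frap_fit")
  a <- lapply(c(1, 2, 3), mkfit)
  b <- lapply(c(4, 5, 6), mkfit)
  cmp <- compare_groups(a, b, field = "tau")
  # independent oracle: classical formula by hand
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(4, 5, 6))) / 4
  t_hand <- (2 - 5) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(t_hand, df = 4)
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p, p_hand, tolerance = 1e-12)
  expect_equal(cmp$t, -3.674, tolerance = 1e-3)
  expect_equal(cmp$p, 0.0214, tolerance = 1e-2)
  # identical groups: t = 0, p = 1
  same <- compare_groups(a, a, field = "tau")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # mixed fit types rejected
  hf <- structure(list(tau1 = 1, converged = TRUE), class = "half_frap_fit")
  expect_error(compare_groups(c(a, list(hf)), b, field = "tau"), "mixed")
})

test_that("control and inhibited tau1 ensembles separate significantly", {
  fits <- function(tau1, tau2, seed0) {
    lapply(1:30, function(s) {
      p <- frap_sim_params(tau1 = tau1, tau2 = tau2, amp1 = 0.5, amp2 = 0.4,
                           noise_sd = 0.02, seed = seed0 + s)
      fit_half_frap(normalize_trajectory(simulate_frap_curve(p)), tau2 = tau2)
    })
  }
  cmp <- compare_groups(fits(3.33, 25, 0), fits(9.05, 50, 900), field = "tau1")
  expect_lt(cmp$p, 0.01)
})
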