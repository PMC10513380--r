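#' Constrained half-FRAP parameter-recovery protocol
#'
#' The full two-step fitting protocol on simulated ensembles: simulate
#' `n` whole-bleach curves (single component, time constant
#' `tau_whole`), fit each with the single exponential and average the
#' fitted time constants; then simulate `n` half-bleach curves (fast
#' component `tau1`, slow component `tau_whole`) and fit each with the
#' double exponential holding `tau2` at the whole-fit mean. Useful for
#' checking how well the pipeline recovers a known fast mixing time
#' under realistic sampling (0.5 s interval, 2 min recovery) and noise.
#'
#' @param tau1 true fast time constant, seconds.
#' @param tau_whole true slow (whole-bleach) time constant, seconds.
#' @param n curves per ensemble.
#' @param noise_sd per-frame Gaussian noise, normalized units.
#' @param amp1,amp2 true amplitudes of the half-bleach curve.
#' @param seed_base integer; whole-curve seeds are `seed_base + 1:n`,
#'   half-curve seeds `seed_base + 100 + 1:n`.
#' @param condition label.
#' @return list with `mean_tau1` (the recovered fast constant averaged
#'   over converged fits), `mean_tau_whole`, `tau2_fixed`, `whole_fits`,
#'   `half_fits`, `n`.
#' @export
frap_recovery_protocol <- function(tau1, tau_whole, n = 30, noise_sd = 0.02,
                                   amp1 = 0.5, amp2 = 0.4, seed_base = 0,
                                   condition = "control") {
  whole <- simulate_frap_ensemble(
    frap_sim_params(tau2 = tau_whole, amp2 = amp1 + amp2, geometry = "whole",
                    noise_sd = noise_sd, condition = condition),
    n, seeds = seed_base + seq_len(n))
  half <- simulate_frap_ensemble(
    frap_sim_params(tau1 = tau1, tau2 = tau_whole, amp1 = amp1, amp2 = amp2,
                    geometry = "half", noise_sd = noise_sd,
                    condition = condition),
    n, seeds = seed_base + 100 + seq_len(n))
  res <- fit_frap_experiment(whole, half, tau2_mode = "condition_mean")
  taus_w <- vapply(res$whole_fits, function(f)
    if (isTRUE(f$converged)) f$tau else NA_real_, numeric(1))
  taus1 <- vapply(res$half_fits, function(f)
    if (isTRUE(f$converged)) f$tau1 else NA_real_, numeric(1))
  list(mean_tau1 = mean(taus1, na.rm = TRUE),
       mean_tau_whole = mean(taus_w, na.rm = TRUE),
       tau2_fixed = res$tau2_used,
       whole_fits = res$whole_fits, half_fits = res$half_fits, n = n)
}

#' Simulate, analyze and phenotype a dividing cell population
#'
#' End-to-end fragmentation scoring on synthetic data: generate a
#' time-lapse population in which some or all cells divide, run nucleus
#' segmentation, tracking, per-channel component measurement
#' ([analyze_timelapse()]) and end-point phenotype classification
#' ([classify_population()]), then score the percentage of classifiable
#' cells called fragmented.
#'
#' @param n_cells population size.
#' @param fragmentation_probability population-level probability that a
#'   cell ends fragmented (fragmenting cells necessarily divide).
#' @param dividing `"all"` (synchronized release: every cell divides at
#'   the movie midpoint), `"subset"` (an unsynchronized culture: half the
#'   cells divide, staggered around the midpoint), or `"none"`.
#' @param condition `"control"` or `"inhibited"` (affects non-dividing
#'   cell dynamics only).
#' @param n_frames movie length in frames.
#' @param seed integer seed.
#' @param ... further arguments to [timelapse_sim_params()].
#' @return list with `pct_fragmented`, `calls`, `truth`, `analysis`.
#' @export
fragmentation_scenario <- function(n_cells = 200,
                                   fragmentation_probability = 0,
                                   dividing = c("all", "subset", "none"),
                                   condition = "control", n_frames = 21,
                                   seed = 1, ...) {
  dividing <- match.arg(dividing)
  mid <- max(2L, n_frames %/% 2L)
  division_frame <- switch(
    dividing,
    all = rep(mid, n_cells),
    none = NULL,
    subset = {
      df <- rep(NA_integer_, n_cells)
      half <- seq_len(n_cells) %% 2 == 0
      df[half] <- mid + (seq_len(sum(half)) %% 5L) - 2L
      df
    })
  sim <- simulate_timelapse(timelapse_sim_params(
    n_cells = n_cells, n_frames = n_frames, condition = condition,
    division_frame = division_frame,
    fragmentation_probability = fragmentation_probability,
    seed = seed, ...))
  ana <- analyze_timelapse(sim$movie)
  calls <- classify_population(ana$series)
  calls$condition <- "all"
  frac <- fraction_fragmented(calls)
  list(pct_fragmented = frac$summary$pct_fragmented[1],
       calls = calls, truth = sim$truth, analysis = ana)
}
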