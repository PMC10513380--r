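#' Parameters for the FRAP curve simulator
#'
#' Describes a normalized fluorescence-recovery curve with a fast
#' intranucleolar mixing component (`tau1`, amplitude `amp1`) and a slow
#' nucleoplasmic-exchange component (`tau2`, amplitude `amp2`). Curves are
#' generated already min-max normalized: pre-bleach frames sit at 1, the
#' bleach frame at 0, so `amp1 + amp2` must equal `plateau`. Whole-bleach
#' geometry has a single diffusive component (`amp1 = 0`).
#'
#' Defaults mirror a spinning-disk half-FRAP protocol: 5 pre-bleach frames,
#' 0.5 s sampling, 2 min of recovery. The default noise (sd 0.02 on the
#' normalized scale) and the amplitude split are generator assumptions, not
#' measured values.
#'
#' @param tau1 fast time constant, seconds (ignored for `geometry = "whole"`).
#' @param tau2 slow time constant, seconds.
#' @param amp1,amp2 recovery amplitudes on the normalized scale.
#' @param plateau asymptotic recovery level in (0, 1]; must equal
#'   `amp1 + amp2` (tolerance 1e-8).
#' @param n_prebleach_frames number of pre-bleach frames (>= 3 for fitting).
#' @param frame_interval seconds between frames.
#' @param duration post-bleach recovery duration, seconds.
#' @param noise_sd i.i.d. Gaussian noise sd per frame, normalized units.
#' @param geometry `"half"` or `"whole"`.
#' @param seed integer seed; identical seeds give bit-identical curves.
#' @param cell_id,condition labels attached to the trajectory.
#' @return an object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(tau1 = 3.33, tau2 = 25, amp1 = 0.5, amp2 = 0.4,
                            plateau = amp1 + amp2,
                            n_prebleach_frames = 5, frame_interval = 0.5,
                            duration = 120, noise_sd = 0.02,
                            geometry = c("half", "whole"), seed = 1,
                            cell_id = "cell1", condition = "control") {
  geometry <- match.arg(geometry)
  if (geometry == "whole") {
    if (!missing(amp1) && amp1 != 0)
      stop_param("whole-bleach geometry is single-component: amp1 must be 0")
    amp1 <- 0
    if (missing(amp2) && !missing(plateau)) amp2 <- plateau
    if (missing(plateau)) plateau <- amp1 + amp2
  }
  for (nm in c("tau2", "frame_interval", "duration"))
    if (!is_num1(get(nm)) || get(nm) <= 0) stop_param(nm, " must be > 0")
  if (geometry == "half" && (!is_num1(tau1) || tau1 <= 0))
    stop_param("tau1 must be > 0")
  if (amp1 < 0 || amp2 < 0) stop_param("amplitudes must be >= 0")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (plateau <= 0 || plateau > 1)
    stop_param("plateau must be in (0, 1]")
  if (abs(amp1 + amp2 - plateau) > 1e-8)
    stop_param("invalid amplitude partition: amp1 + amp2 must equal plateau ",
               "(curve starts at 0 immediately post-bleach)")
  if (n_prebleach_frames < 1) stop_param("need at least one pre-bleach frame")
  structure(list(tau1 = tau1, tau2 = tau2, amp1 = amp1, amp2 = amp2,
                 plateau = plateau,
                 n_prebleach_frames = as.integer(n_prebleach_frames),
                 frame_interval = frame_interval, duration = duration,
                 noise_sd = noise_sd, geometry = geometry, seed = seed,
                 cell_id = cell_id, condition = condition),
            class = "frap_sim_params")
}

#' Simulate a normalized FRAP recovery curve
#'
#' Generates `n_prebleach_frames` frames at 1, then a bleach frame at 0 and
#' a recovery following
#' \deqn{F(t) = plateau - amp_1 e^{-t/\tau_1} - amp_2 e^{-t/\tau_2}}
#' with t measured from the bleach frame, plus i.i.d. Gaussian noise on
#' every frame. The trajectory records its true bleach index.
#'
#' @param params a [frap_sim_params()] object.
#' @return a [frap_trajectory()] of length
#'   `n_prebleach_frames + duration/frame_interval + 1`.
#' @export
#' @examples
#' p <- frap_sim_params(geometry = "whole", amp2 = 0.9, tau2 = 20,
#'                      noise_sd = 0, seed = 1)
#' traj <- simulate_frap_curve(p)
#' traj$intensities[traj$bleach_index + 40]  # t = 20 s: 0.9 * (1 - exp(-1))
simulate_frap_curve <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  n_post <- round(p$duration / p$frame_interval)
  t_post <- (0:n_post) * p$frame_interval
  recovery <- p$plateau - p$amp1 * exp(-t_post / p$tau1) -
    p$amp2 * exp(-t_post / p$tau2)
  mean_curve <- c(rep(1, p$n_prebleach_frames), recovery)
  n <- length(mean_curve)
  noise <- if (p$noise_sd > 0)
    with_seed(p$seed, rnorm(n, 0, p$noise_sd)) else rep(0, n)
  frap_trajectory(
    times = (seq_len(n) - 1) * p$frame_interval,
    intensities = mean_curve + noise,
    bleach_index = p$n_prebleach_frames + 1L,
    geometry = p$geometry, cell_id = p$cell_id, condition = p$condition)
}

#' Simulate an ensemble of FRAP curves
#'
#' Convenience wrapper producing `n` curves that differ only in seed (and
#' cell id), e.g. one experimental session's worth of bleached cells.
#'
#' @param params template [frap_sim_params()].
#' @param n number of curves.
#' @param seeds integer vector of length `n`; defaults to
#'   `params$seed + 0:(n-1)`.
#' @return list of [frap_trajectory()] objects.
#' @export
simulate_frap_ensemble <- function(params, n, seeds = params$seed + 0:(n - 1)) {
  stopifnot(length(seeds) == n)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- seeds[i]
    p$cell_id <- sprintf("%s_c%02d", p$condition, i)
    simulate_frap_curve(p)
  })
}
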