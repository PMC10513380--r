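#' Fit a single-exponential recovery to a whole-bleach trajectory
#'
#' Least-squares fit of \eqn{F(t) = plateau\,(1 - e^{-t/\tau})} to the
#' post-bleach segment of a normalized trajectory, t measured from the
#' bleach frame. The single time constant corresponds to exchange of the
#' bleached protein with the surrounding nucleoplasm; `percent_recovery`
#' is 100 times the fitted plateau (pre-bleach intensity is 1 on the
#' normalized scale).
#'
#' Fitting uses bounded Levenberg-Marquardt least squares initialized at
#' `tau = ` time-to-half-recovery`/ln 2` and `plateau = ` mean of the last
#' five frames, with up to 5 restarts from jittered initializations on
#' non-convergence. Bounds are `tau` in `[frame_interval/10, 10 * duration]`
#' and `plateau` in `[0, 1.05]`; a parameter landing on a bound is flagged
#' (`boundary_hit`), never silently clipped. A post-bleach segment that is
#' flat at 0 is returned as a degenerate zero-recovery fit rather than an
#' optimizer failure.
#'
#' @param traj a normalized [frap_trajectory()] with `geometry = "whole"`,
#'   at least 3 pre-bleach and 10 post-bleach frames.
#' @return an object of class `whole_frap_fit`: `tau`, `plateau`,
#'   `percent_recovery`, `rss`, `converged`, `boundary_hit`, `degenerate`.
#' @export
fit_whole_frap <- function(traj) {
  if (traj$geometry != "whole")
    stop_param("fit_whole_frap requires geometry = 'whole'")
  seg <- post_bleach_segment(traj)
  fit_exponential(seg, model = "whole", tau2 = NULL, traj = traj)
}

#' Fit a constrained double-exponential to a half-bleach trajectory
#'
#' Least-squares fit of
#' \deqn{F(t) = plateau - amp_1 e^{-t/\tau_1} - amp_2 e^{-t/\tau_2}}
#' with the slow constant `tau2` held fixed (supplied from a whole-bleach
#' fit, so the nucleoplasmic-exchange component is accounted for and
#' `tau1` isolates internal mixing). `amp1`, `amp2` and `tau1` are free;
#' the constraint `plateau = amp1 + amp2` (curve equals 0 at the bleach
#' frame) is built into the model. The returned `tau2_fixed` echoes the
#' input bit-exactly.
#'
#' @param traj a normalized [frap_trajectory()] with `geometry = "half"`.
#' @param tau2 slow time constant in seconds, held fixed during the fit.
#' @param amp2_fixed optionally hold `amp2` at a fixed value (e.g. 0 to
#'   reduce the model to single-exponential recovery in `tau1`); default
#'   `NULL` leaves it free.
#' @return an object of class `half_frap_fit`: `tau1`, `tau2_fixed`,
#'   `amp1`, `amp2`, `plateau`, `percent_recovery`, `rss`, `converged`,
#'   `boundary_hit`.
#' @export
fit_half_frap <- function(traj, tau2, amp2_fixed = NULL) {
  if (traj$geometry != "half")
    stop_param("fit_half_frap requires geometry = 'half'")
  if (!is_num1(tau2) || tau2 <= 0) stop_param("tau2 must be > 0")
  seg <- post_bleach_segment(traj)
  fit_exponential(seg, model = "half", tau2 = tau2, traj = traj,
                  amp2_fixed = amp2_fixed)
}

# Extract the post-bleach segment with t measured from the bleach frame.
post_bleach_segment <- function(traj) {
  if (!is_normalized(traj))
    stop_param("fit requires a normalized trajectory; see normalize_trajectory()")
  check_fittable(traj)
  idx <- traj$bleach_index:length(traj$times)
  keep <- !is.na(traj$intensities[idx])
  list(t = (traj$times[idx] - traj$times[traj$bleach_index])[keep],
       y = traj$intensities[idx][keep],
       dt = mean(diff(traj$times)))
}

fit_exponential <- function(seg, model, tau2, traj, amp2_fixed = NULL,
                            max_restarts = 5) {
  t <- seg$t; y <- seg$y
  dur <- max(t)
  lower_tau <- seg$dt / 10
  upper_tau <- 10 * dur
  plateau0 <- mean(tail(y, 5))

  base <- list(cell_id = traj$cell_id, condition = traj$condition,
               n_points = length(y))

  # degenerate: no recovery at all
  if (sd(y) < 1e-12 && abs(mean(y)) < 1e-8) {
    out <- c(base, list(tau = NA_real_, plateau = 0, percent_recovery = 0,
                        rss = sum(y^2), converged = TRUE, boundary_hit = FALSE,
                        degenerate = TRUE))
    if (model == "half")
      out <- c(out, list(tau1 = NA_real_, tau2_fixed = tau2,
                         amp1 = 0, amp2 = 0))
    class(out) <- paste0(model, "_frap_fit")
    return(out)
  }

  # initialization: time to half recovery / ln 2
  half_idx <- which(y >= plateau0 / 2)
  t_half <- if (length(half_idx)) max(t[min(half_idx)], seg$dt) else dur / 4
  tau0 <- t_half / log(2)

  fit1 <- NULL
  for (try in 0:max_restarts) {
    jit <- if (try == 0) 1 else exp(runif(1, -1, 1))
    res <- tryCatch({
      if (model == "whole") {
        minpack.lm::nlsLM(
          y ~ p * (1 - exp(-t / tau)),
          start = list(p = min(max(plateau0 * jit, 0.01), 1.05),
                       tau = min(max(tau0 * jit, lower_tau), upper_tau)),
          lower = c(p = 0, tau = lower_tau),
          upper = c(p = 1.05, tau = upper_tau),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else if (is.null(amp2_fixed)) {
        minpack.lm::nlsLM(
          y ~ (a1 + a2) - a1 * exp(-t / tau1) - a2 * exp(-t / .tau2),
          data = list(t = t, y = y, .tau2 = tau2),
          start = list(a1 = min(0.55 * plateau0 * jit, 1),
                       a2 = min(0.45 * plateau0 * jit, 1),
                       tau1 = min(max(tau0 / 2 * jit, lower_tau), upper_tau)),
          lower = c(a1 = 0, a2 = 0, tau1 = lower_tau),
          upper = c(a1 = 1.05, a2 = 1.05, tau1 = upper_tau),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ (a1 + .a2) - a1 * exp(-t / tau1) - .a2 * exp(-t / .tau2),
          data = list(t = t, y = y, .tau2 = tau2, .a2 = amp2_fixed),
          start = list(a1 = min(plateau0 * jit, 1),
                       tau1 = min(max(tau0 * jit, lower_tau), upper_tau)),
          lower = c(a1 = 0, tau1 = lower_tau),
          upper = c(a1 = 1.05, tau1 = upper_tau),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(res)) { fit1 <- res; break }
  }

  if (is.null(fit1)) {
    out <- c(base, list(tau = NA_real_, plateau = NA_real_,
                        percent_recovery = NA_real_, rss = NA_real_,
                        converged = FALSE, boundary_hit = FALSE,
                        degenerate = FALSE,
                        diagnostics = "optimizer failed after restarts"))
    if (model == "half")
      out <- c(out, list(tau1 = NA_real_, tau2_fixed = tau2,
                         amp1 = NA_real_, amp2 = NA_real_))
    class(out) <- paste0(model, "_frap_fit")
    return(out)
  }

  cf <- coef(fit1)
  rss <- sum(residuals(fit1)^2)
  tol <- 1e-6
  if (model == "whole") {
    boundary <- cf["tau"] <= lower_tau * (1 + tol) ||
      cf["tau"] >= upper_tau * (1 - tol)
    out <- c(base, list(
      tau = unname(cf["tau"]), plateau = unname(cf["p"]),
      percent_recovery = 100 * unname(cf["p"]), rss = rss,
      converged = !boundary, boundary_hit = boundary, degenerate = FALSE))
  } else {
    a1 <- unname(cf["a1"])
    a2 <- if (is.null(amp2_fixed)) unname(cf["a2"]) else amp2_fixed
    boundary <- cf["tau1"] <= lower_tau * (1 + tol) ||
      cf["tau1"] >= upper_tau * (1 - tol)
    out <- c(base, list(
      tau1 = unname(cf["tau1"]), tau2_fixed = tau2, amp1 = a1, amp2 = a2,
      plateau = a1 + a2, percent_recovery = 100 * (a1 + a2), rss = rss,
      converged = !boundary, boundary_hit = boundary, degenerate = FALSE))
  }
  class(out) <- paste0(model, "_frap_fit")
  out
}

#' @export
print.whole_frap_fit <- function(x, ...) {
  cat(sprintf("<whole_frap_fit> tau=%.3g s, recovery=%.1f%%, rss=%.3g, converged=%s\n",
              x$tau, x$percent_recovery, x$rss, x$converged))
  invisible(x)
}

#' @export
print.half_frap_fit <- function(x, ...) {
  cat(sprintf("<half_frap_fit> tau1=%.3g s (tau2 fixed %.3g s), recovery=%.1f%%, converged=%s\n",
              x$tau1, x$tau2_fixed, x$percent_recovery, x$converged))
  invisible(x)
}

#' Percent recovery of a converged fit
#'
#' 100 times the fitted plateau, i.e. the fluorescence reached at the end
#' of recovery as a percentage of the pre-bleach intensity (1 on the
#' normalized scale). Errors on unconverged fits. For an empirical
#' (model-free) alternative see [empirical_recovery()].
#'
#' @param fit a `whole_frap_fit` or `half_frap_fit`.
#' @return percentage.
#' @export
percent_recovery <- function(fit) {
  if (!inherits(fit, c("whole_frap_fit", "half_frap_fit")))
    stop_param("not a FRAP fit object")
  if (!isTRUE(fit$converged))
    stop_param("fit did not converge; inspect $rss, $boundary_hit and $diagnostics")
  100 * fit$plateau
}

#' Empirical plateau estimate (diagnostic)
#'
#' Mean of the last `n_last` frames times 100. A model-free cross-check of
#' [percent_recovery()]; the fitted plateau remains the reported quantity.
#'
#' @param traj a normalized [frap_trajectory()].
#' @param n_last number of trailing frames to average.
#' @return percentage.
#' @export
empirical_recovery <- function(traj, n_last = 5) {
  100 * mean(tail(traj$intensities, n_last), na.rm = TRUE)
}

#' Compare a fitted parameter between two groups of fits
#'
#' Two-sided two-sample t test (pooled variance by default, the classical
#' Student's t test; Welch with `var_equal = FALSE`) on one fitted field
#' across two groups of fits.
#'
#' @param a,b lists of fit objects of one type (all `whole_frap_fit` or all
#'   `half_frap_fit`), n >= 2 each.
#' @param field `"tau"`, `"tau1"`, or `"percent_recovery"`.
#' @param var_equal pooled-variance test if `TRUE` (default).
#' @param label comparison label carried into the result.
#' @return an object of class `group_comparison`: per-group mean, sd, n,
#'   plus `t` and `p`.
#' @export
compare_groups <- function(a, b, field = c("tau", "tau1", "percent_recovery"),
                           var_equal = TRUE, label = NULL) {
  field <- match.arg(field)
  for (grp in list(a, b)) {
    cls <- unique(vapply(grp, function(f) class(f)[1], character(1)))
    if (length(cls) != 1)
      stop_param("mixed fit types within one group: ", paste(cls, collapse = ", "))
  }
  if (class(a[[1]])[1] != class(b[[1]])[1])
    stop_param("groups contain different fit types")
  xa <- vapply(a, function(f) as.numeric(f[[field]]), numeric(1))
  xb <- vapply(b, function(f) as.numeric(f[[field]]), numeric(1))
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 2 || length(xb) < 2)
    stop_param("need n >= 2 converged fits per group")
  tt <- t.test(xa, xb, var.equal = var_equal)
  structure(list(field = field, label = label,
                 mean_a = mean(xa), mean_b = mean(xb),
                 sd_a = sd(xa), sd_b = sd(xb),
                 n_a = length(xa), n_b = length(xb),
                 t = unname(tt$statistic), p = unname(tt$p.value),
                 var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d); t=%.3f, p=%.4g\n",
              x$field, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
              x$t, x$p))
  invisible(x)
}

#' Whole-then-half FRAP fitting for one condition
#'
#' Runs the full constrained protocol on one condition's curves: fit every
#' whole-bleach trajectory with the single exponential, average the fitted
#' time constants, then fit every half-bleach trajectory with the double
#' exponential holding `tau2` at that per-condition mean (`tau2_mode =
#' "condition_mean"`). With `tau2_mode = "per_cell"` the half fits are
#' instead paired with whole fits by `cell_id`.
#'
#' Trajectories are min-max normalized first if they are not already.
#'
#' @param whole,half lists of [frap_trajectory()] objects.
#' @param tau2_mode `"condition_mean"` (default) or `"per_cell"`.
#' @return list with `whole_fits`, `half_fits`, `tau2_used`.
#' @export
fit_frap_experiment <- function(whole, half,
                                tau2_mode = c("condition_mean", "per_cell")) {
  tau2_mode <- match.arg(tau2_mode)
  prep <- function(x) if (is_normalized(x)) x else normalize_trajectory(x)
  whole <- lapply(whole, prep)
  half <- lapply(half, prep)
  whole_fits <- lapply(whole, fit_whole_frap)
  taus <- vapply(whole_fits, function(f) f$tau, numeric(1))
  conv <- vapply(whole_fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop_param("no whole-bleach fit converged; cannot fix tau2")
  tau2_mean <- mean(taus[conv])
  half_fits <- lapply(half, function(tr) {
    tau2 <- tau2_mean
    if (tau2_mode == "per_cell") {
      m <- match(tr$cell_id, vapply(whole, function(w) w$cell_id, character(1)))
      if (!is.na(m) && conv[m]) tau2 <- taus[m]
    }
    fit_half_frap(tr, tau2 = tau2)
  })
  list(whole_fits = whole_fits, half_fits = half_fits, tau2_used = tau2_mean)
}
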