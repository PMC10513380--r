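#' FRAP trajectory container
#'
#' A single bleached-ROI intensity time series. Times are seconds on a
#' uniform grid; `bleach_index` is the 1-based index of the first
#' post-bleach frame (the intensity minimum immediately after bleaching).
#'
#' @param times numeric vector of acquisition times in seconds, strictly
#'   increasing on a uniform grid (step tolerance 1%).
#' @param intensities numeric vector of mean ROI intensities (arbitrary
#'   units, or normalized units if `normalized = TRUE`).
#' @param bleach_index integer index of the bleach frame.
#' @param geometry `"half"` (part of the structure bleached, probing
#'   internal mixing) or `"whole"` (entire structure bleached, probing
#'   exchange with the surroundings).
#' @param cell_id,condition labels carried through fitting and comparison.
#' @param normalization `NULL`, or a list with `raw_min`/`raw_max` recorded
#'   by [normalize_trajectory()].
#' @return an object of class `frap_trajectory`.
#' @export
frap_trajectory <- function(times, intensities, bleach_index,
                            geometry = c("half", "whole"),
                            cell_id = "cell1", condition = "control",
                            normalization = NULL) {
  geometry <- match.arg(geometry)
  if (length(times) != length(intensities))
    stop_param("times and intensities must have equal length")
  if (length(times) >= 2) {
    dt <- diff(times)
    if (any(dt <= 0)) stop_param("times must be strictly increasing")
    if (max(dt) - min(dt) > 0.01 * mean(dt))
      stop_param("times must lie on a uniform grid (1% step tolerance)")
  }
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 1 || bleach_index > length(times))
    stop_param("bleach_index out of range")
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         bleach_index = bleach_index, geometry = geometry,
         cell_id = cell_id, condition = condition,
         normalization = normalization),
    class = "frap_trajectory")
}

#' @export
print.frap_trajectory <- function(x, ...) {
  cat(sprintf("<frap_trajectory> %s/%s, geometry=%s, %d frames, bleach at %d%s\n",
              x$cell_id, x$condition, x$geometry, length(x$times),
              x$bleach_index,
              if (is.null(x$normalization)) "" else ", normalized"))
  invisible(x)
}

is_normalized <- function(traj) !is.null(traj$normalization)

# frames available for fitting: requires >= 3 pre-bleach and >= 10 post-bleach
check_fittable <- function(traj) {
  n_pre <- traj$bleach_index - 1
  n_post <- length(traj$times) - traj$bleach_index
  if (n_pre < 3) stop_param("need >= 3 pre-bleach frames, have ", n_pre)
  if (n_post < 10) stop_param("need >= 10 post-bleach frames, have ", n_post)
  invisible(traj)
}

#' Locate the bleach frame of a trajectory
#'
#' Returns the index of the frame following the largest single-frame
#' intensity drop, i.e. the first post-bleach frame. Ties are broken toward
#' the earliest frame; the result is deterministic.
#'
#' @param traj a [frap_trajectory()] with at least 5 frames.
#' @return integer frame index (1-based).
#' @export
detect_bleach_index <- function(traj) {
  v <- traj$intensities
  if (length(v) < 5) stop_param("need at least 5 frames to detect a bleach event")
  d <- diff(v)
  if (all(d >= 0)) stop_param("no bleach event detected")
  which.min(d) + 1L
}

#' Min-max normalize a trajectory
#'
#' Rescales intensities so that the curve minimum is exactly 0 and the
#' maximum exactly 1; the raw extremes are recorded so the map is
#' invertible with [denormalize_trajectory()].
#'
#' @param traj a [frap_trajectory()] with non-zero dynamic range.
#' @return a normalized `frap_trajectory`.
#' @export
normalize_trajectory <- function(traj) {
  v <- traj$intensities
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop_param("constant trajectory: zero dynamic range")
  out <- traj
  out$intensities <- (v - lo) / (hi - lo)
  out$normalization <- list(raw_min = lo, raw_max = hi)
  out
}

#' @rdname normalize_trajectory
#' @export
denormalize_trajectory <- function(traj) {
  if (!is_normalized(traj)) stop_param("trajectory is not normalized")
  out <- traj
  nr <- traj$normalization
  out$intensities <- traj$intensities * (nr$raw_max - nr$raw_min) + nr$raw_min
  out$normalization <- NULL
  out
}

#' Align trajectories on their bleach frames
#'
#' Shifts every trajectory so the bleach occurs at a common frame index
#' (the maximum bleach index across the set). Leading frames are padded
#' with `NA`, never with fabricated values; [mean_recovery()] ignores the
#' padding when averaging per frame.
#'
#' @param trajs a non-empty list of [frap_trajectory()] objects sharing one
#'   frame interval.
#' @return a list of trajectories, all with the same `bleach_index`.
#' @export
align_bleach <- function(trajs) {
  if (length(trajs) == 0) stop_param("empty trajectory list")
  bi <- vapply(trajs, function(x) x$bleach_index, integer(1))
  common <- max(bi)
  dts <- vapply(trajs, function(x) mean(diff(x$times)), numeric(1))
  if (max(dts) - min(dts) > 0.01 * mean(dts))
    stop_param("trajectories must share one frame interval")
  dt <- mean(dts)
  lapply(trajs, function(x) {
    pad <- common - x$bleach_index
    x$intensities <- c(rep(NA_real_, pad), x$intensities)
    n <- length(x$intensities)
    # shared grid with the bleach frame at t = 0
    x$times <- (seq_len(n) - common) * dt
    x$bleach_index <- common
    x
  })
}

#' Plot the mean recovery curve of an aligned trajectory set
#'
#' Base-graphics plot of the per-frame mean intensity against time from
#' the bleach, with individual curves in light gray behind it.
#'
#' @param aligned output of [align_bleach()].
#' @param main plot title.
#' @export
plot_mean_recovery <- function(aligned, main = "FRAP recovery") {
  m <- mean_recovery(aligned)
  graphics::plot(m$time_s, m$mean_intensity, type = "n",
                 xlab = "time from bleach (s)",
                 ylab = "normalized intensity", main = main,
                 ylim = c(0, 1.1))
  for (tr in aligned)
    graphics::lines(tr$times, tr$intensities, col = "gray80")
  graphics::lines(m$time_s, m$mean_intensity, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(m)
}

#' Per-frame mean of aligned trajectories
#'
#' @param aligned output of [align_bleach()].
#' @return data.frame with `time_s`, `mean_intensity`, `n` (trajectories
#'   contributing at each frame).
#' @export
mean_recovery <- function(aligned) {
  n_max <- max(vapply(aligned, function(x) length(x$intensities), integer(1)))
  mat <- vapply(aligned, function(x) {
    v <- x$intensities
    c(v, rep(NA_real_, n_max - length(v)))
  }, numeric(n_max))
  mat <- matrix(mat, nrow = n_max)
  bi <- aligned[[1]]$bleach_index
  dt <- mean(diff(aligned[[1]]$times))
  data.frame(time_s = (seq_len(n_max) - bi) * dt,
             mean_intensity = rowMeans(mat, na.rm = TRUE),
             n = rowSums(!is.na(mat)))
}
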