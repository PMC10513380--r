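# Readers and writers for the pipeline's on-disk formats.
# CSV dialect: UTF-8, comma separator, '.' decimal, mandatory header,
# missing values as empty fields. Physical quantities carry units in the
# column names (time_s, area_um2, density_per_nm2, ...).

write_csv_strict <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write / read FRAP trajectories as CSV
#'
#' Long format, one row per frame: `cell_id`, `roi_id`, `condition`,
#' `geometry`, `bleach_index`, `frame`, `time_s`, `intensity`.
#'
#' @param trajs list of [frap_trajectory()] objects.
#' @param path CSV file path.
#' @return `write_frap_csv` returns `path` invisibly; `read_frap_csv`
#'   returns a list of trajectories.
#' @export
write_frap_csv <- function(trajs, path) {
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(cell_id = tr$cell_id, roi_id = 1L, condition = tr$condition,
               geometry = tr$geometry, bleach_index = tr$bleach_index,
               frame = seq_along(tr$times), time_s = tr$times,
               intensity = tr$intensities)
  }))
  write_csv_strict(rows, path)
  invisible(path)
}

#' @rdname write_frap_csv
#' @param geometry,cell_id,condition metadata applied when reading the
#'   plain two-column (`time_s`, `intensity`) single-curve variant; the
#'   bleach frame is then located with [detect_bleach_index()].
#' @export
read_frap_csv <- function(path, geometry = "half", cell_id = "cell1",
                          condition = "control") {
  df <- read.csv(path)
  if (identical(sort(names(df)), c("intensity", "time_s"))) {
    tr <- frap_trajectory(df$time_s, df$intensity, bleach_index = 1L,
                          geometry = geometry, cell_id = cell_id,
                          condition = condition)
    tr$bleach_index <- detect_bleach_index(tr)
    return(setNames(list(tr), cell_id))
  }
  need <- c("cell_id", "condition", "geometry", "frame", "time_s", "intensity")
  if (!all(need %in% names(df)))
    stop_param("FRAP CSV missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$cell_id), function(s) {
    s <- s[order(s$frame), ]
    bi <- if ("bleach_index" %in% names(s)) s$bleach_index[1] else NA
    tr <- frap_trajectory(s$time_s, s$intensity,
                          bleach_index = if (is.na(bi)) 1L else bi,
                          geometry = s$geometry[1],
                          cell_id = as.character(s$cell_id[1]),
                          condition = as.character(s$condition[1]))
    if (is.na(bi)) tr$bleach_index <- detect_bleach_index(tr)
    tr
  })
}

#' Write / read a detected particle set as CSV
#'
#' Columns `x_px`, `y_px` (0-based pixel centers), `size_class`,
#' `response`, `in_roi`.
#'
#' @param particles a `particle_set` from [detect_two_pass()] (or the
#'   truth table of [simulate_em_image()], whose `response` is absent).
#' @param path CSV file path.
#' @export
write_particles_csv <- function(particles, path) {
  write_csv_strict(as.data.frame(particles), path)
  invisible(path)
}

#' @rdname write_particles_csv
#' @export
read_particles_csv <- function(path) {
  df <- read.csv(path)
  if ("in_roi" %in% names(df)) df$in_roi <- as.logical(df$in_roi)
  df
}

#' Write a grayscale image (or stack) as TIFF
#'
#' Images are written as 32-bit float TIFF; multi-frame input (a list of
#' matrices, or a 3-D/4-D array which is unrolled with channel fastest,
#' then time: page = (frame-1)*n_channels + channel) becomes a multi-page
#' file. Physical metadata (pixel size, frame interval, channel names)
#' goes into a YAML sidecar written next to the TIFF.
#'
#' @param x matrix, list of matrices, or array.
#' @param path output path ending in `.tif`.
#' @param metadata named list written to `<path>.yaml` (omitted if empty).
#' @export
write_image_tiff <- function(x, path, metadata = list()) {
  pages <- if (is.matrix(x)) list(x)
  else if (is.list(x)) x
  else if (length(dim(x)) == 3) lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  else if (length(dim(x)) == 4) {
    d <- dim(x)
    unlist(lapply(seq_len(d[4]), function(f)
      lapply(seq_len(d[3]), function(c) x[, , c, f])), recursive = FALSE)
  } else stop_param("unsupported image dimensionality")
  # tiff expects [row, col] with values in [0,1] for float output
  pages <- lapply(pages, function(m) t(pmin(pmax(m, 0), 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  if (length(metadata))
    yaml::write_yaml(metadata, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @param n_channels reshape pages into channels x frames on read (NULL
#'   returns a list of matrices, or a single matrix for one page).
#' @export
read_image_tiff <- function(path, n_channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) t(m))
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(n_channels)) {
    out <- if (length(pages) == 1) pages[[1]] else pages
  } else {
    nf <- length(pages) / n_channels
    d <- dim(pages[[1]])
    out <- array(0, c(d[1], d[2], n_channels, nf))
    for (f in seq_len(nf)) for (c in seq_len(n_channels))
      out[, , c, f] <- pages[[(f - 1) * n_channels + c]]
  }
  attr(out, "metadata") <- meta
  out
}

#' Write FRAP fit results as CSV
#'
#' One row per curve: label columns, then `tau_s` or `tau1_s`/
#' `tau2_fixed_s`, `percent_recovery`, `rss`, `converged`.
#'
#' @param fits list of `whole_frap_fit` or `half_frap_fit` objects.
#' @param path CSV file path.
#' @export
write_fits_csv <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    if (inherits(f, "whole_frap_fit"))
      data.frame(cell_id = f$cell_id, condition = f$condition,
                 geometry = "whole", tau_s = f$tau, tau1_s = NA_real_,
                 tau2_fixed_s = NA_real_,
                 percent_recovery = f$percent_recovery, rss = f$rss,
                 converged = f$converged)
    else
      data.frame(cell_id = f$cell_id, condition = f$condition,
                 geometry = "half", tau_s = NA_real_, tau1_s = f$tau1,
                 tau2_fixed_s = f$tau2_fixed,
                 percent_recovery = f$percent_recovery, rss = f$rss,
                 converged = f$converged)
  }))
  write_csv_strict(rows, path)
  invisible(path)
}
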