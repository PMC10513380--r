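# internal helpers shared across modules

# Run expr with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a per-stage seed from a single run seed
#'
#' One configured seed reproduces an entire multi-stage run: each stage draws
#' its own sub-seed from the run seed and the stage name, so stages can be
#' re-run independently without sharing RNG streams. The derivation hashes
#' the stage name onto the integer line and folds in the run seed; results
#' stay below 2^31.
#'
#' @param seed integer run seed.
#' @param stage character stage name (e.g. `"simulate_frap"`).
#' @return a single integer usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "simulate_frap")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 2147483647L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# check a numeric scalar
is_num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_param <- function(...) stop(..., call. = FALSE)

# Otsu threshold on a numeric vector (histogram-based, 256 bins).
# Thin wrapper over EBImage's implementation; values are rescaled into [0, 1]
# because EBImage::otsu thresholds within a fixed range.
otsu_threshold <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  x <- (v - lo) / (hi - lo)
  thr <- EBImage::otsu(EBImage::Image(matrix(x, ncol = 1)), range = c(0, 1))
  thr * (hi - lo) + lo
}
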