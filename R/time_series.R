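#' Single-voxel / VOI time series
#'
#' The universal currency of the package: an ordered vector of finite real
#' samples acquired at a fixed repetition time (TR). One sample corresponds
#' to one fMRI volume.
#'
#' @param values numeric vector of samples; must be finite, length >= 1.
#' @param tr_seconds repetition time in seconds (> 0).
#' @return an object of class `time_series` with fields `values` and
#'   `tr_seconds`.
#' @export
#' @examples
#' x <- time_series(sin(seq_len(100) / 5), tr_seconds = 2)
#' length(ts_values(x))
time_series <- function(values, tr_seconds = 2) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("time_series: 'values' must contain at least one sample", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("time_series: 'values' must be finite", call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("time_series: 'tr_seconds' must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, tr_seconds = as.numeric(tr_seconds)),
            class = "time_series")
}

#' Extract the sample vector of a time series
#'
#' @param x a `time_series` or a plain numeric vector.
#' @return numeric vector of samples.
#' @export
ts_values <- function(x) {
  if (inherits(x, "time_series")) x$values else as.numeric(x)
}

#' Coerce to a time series
#'
#' @param x a `time_series` (returned unchanged) or numeric vector.
#' @param tr_seconds TR used when `x` is a plain vector.
#' @return a `time_series`.
#' @export
as_time_series <- function(x, tr_seconds = 2) {
  if (inherits(x, "time_series")) x else time_series(x, tr_seconds)
}

#' @export
length.time_series <- function(x) length(x$values)

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series: %d samples, TR = %g s>\n",
              length(x$values), x$tr_seconds))
  print(utils::head(x$values, 10L))
  if (length(x$values) > 10L) cat("...\n")
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic generators in the package route their
# randomness through this helper so that a (inputs, seed) pair is a pure
# function.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream seed derivation. Maps (master seed, stream index)
# to a seed in [0, 2^31): a linear congruence modulo a prime, injective in
# the index for index < 2147483629.
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483629
  v <- (m * 48271 + as.double(index) * 69621 + 1) %% 2147483629
  as.integer(v)
}
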