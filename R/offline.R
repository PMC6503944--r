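# Retrospective reference detrenders.

#' Straight-line (piecewise) least-squares detrending
#'
#' Within each piece — delimited by `breakpoints`, each of which starts a new
#' piece — the least-squares straight line is subtracted. Pieces are fitted
#' independently and are not constrained to join.
#'
#' @param series a `time_series` or numeric vector.
#' @param breakpoints strictly increasing sample indices in (1, N]; empty for
#'   a single global fit.
#' @return detrended series, same type as the input.
#' @export
#' @examples
#' line_detrend(3 + 0.2 * (1:50))  # ~ all zeros
line_detrend <- function(series, breakpoints = integer(0)) {
  x <- ts_values(series)
  n <- length(x)
  bp <- as.integer(breakpoints)
  if (length(bp)) {
    if (any(is.na(bp)) || is.unsorted(bp, strictly = TRUE) ||
        any(bp <= 1L) || any(bp > n)) {
      stop("line_detrend: breakpoints must be strictly increasing and within (1, N]",
           call. = FALSE)
    }
  }
  starts <- c(1L, bp)
  ends <- c(bp - 1L, n)
  out <- numeric(n)
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 2L) {
      stop(sprintf("line_detrend: piece %d has fewer than 2 samples", k),
           call. = FALSE)
    }
    tt <- seq_along(idx)
    fit <- stats::.lm.fit(cbind(1, tt), x[idx])
    out[idx] <- fit$residuals
  }
  .rewrap(series, out)
}

#' Discrete-cosine-basis high-pass detrending
#'
#' Regresses the series on a constant plus the leading `order` discrete
#' cosine basis functions (see [cosine_basis()]) and returns the residual,
#' i.e. the series minus its fitted low-frequency components. The cutoff
#' period corresponding to `order` k is `2 N TR / k` seconds, so either the
#' order or a desired cutoff period can be used to choose k.
#'
#' @param series a `time_series` or numeric vector.
#' @param order number of cosine regressors, `1 <= order < N`.
#' @return detrended series, same type as the input.
#' @export
cosine_detrend <- function(series, order = 7L) {
  x <- ts_values(series)
  n <- length(x)
  order <- as.integer(order)
  if (is.na(order) || order < 1L || order >= n) {
    stop("cosine_detrend: 'order' must satisfy 1 <= order < N", call. = FALSE)
  }
  X <- cbind(1, cosine_basis(n, order))
  fit <- stats::.lm.fit(X, x)
  .rewrap(series, fit$residuals)
}
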