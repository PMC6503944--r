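#' Add Gaussian noise at an exact empirical SNR
#'
#' Zero-mean Gaussian noise is drawn under `seed` and rescaled so that the
#' empirical variance ratio satisfies
#' `10 * log10(var(signal) / var(noise)) = snr_db` exactly.
#'
#' @param signal a `time_series` or numeric vector with non-zero variance.
#' @param snr_db target signal-to-noise ratio in decibels.
#' @param seed RNG seed; the same seed yields an identical series.
#' @return degraded series, same type as `signal`.
#' @export
add_gaussian <- function(signal, snr_db, seed = NULL) {
  x <- ts_values(signal)
  if (!is.finite(snr_db)) stop("add_gaussian: 'snr_db' must be finite", call. = FALSE)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) {
    stop("add_gaussian: signal has zero variance; SNR undefined", call. = FALSE)
  }
  z <- with_seed(seed, stats::rnorm(length(x)))
  target <- vx / 10^(snr_db / 10)
  z <- z * sqrt(target / stats::var(z))
  .rewrap(signal, x + z)
}

#' Add a linear drift
#'
#' `output_i = signal_i + slope * (i - 1)`, slope in signal units per sample.
#'
#' @param signal input series.
#' @param slope drift slope per sample.
#' @return degraded series.
#' @export
add_linear_drift <- function(signal, slope) {
  x <- ts_values(signal)
  if (!is.finite(slope)) stop("add_linear_drift: 'slope' must be finite", call. = FALSE)
  .rewrap(signal, x + slope * (seq_along(x) - 1))
}

#' Seeded non-linear (low-frequency) drift trace
#'
#' A surrogate for slow scanner drift: the sum of K = 4 sinusoids with
#' random phases and amplitudes whose periods all lie at or above 128 s (the
#' conventional fMRI high-pass cutoff period), rescaled to an exact standard
#' deviation of `level`. Periods are drawn from the record's harmonic grid
#' (`duration / m` for random integers m with `duration / m >= 128 s`), so
#' each component completes an integer number of cycles and the trace's
#' periodogram power stays entirely at periods >= 128 s; for records shorter
#' than two cutoff periods the periods are drawn from
#' `[128 s, 256 s]` instead (sub-cycle trends).
#'
#' @param n_samples trace length (>= 8).
#' @param tr_seconds sampling interval in seconds.
#' @param level target standard deviation in signal units; 0 yields zeros.
#' @param seed RNG seed.
#' @param min_period_s shortest admissible sinusoid period (seconds).
#' @return a `time_series` of the additive drift trace.
#' @export
make_nonlinear_drift <- function(n_samples, tr_seconds = 2, level = 0.5,
                                 seed = NULL, min_period_s = 128) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 8L) {
    stop("make_nonlinear_drift: 'n_samples' must be >= 8", call. = FALSE)
  }
  if (level == 0) return(time_series(rep(0, n_samples), tr_seconds))
  duration <- n_samples * tr_seconds
  k <- 4L
  tr <- tr_seconds
  trace <- with_seed(seed, {
    m_max <- floor(duration / min_period_s)
    periods <- if (m_max >= 1L) {
      duration / sample(seq_len(m_max), k, replace = m_max < k)
    } else {
      stats::runif(k, min_period_s, 2 * min_period_s)
    }
    phases <- stats::runif(k, 0, 2 * pi)
    amps <- stats::runif(k, 0.5, 1.5)
    t <- (seq_len(n_samples) - 1) * tr
    rowSums(vapply(seq_len(k),
                   function(j) amps[j] * sin(2 * pi * t / periods[j] + phases[j]),
                   numeric(n_samples)))
  })
  s <- stats::sd(trace)
  if (s == 0) trace <- trace else trace <- trace * (level / s)
  time_series(trace, tr_seconds)
}

#' Seeded autocorrelated ("colored") noise trace
#'
#' A stationary AR(1) surrogate for the temporally autocorrelated noise of
#' resting-state VOI time courses: `e_i = phi * e_{i-1} + w_i` with white
#' Gaussian innovations and a stationary initial state, rescaled to an exact
#' standard deviation of `sd`.
#'
#' @param n_samples trace length.
#' @param ar_coefficient AR(1) coefficient `phi`, `|phi| < 1`.
#' @param sd target standard deviation in signal units.
#' @param seed RNG seed.
#' @param tr_seconds sampling interval (carried on the returned series).
#' @return a `time_series` of the additive noise trace.
#' @export
make_colored_noise <- function(n_samples, ar_coefficient = 0.6, sd = 0.5,
                               seed = NULL, tr_seconds = 2) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) {
    stop("make_colored_noise: 'n_samples' must be >= 2", call. = FALSE)
  }
  phi <- ar_coefficient
  if (!is.finite(phi) || abs(phi) >= 1) {
    stop("make_colored_noise: need |ar_coefficient| < 1", call. = FALSE)
  }
  trace <- with_seed(seed, {
    w <- stats::rnorm(n_samples)
    e0 <- stats::rnorm(1) / sqrt(1 - phi^2)
    as.numeric(stats::filter(w, phi, method = "recursive", init = e0))
  })
  s <- stats::sd(trace)
  if (s > 0 && sd > 0) trace <- trace * (sd / s) else trace <- trace * 0
  time_series(trace, tr_seconds)
}

#' Add spike artifacts
#'
#' Adds `count` single-sample deltas at distinct, uniformly drawn positions;
#' each magnitude is drawn uniformly from `magnitude_range` with a random
#' sign.
#'
#' @param signal input series.
#' @param count number of spikes (default 3).
#' @param magnitude_range range the absolute spike height is drawn from,
#'   in clean-signal peak units.
#' @param seed RNG seed.
#' @return degraded series.
#' @export
add_spikes <- function(signal, count = 3, magnitude_range = c(2, 10),
                       seed = NULL) {
  x <- ts_values(signal)
  count <- as.integer(count)
  if (is.na(count) || count < 0L) stop("add_spikes: 'count' must be >= 0", call. = FALSE)
  if (count > length(x)) {
    stop("add_spikes: 'count' exceeds the series length", call. = FALSE)
  }
  if (count == 0L) return(.rewrap(signal, x))
  out <- with_seed(seed, {
    pos <- sample.int(length(x), count)
    mag <- stats::runif(count, magnitude_range[1], magnitude_range[2]) *
      sample(c(-1, 1), count, replace = TRUE)
    x[pos] <- x[pos] + mag
    x
  })
  .rewrap(signal, out)
}

#' Add a stepped baseline shift
#'
#' `output_i = signal_i + magnitude` for `i >= t0`. When `t0` is not given
#' it is drawn uniformly from the middle 80% of the series under `seed`, so
#' both pre- and post-step data exist.
#'
#' @param signal input series.
#' @param magnitude step height in clean-signal peak units (default 5).
#' @param seed RNG seed used when `t0` is drawn.
#' @param t0 optional explicit step onset sample, `2 <= t0 <= N`.
#' @return degraded series.
#' @export
add_step <- function(signal, magnitude = 5, seed = NULL, t0 = NULL) {
  x <- ts_values(signal)
  n <- length(x)
  if (!is.finite(magnitude)) stop("add_step: 'magnitude' must be finite", call. = FALSE)
  if (is.null(t0)) {
    lo <- max(2L, as.integer(ceiling(0.1 * n)))
    hi <- min(n, as.integer(floor(0.9 * n)))
    if (hi < lo) stop("add_step: series too short to place a step", call. = FALSE)
    t0 <- with_seed(seed, sample(lo:hi, 1L))
  }
  t0 <- as.integer(t0)
  if (is.na(t0) || t0 <= 1L || t0 > n) {
    stop("add_step: 't0' must lie within (1, N]", call. = FALSE)
  }
  .rewrap(signal, x + magnitude * (seq_len(n) >= t0))
}

#' Artifact condition descriptor
#'
#' A tagged description of one artifact condition applied to a clean signal.
#'
#' @param kind one of `"gaussian"`, `"linear_drift"`, `"nonlinear_drift"`,
#'   `"colored"`, `"spikes"`, `"step"`.
#' @param level kind-specific magnitude: SNR in dB (gaussian), slope per
#'   sample (linear_drift), standard deviation in signal units (colored,
#'   nonlinear_drift), step magnitude (step); ignored for spikes.
#' @param count spike count (spikes only).
#' @param seed RNG seed (ignored by deterministic kinds).
#' @param magnitude_range spike magnitude range (spikes only).
#' @param ar_coefficient AR(1) coefficient (colored only).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(kind, level = NA_real_, count = 3, seed = NULL,
                       magnitude_range = c(2, 10), ar_coefficient = 0.6) {
  kinds <- c("gaussian", "linear_drift", "nonlinear_drift", "colored",
             "spikes", "step")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop("noise_spec: unknown artifact kind", call. = FALSE)
  }
  lv <- as.numeric(level)
  switch(kind,
    gaussian = if (!is.finite(lv)) stop("noise_spec: gaussian needs a finite snr_db level", call. = FALSE),
    linear_drift = if (!is.finite(lv) || lv < 0) stop("noise_spec: linear slope must be >= 0", call. = FALSE),
    nonlinear_drift = ,
    colored = if (!is.finite(lv) || lv < 0) stop("noise_spec: level (sd) must be >= 0", call. = FALSE),
    spikes = if (as.integer(count) < 0L) stop("noise_spec: spike count must be >= 0", call. = FALSE),
    step = if (!is.finite(lv)) stop("noise_spec: step magnitude must be finite", call. = FALSE)
  )
  structure(list(kind = kind, level = lv, count = as.integer(count),
                 seed = seed, magnitude_range = magnitude_range,
                 ar_coefficient = ar_coefficient),
            class = "noise_spec")
}

#' Apply one artifact condition to a clean signal
#'
#' @param signal input series.
#' @param spec a `noise_spec`.
#' @return degraded series.
#' @export
apply_noise <- function(signal, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  x <- as_time_series(signal)
  n <- length(x$values)
  switch(spec$kind,
    gaussian = add_gaussian(signal, spec$level, spec$seed),
    linear_drift = add_linear_drift(signal, spec$level),
    nonlinear_drift = .rewrap(signal, ts_values(signal) +
      ts_values(make_nonlinear_drift(n, x$tr_seconds, spec$level, spec$seed))),
    colored = .rewrap(signal, ts_values(signal) +
      ts_values(make_colored_noise(n, spec$ar_coefficient, spec$level,
                                   spec$seed, x$tr_seconds))),
    spikes = add_spikes(signal, spec$count, spec$magnitude_range, spec$seed),
    step = add_step(signal, spec$level, spec$seed)
  )
}

# Canonical composition order for fully-confounded series.
.noise_order <- c("gaussian", "colored", "spikes", "linear_drift",
                  "nonlinear_drift", "step")

#' Compose several artifact conditions onto one signal
#'
#' Conditions are applied sequentially in the canonical order gaussian ->
#' colored -> spikes -> linear drift -> non-linear drift -> step, regardless
#' of the order they are supplied in. All artifact models are additive, so
#' the composed series equals the clean signal plus the sum of the
#' individual additive traces.
#'
#' @param signal clean input series.
#' @param specs list of `noise_spec` objects (at most one per kind).
#' @return degraded series.
#' @export
compose_noise <- function(signal, specs) {
  stopifnot(is.list(specs), all(vapply(specs, inherits, TRUE, "noise_spec")))
  kinds <- vapply(specs, `[[`, "", "kind")
  if (anyDuplicated(kinds)) {
    stop("compose_noise: at most one condition per artifact kind", call. = FALSE)
  }
  out <- signal
  for (k in .noise_order) {
    i <- match(k, kinds)
    if (!is.na(i)) out <- apply_noise(out, specs[[i]])
  }
  out
}

# Return `values` wrapped like `like` (time_series in -> time_series out).
.rewrap <- function(like, values) {
  if (inherits(like, "time_series")) time_series(values, like$tr_seconds)
  else values
}
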