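# Streaming (causal, sample-by-sample) detrenders. Each estimator exposes
# a constructor (`*_state`), a one-sample update returning the new state and
# a `detrend_output`, and shares its arithmetic with the batch runners in
# detrend.R.

#' One-sample output of an online detrender
#'
#' @param detrended_value detrended sample in signal units.
#' @param warmup_flag TRUE while the estimate is not yet well-posed.
#' @param beta_hat current coefficient vector (GLM variants only).
#' @return an object of class `detrend_output`.
#' @export
detrend_output <- function(detrended_value, warmup_flag = FALSE,
                           beta_hat = NULL) {
  structure(list(detrended_value = detrended_value,
                 warmup_flag = isTRUE(warmup_flag), beta_hat = beta_hat),
            class = "detrend_output")
}

#' Exponential moving average state
#'
#' The EMA detrender subtracts a recursive exponential average from the
#' incoming sample: `m_1 = x_1`, `m_t = alpha * m_{t-1} + (1 - alpha) * x_t`,
#' `d_t = x_t - m_t`. The smoothing parameter `alpha` in (0, 1] sets the
#' filter steepness: values near 1 converge slowly to trends but barely
#' distort the task signal; smaller values converge fast at the price of
#' distortion.
#'
#' @param alpha smoothing parameter, `0 < alpha <= 1`.
#' @return an object of class `ema_state`.
#' @export
ema_state <- function(alpha = 0.995) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("ema_state: 'alpha' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, running_mean = NA_real_, n_seen = 0L),
            class = "ema_state")
}

#' Advance the EMA detrender by one sample
#'
#' @param state an `ema_state`.
#' @param x next sample (finite).
#' @return `list(state = <new state>, output = <detrend_output>)`.
#' @export
#' @examples
#' st <- ema_state(0.98)
#' for (x in c(1, 2, 3)) { up <- ema_update(st, x); st <- up$state }
ema_update <- function(state, x) {
  stopifnot(inherits(state, "ema_state"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("ema_update: 'x' must be a finite sample", call. = FALSE)
  }
  if (state$n_seen == 0L) {
    state$running_mean <- x
  } else {
    state$running_mean <- state$alpha * state$running_mean +
      (1 - state$alpha) * x
  }
  state$n_seen <- state$n_seen + 1L
  list(state = state,
       output = detrend_output(x - state$running_mean, warmup_flag = FALSE))
}

#' Incremental GLM state
#'
#' Maintains the accumulated normal equations `X'X` and `X'y` of an ordinary
#' least-squares fit, updated one sample at a time, so that the coefficient
#' estimate at sample t equals the batch OLS fit on samples 1..t. The
#' detrended output is the incoming sample minus the fitted nuisance
#' contribution (constant + linear drift + cosine terms), i.e. the task
#' component plus residual.
#'
#' During warm-up (`n_seen < warmup_min`) no fit is attempted and the output
#' is the sample minus the running mean, flagged via `warmup_flag`. From
#' `warmup_min` on, the normal matrix is screened for conditioning before
#' each solve; when the screen fails a tiny ridge (`1e-10 * trace / p`) is
#' added and counted in `ridge_count`.
#'
#' @param design a `design_matrix` (see [build_design_matrix()]).
#' @param warmup_min first sample index at which estimates are produced;
#'   default `p + 5`.
#' @param cond_tol conditioning screen threshold (default 1e8).
#' @return an object of class `iglm_state`.
#' @export
iglm_state <- function(design, warmup_min = NULL, cond_tol = 1e8) {
  stopifnot(inherits(design, "design_matrix"))
  p <- design$p
  if (is.null(warmup_min)) warmup_min <- p + 5L
  structure(list(design = design, p = p,
                 xtx = matrix(0, p, p), xty = numeric(p),
                 n_seen = 0L, sum_x = 0,
                 warmup_min = as.integer(warmup_min),
                 cond_tol = cond_tol, ridge_count = 0L),
            class = "iglm_state")
}

#' Advance the incremental GLM by one sample
#'
#' @param state an `iglm_state`.
#' @param x next sample.
#' @return `list(state = <new state>, output = <detrend_output>)`.
#' @export
iglm_update <- function(state, x) {
  stopifnot(inherits(state, "iglm_state"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("iglm_update: 'x' must be a finite sample", call. = FALSE)
  }
  t <- state$n_seen + 1L
  if (t > state$design$n_samples) {
    stop("iglm_update: more samples than the design matrix supports",
         call. = FALSE)
  }
  row <- state$design$X[t, ]
  state$xtx <- state$xtx + tcrossprod(row)
  state$xty <- state$xty + row * x
  state$sum_x <- state$sum_x + x
  state$n_seen <- t
  if (t < state$warmup_min) {
    out <- detrend_output(x - state$sum_x / t, warmup_flag = TRUE)
  } else {
    sol <- .solve_normal(state$xtx, state$xty, state$cond_tol)
    state$ridge_count <- state$ridge_count + sol$ridged
    d <- x - sum(row[state$design$nuisance_idx] *
                   sol$beta[state$design$nuisance_idx])
    out <- detrend_output(d, warmup_flag = FALSE, beta_hat = sol$beta)
  }
  list(state = state, output = out)
}

#' Sliding-window incremental GLM state
#'
#' As [iglm_state()], but the fit is restricted to the most recent `window`
#' samples: each update adds the newest (design row, sample) pair and, once
#' the buffer exceeds the window, downdates the accumulators by the evicted
#' pair. To guard against numerical drift of the downdating, the
#' accumulators are recomputed exactly from the buffered rows every 64
#' updates. Design-matrix rows are taken at the global time indices (not
#' re-centred per window), so `window = n_samples` reproduces the full iGLM
#' exactly.
#'
#' @param design a `design_matrix`.
#' @param window window length n in samples; must be >= p.
#' @param warmup_min first sample with estimates; default
#'   `max(p, min(window, p + 5))`.
#' @param cond_tol conditioning screen threshold.
#' @param anchor_every exact-recomputation interval (updates).
#' @return an object of class `iglm_window_state`.
#' @export
iglm_window_state <- function(design, window = 50L, warmup_min = NULL,
                              cond_tol = 1e8, anchor_every = 64L) {
  stopifnot(inherits(design, "design_matrix"))
  p <- design$p
  window <- as.integer(window)
  if (is.na(window) || window < p) {
    stop(sprintf("iglm_window_state: window (%d) must be >= p (%d)",
                 window, p), call. = FALSE)
  }
  if (is.null(warmup_min)) warmup_min <- max(p, min(window, p + 5L))
  structure(list(design = design, p = p, window = window,
                 xtx = matrix(0, p, p), xty = numeric(p),
                 xs = numeric(0), n_seen = 0L,
                 warmup_min = as.integer(warmup_min),
                 cond_tol = cond_tol, anchor_every = as.integer(anchor_every),
                 ridge_count = 0L),
            class = "iglm_window_state")
}

#' Advance the sliding-window iGLM by one sample
#'
#' @param state an `iglm_window_state`.
#' @param x next sample.
#' @return `list(state = <new state>, output = <detrend_output>)`.
#' @export
iglm_window_update <- function(state, x) {
  stopifnot(inherits(state, "iglm_window_state"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("iglm_window_update: 'x' must be a finite sample", call. = FALSE)
  }
  t <- state$n_seen + 1L
  if (t > state$design$n_samples) {
    stop("iglm_window_update: more samples than the design matrix supports",
         call. = FALSE)
  }
  X <- state$design$X
  row <- X[t, ]
  state$xs <- c(state$xs, x)
  state$xtx <- state$xtx + tcrossprod(row)
  state$xty <- state$xty + row * x
  if (t > state$window) {
    j <- t - state$window
    rj <- X[j, ]
    state$xtx <- state$xtx - tcrossprod(rj)
    state$xty <- state$xty - rj * state$xs[j]
  }
  # re-anchor against downdating round-off; only meaningful once evictions
  # have begun (before that the accumulators are exact sums)
  if (t > state$window && t %% state$anchor_every == 0L) {
    lo <- t - state$window + 1L
    Xb <- X[lo:t, , drop = FALSE]
    state$xtx <- crossprod(Xb)
    state$xty <- as.numeric(crossprod(Xb, state$xs[lo:t]))
  }
  state$n_seen <- t
  if (t < state$warmup_min) {
    lo <- max(1L, t - state$window + 1L)
    out <- detrend_output(x - mean(state$xs[lo:t]), warmup_flag = TRUE)
  } else {
    sol <- .solve_normal(state$xtx, state$xty, state$cond_tol)
    state$ridge_count <- state$ridge_count + sol$ridged
    d <- x - sum(row[state$design$nuisance_idx] *
                   sol$beta[state$design$nuisance_idx])
    out <- detrend_output(d, warmup_flag = FALSE, beta_hat = sol$beta)
  }
  list(state = state, output = out)
}

# Solve the accumulated normal equations via Cholesky, with a conditioning
# screen on the Cholesky diagonal ((max d / min d)^2 ~ kappa_2) and a tiny
# ridge fallback when the screen fails or the factorization breaks down.
.solve_normal <- function(xtx, xty, cond_tol) {
  p <- ncol(xtx)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(ch)) {
    d <- diag(ch)
    ok <- (max(d) / min(d))^2 < cond_tol
  }
  ridged <- 0L
  if (!ok) {
    ridged <- 1L
    lam <- 1e-10 * sum(diag(xtx)) / p
    ch <- chol(xtx + diag(lam, p))
  }
  beta <- backsolve(ch, backsolve(ch, xty, transpose = TRUE))
  list(beta = as.numeric(beta), ridged = ridged)
}
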