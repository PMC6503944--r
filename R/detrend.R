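# Batch runners: map a whole time series through the streaming detrenders.
# The loops repeat the streaming updates' arithmetic operation-for-operation
# (without per-sample state copies) so batch and streaming outputs agree to
# machine precision; tests pin that equivalence.

#' Detrend a whole time series
#'
#' Convenience batch interface over the streaming detrenders and the offline
#' references. Online methods (`ema`, `iglm`, `iglm_window`) process the
#' series strictly causally, exactly as the corresponding `*_update`
#' functions would sample-by-sample; offline methods (`line`, `cosine`) fit
#' retrospectively.
#'
#' @param series a `time_series` or numeric vector.
#' @param method one of `"ema"`, `"iglm"`, `"iglm_window"`, `"line"`,
#'   `"cosine"`.
#' @param design a `block_design` or `design_matrix`; required by the iGLM
#'   variants.
#' @param alpha EMA smoothing parameter.
#' @param window sliding-window length in samples (iglm_window).
#' @param order number of cosine regressors (cosine).
#' @param breakpoints piece starts for piecewise line removal (line).
#' @param task_mode task regressor mode when `design` is a `block_design`.
#' @param warmup_min,cond_tol see [iglm_state()].
#' @return an object of class `detrend_result`: `detrended` (`time_series`),
#'   `warmup` (logical per sample), `beta_hat` (final GLM coefficients or
#'   NULL), `ridge_count`, `method`, `params`.
#' @export
#' @examples
#' d <- block_design(10, 10, 15)
#' y <- add_linear_drift(make_clean_signal(d), 0.1)
#' r <- detrend(y, "iglm", design = d)
#' pearson_corr(r$detrended, make_clean_signal(d), skip = 14)
detrend <- function(series, method = c("ema", "iglm", "iglm_window", "line",
                                       "cosine"),
                    design = NULL, alpha = 0.995, window = 50L, order = 7L,
                    breakpoints = integer(0),
                    task_mode = c("convolved", "boxcar"),
                    warmup_min = NULL, cond_tol = 1e8) {
  method <- match.arg(method)
  task_mode <- match.arg(task_mode)
  x <- ts_values(series)
  tr <- if (inherits(series, "time_series")) series$tr_seconds else 2
  res <- switch(method,
    ema = {
      r <- .ema_run(x, alpha)
      list(d = r, warm = rep(FALSE, length(x)), beta = NULL, ridge = 0L,
           params = list(alpha = alpha))
    },
    iglm = {
      dm <- .as_design_matrix(design, length(x), task_mode)
      r <- .iglm_run(x, dm, window = NULL, warmup_min = warmup_min,
                     cond_tol = cond_tol)
      list(d = r$detrended, warm = r$warmup, beta = r$beta_hat,
           ridge = r$ridge_count, params = list(task_mode = task_mode))
    },
    iglm_window = {
      dm <- .as_design_matrix(design, length(x), task_mode)
      r <- .iglm_run(x, dm, window = as.integer(window),
                     warmup_min = warmup_min, cond_tol = cond_tol)
      list(d = r$detrended, warm = r$warmup, beta = r$beta_hat,
           ridge = r$ridge_count,
           params = list(window = as.integer(window), task_mode = task_mode))
    },
    line = {
      r <- line_detrend(x, breakpoints)
      list(d = r, warm = rep(FALSE, length(x)), beta = NULL, ridge = 0L,
           params = list(breakpoints = breakpoints))
    },
    cosine = {
      r <- cosine_detrend(x, order)
      list(d = r, warm = rep(FALSE, length(x)), beta = NULL, ridge = 0L,
           params = list(order = as.integer(order)))
    }
  )
  structure(list(detrended = time_series(res$d, tr), warmup = res$warm,
                 beta_hat = res$beta, ridge_count = res$ridge,
                 method = method, params = res$params),
            class = "detrend_result")
}

#' @export
print.detrend_result <- function(x, ...) {
  cat(sprintf("<detrend_result: %s, %d samples, %d warm-up, %d ridge solve(s)>\n",
              x$method, length(x$detrended$values), sum(x$warmup),
              x$ridge_count))
  invisible(x)
}

.as_design_matrix <- function(design, n, task_mode) {
  if (is.null(design)) {
    stop("detrend: iGLM methods require a 'design'", call. = FALSE)
  }
  dm <- if (inherits(design, "design_matrix")) design
        else build_design_matrix(design, task_mode = task_mode)
  if (dm$n_samples < n) {
    stop(sprintf("detrend: series (%d samples) longer than the design (%d)",
                 n, dm$n_samples), call. = FALSE)
  }
  dm
}

# EMA recursion over a full series. stats::filter(method = "recursive")
# computes m_t = (1 - alpha) x_t + alpha m_{t-1} with m_1 = x_1 (init is the
# value just before the first sample), i.e. the identical recursion as
# ema_update.
.ema_run <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("detrend: 'alpha' must lie in (0, 1]", call. = FALSE)
  }
  m <- as.numeric(stats::filter((1 - alpha) * x, alpha,
                                method = "recursive", init = x[1]))
  x - m
}

# Shared batch loop for iGLM (window = NULL) and sliding-window iGLM.
.iglm_run <- function(x, dm, window = NULL, warmup_min = NULL,
                      cond_tol = 1e8, anchor_every = 64L) {
  N <- length(x)
  if (N < 1L) stop("detrend: empty series", call. = FALSE)
  X <- dm$X
  p <- dm$p
  nuis <- dm$nuisance_idx
  if (!is.null(window) && window < p) {
    stop(sprintf("detrend: window (%d) must be >= p (%d)", window, p),
         call. = FALSE)
  }
  if (is.null(warmup_min)) {
    warmup_min <- if (is.null(window)) p + 5L else max(p, min(window, p + 5L))
  }
  out <- numeric(N)
  warm <- logical(N)
  xtx <- matrix(0, p, p)
  xty <- numeric(p)
  csum <- 0
  ridge_count <- 0L
  beta <- NULL
  for (t in seq_len(N)) {
    row <- X[t, ]
    xv <- x[t]
    xtx <- xtx + tcrossprod(row)
    xty <- xty + row * xv
    if (!is.null(window)) {
      if (t > window) {
        j <- t - window
        rj <- X[j, ]
        xtx <- xtx - tcrossprod(rj)
        xty <- xty - rj * x[j]
      }
      if (t > window && t %% anchor_every == 0L) {
        lo <- t - window + 1L
        Xb <- X[lo:t, , drop = FALSE]
        xtx <- crossprod(Xb)
        xty <- as.numeric(crossprod(Xb, x[lo:t]))
      }
    }
    if (t < warmup_min) {
      warm[t] <- TRUE
      if (is.null(window)) {
        csum <- csum + xv
        out[t] <- xv - csum / t
      } else {
        lo <- max(1L, t - window + 1L)
        out[t] <- xv - mean(x[lo:t])
      }
    } else {
      if (is.null(window)) csum <- csum + xv
      sol <- .solve_normal(xtx, xty, cond_tol)
      ridge_count <- ridge_count + sol$ridged
      beta <- sol$beta
      out[t] <- xv - sum(row[nuis] * beta[nuis])
    }
  }
  list(detrended = out, warmup = warm, beta_hat = beta,
       ridge_count = ridge_count, warmup_min = warmup_min)
}
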