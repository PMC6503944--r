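#' Block-design specification
#'
#' Task timing for an alternating baseline/regulation block paradigm. Each
#' repetition unit consists of `n_bl` baseline samples followed by `n_reg`
#' regulation samples; an optional extra baseline block can be prepended.
#'
#' @param n_reg samples (TRs) per regulation block, >= 1.
#' @param n_bl samples (TRs) per baseline block, >= 1.
#' @param n_blocks number of repetition units, >= 1.
#' @param tr_seconds repetition time in seconds.
#' @param leading_baseline prepend one baseline block before the first
#'   repetition unit.
#' @return an object of class `block_design`.
#' @export
#' @examples
#' d <- block_design(10, 10, 15)
#' n_samples(d)  # 300
block_design <- function(n_reg, n_bl, n_blocks, tr_seconds = 2,
                         leading_baseline = FALSE) {
  chk <- function(v, name) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 1 || v != round(v)) {
      stop(sprintf("block_design: '%s' must be a positive integer", name),
           call. = FALSE)
    }
    as.integer(v)
  }
  n_reg <- chk(n_reg, "n_reg")
  n_bl <- chk(n_bl, "n_bl")
  n_blocks <- chk(n_blocks, "n_blocks")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("block_design: 'tr_seconds' must be positive", call. = FALSE)
  }
  structure(list(n_reg = n_reg, n_bl = n_bl, n_blocks = n_blocks,
                 tr_seconds = as.numeric(tr_seconds),
                 leading_baseline = isTRUE(leading_baseline)),
            class = "block_design")
}

#' Total number of samples in a block design
#'
#' @param design a `block_design`.
#' @return integer sample count: `n_blocks * (n_bl + n_reg)`, plus `n_bl`
#'   when a leading baseline block is present.
#' @export
n_samples <- function(design) {
  stopifnot(inherits(design, "block_design"))
  design$n_blocks * (design$n_bl + design$n_reg) +
    if (design$leading_baseline) design$n_bl else 0L
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design: REG %d / BL %d TRs x %d blocks, TR = %g s%s>\n",
              x$n_reg, x$n_bl, x$n_blocks, x$tr_seconds,
              if (x$leading_baseline) ", leading baseline" else ""))
  invisible(x)
}

#' Binary task boxcar for a block design
#'
#' @param design a `block_design`.
#' @return a `time_series` of 0 (baseline) / 1 (regulation) samples.
#' @export
#' @examples
#' ts_values(make_boxcar(block_design(1, 1, 2)))  # 0 1 0 1
make_boxcar <- function(design) {
  stopifnot(inherits(design, "block_design"))
  unit <- c(rep(0, design$n_bl), rep(1, design$n_reg))
  v <- rep(unit, design$n_blocks)
  if (design$leading_baseline) v <- c(rep(0, design$n_bl), v)
  time_series(v, design$tr_seconds)
}

#' Parameters of the canonical double-gamma haemodynamic response
#'
#' Defaults are the standard "canonical" parameterization: response peaking
#' at 6 s with a late undershoot at 16 s, unit dispersions, undershoot
#' amplitude ratio 1/6, and a 32 s kernel.
#'
#' @param peak_delay,undershoot_delay delays of response and undershoot (s).
#' @param peak_dispersion,undershoot_dispersion dispersions (s).
#' @param undershoot_ratio amplitude of the undershoot relative to the peak.
#' @param kernel_length kernel support in seconds.
#' @return an object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, kernel_length = 32) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            undershoot_ratio = undershoot_ratio,
            kernel_length = kernel_length)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("hrf_params: '%s' must be a single positive number", nm),
           call. = FALSE)
    }
  }
  if (kernel_length < undershoot_delay) {
    stop("hrf_params: 'kernel_length' must be >= 'undershoot_delay'",
         call. = FALSE)
  }
  structure(p, class = "hrf_params")
}

#' Canonical haemodynamic response kernel
#'
#' Samples the double-gamma difference
#' `h(t) = g(t; a1, b1) - r * g(t; a2, b2)` (with `g` the gamma density,
#' shape `a = delay / dispersion`, scale `b = dispersion`) at
#' `t = 0, TR, 2 TR, ... <= kernel_length`, rescaled so its maximum is 1.
#'
#' @param tr_seconds sampling interval (TR) in seconds.
#' @param params an `hrf_params` object.
#' @return a `time_series` holding the kernel samples.
#' @export
#' @examples
#' h <- canonical_hrf(2)
#' max(ts_values(h))  # 1
canonical_hrf <- function(tr_seconds, params = hrf_params()) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("canonical_hrf: 'tr_seconds' must be positive", call. = FALSE)
  }
  if (!inherits(params, "hrf_params")) params <- do.call(hrf_params, params)
  t <- seq(0, params$kernel_length, by = tr_seconds)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                    scale = params$undershoot_dispersion)
  m <- max(h)
  if (m <= 0) stop("canonical_hrf: degenerate kernel (non-positive maximum)",
                   call. = FALSE)
  time_series(h / m, tr_seconds)
}

#' Clean (noise-free) simulated BOLD response
#'
#' Linear convolution of the task boxcar with the HRF kernel, truncated to
#' the design length and rescaled to a maximum of 1. The unit of every
#' artifact magnitude in the package (spike heights, the step of magnitude
#' 5, drift slopes) is this clean-signal peak.
#'
#' @param design a `block_design`, or a `time_series` holding an arbitrary
#'   boxcar (same TR as the kernel).
#' @param hrf kernel as a `time_series`; default is the canonical HRF
#'   sampled at the design's TR.
#' @return a `time_series` of the same length as the boxcar.
#' @export
make_clean_signal <- function(design, hrf = NULL) {
  box <- if (inherits(design, "block_design")) make_boxcar(design)
         else as_time_series(design)
  if (is.null(hrf)) hrf <- canonical_hrf(box$tr_seconds)
  hrf <- as_time_series(hrf, box$tr_seconds)
  if (abs(box$tr_seconds - hrf$tr_seconds) > 1e-9) {
    stop("make_clean_signal: boxcar and kernel TR differ", call. = FALSE)
  }
  n <- length(box$values)
  y <- stats::convolve(box$values, rev(hrf$values), type = "open")[seq_len(n)]
  y[abs(y) < 1e-14] <- 0  # kill convolution round-off on exact zeros
  m <- max(y)
  if (m > 0) y <- y / m
  time_series(y, box$tr_seconds)
}

#' Orthonormal discrete cosine high-pass basis
#'
#' Column `k` (k = 1..order) has entries
#' `sqrt(2/N) * cos(pi * k * (2 i - 1) / (2 N))`, i = 1..N. Columns are
#' mutually orthonormal and orthogonal to the constant. The cutoff period
#' corresponding to order `k` is `2 N TR / k` seconds.
#'
#' @param n_samples number of rows N.
#' @param order number of cosine columns, `1 <= order < n_samples`.
#' @return an `n_samples x order` matrix.
#' @export
cosine_basis <- function(n_samples, order) {
  n_samples <- as.integer(n_samples)
  order <- as.integer(order)
  if (is.na(n_samples) || n_samples < 2L) {
    stop("cosine_basis: 'n_samples' must be >= 2", call. = FALSE)
  }
  if (is.na(order) || order < 1L || order >= n_samples) {
    stop("cosine_basis: 'order' must satisfy 1 <= order < n_samples",
         call. = FALSE)
  }
  i <- seq_len(n_samples)
  out <- vapply(seq_len(order),
                function(k) sqrt(2 / n_samples) *
                  cos(pi * k * (2 * i - 1) / (2 * n_samples)),
                numeric(n_samples))
  colnames(out) <- paste0("cosine_", seq_len(order))
  out
}

#' GLM design matrix for the incremental detrenders
#'
#' Columns, in order: constant; task regressor (raw boxcar or HRF-convolved,
#' per `task_mode`); linear drift (zero-mean line spanning -0.5..0.5);
#' `n_cosine` discrete cosine high-pass terms. With the default
#' `n_cosine = 7` the matrix has p = 10 columns.
#'
#' @param design a `block_design`.
#' @param task_mode `"convolved"` (default; HRF-convolved boxcar, matching
#'   the simulated BOLD signal) or `"boxcar"`.
#' @param n_cosine number of cosine columns.
#' @param hrf optional kernel `time_series` for `task_mode = "convolved"`.
#' @return an object of class `design_matrix` with fields `X` (matrix),
#'   `column_roles`, `n_samples`, `p`, and `nuisance_idx` (all columns
#'   except the task regressor).
#' @export
build_design_matrix <- function(design, task_mode = c("convolved", "boxcar"),
                                n_cosine = 7, hrf = NULL) {
  stopifnot(inherits(design, "block_design"))
  task_mode <- match.arg(task_mode)
  n <- n_samples(design)
  p <- 3L + as.integer(n_cosine)
  if (n < p) {
    stop(sprintf("build_design_matrix: need n_samples >= p (%d < %d)", n, p),
         call. = FALSE)
  }
  task <- if (task_mode == "convolved") {
    ts_values(make_clean_signal(design, hrf))
  } else {
    ts_values(make_boxcar(design))
  }
  X <- cbind(constant = 1,
             task = task,
             linear = seq(-0.5, 0.5, length.out = n),
             cosine_basis(n, n_cosine))
  roles <- c("constant", "task", "linear", paste0("cosine_", seq_len(n_cosine)))
  colnames(X) <- roles
  structure(list(X = X, column_roles = roles, n_samples = n, p = p,
                 task_mode = task_mode,
                 nuisance_idx = which(roles != "task"),
                 tr_seconds = design$tr_seconds),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix: %d samples x %d regressors (%s task)>\n",
              x$n_samples, x$p, x$task_mode))
  invisible(x)
}

#' Experiment schedule (segments of labelled durations)
#'
#' @param segments a list of `(label, duration_seconds)` pairs, or a
#'   data.frame with columns `label` and `duration_seconds`.
#' @return an object of class `schedule` (data.frame).
#' @export
#' @examples
#' sched <- schedule(c(list(list("baseline", 20)),
#'   rep(list(list("reg", 20), list("fb", 4), list("bl", 16)), 7)))
#' schedule_duration(sched)  # 300
schedule <- function(segments) {
  if (is.data.frame(segments)) {
    df <- segments[, c("label", "duration_seconds")]
  } else {
    if (!is.list(segments) || length(segments) == 0L) {
      stop("schedule: 'segments' must be a nonempty list", call. = FALSE)
    }
    df <- data.frame(
      label = vapply(segments, function(s) as.character(s[[1]]), ""),
      duration_seconds = vapply(segments, function(s) as.numeric(s[[2]]), 0)
    )
  }
  if (nrow(df) == 0L) stop("schedule: empty schedule", call. = FALSE)
  if (any(!nzchar(df$label))) stop("schedule: labels must be nonempty", call. = FALSE)
  if (any(!is.finite(df$duration_seconds)) || any(df$duration_seconds <= 0)) {
    stop("schedule: durations must be positive", call. = FALSE)
  }
  class(df) <- c("schedule", "data.frame")
  df
}

#' Total duration of a schedule in seconds
#'
#' @param sched a `schedule`.
#' @return sum of segment durations (seconds).
#' @export
schedule_duration <- function(sched) {
  if (!inherits(sched, "schedule")) sched <- schedule(sched)
  sum(sched$duration_seconds)
}
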