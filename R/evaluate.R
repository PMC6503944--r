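# Performance metric, benchmark runner, grid search, and GLM statistics.

#' Pearson correlation between two series
#'
#' The benchmark's performance measure: the product-moment correlation
#' between the clean signal and a detrended series. Warm-up samples are
#' included by default; `skip` drops the first samples of both series first
#' (used for steady-state comparisons).
#'
#' @param a,b series of equal length (>= 3 after skipping).
#' @param skip number of leading samples to exclude.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_corr <- function(a, b, skip = 0L) {
  x <- ts_values(a)
  y <- ts_values(b)
  if (length(x) != length(y)) {
    stop("pearson_corr: series lengths differ", call. = FALSE)
  }
  skip <- as.integer(skip)
  if (skip > 0L) {
    x <- x[-seq_len(skip)]
    y <- y[-seq_len(skip)]
  }
  if (length(x) < 3L) {
    stop("pearson_corr: need at least 3 samples", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_corr: zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Describe one detrending algorithm for the benchmark
#'
#' @param method detrending method (see [detrend()]).
#' @param ... method parameters (`alpha`, `window`, `order`, ...).
#' @param id optional identifier; a readable default is derived from the
#'   method and parameters.
#' @return an object of class `algorithm_spec`.
#' @export
#' @examples
#' algorithm("ema", alpha = 0.995)
algorithm <- function(method, ..., id = NULL) {
  params <- list(...)
  if (is.null(id)) {
    id <- if (length(params)) {
      paste0(method, "_", paste(vapply(params, function(v)
        paste(format(v, trim = TRUE), collapse = "-"), ""), collapse = "_"))
    } else method
  }
  structure(list(id = id, method = method, params = params),
            class = "algorithm_spec")
}

#' Run the correlation benchmark
#'
#' For every (design, artifact condition, replicate) in the suite and every
#' algorithm: detrend the degraded series and correlate the output with the
#' clean signal. Fully deterministic given the suite.
#'
#' @param suite a `noise_suite` from [generate_suite()] or [read_suite()].
#' @param algorithms list of `algorithm_spec` objects.
#' @param skip leading samples excluded from the correlation (default 0:
#'   warm-up included).
#' @param task_mode task regressor mode for the GLM design matrices.
#' @return data.frame of `benchmark_record` rows: algorithm id, method,
#'   design id and block lengths, artifact kind / level / replicate / seed,
#'   and the correlation `r`.
#' @export
run_benchmark <- function(suite, algorithms, skip = 0L,
                          task_mode = c("convolved", "boxcar")) {
  stopifnot(inherits(suite, "noise_suite"))
  task_mode <- match.arg(task_mode)
  if (inherits(algorithms, "algorithm_spec")) algorithms <- list(algorithms)
  stopifnot(length(algorithms) >= 1L,
            all(vapply(algorithms, inherits, TRUE, "algorithm_spec")))
  tr <- suite$config$tr_seconds
  recs <- vector("list", 0L)
  for (d in suite$designs) {
    needs_dm <- any(vapply(algorithms, function(a)
      a$method %in% c("iglm", "iglm_window"), TRUE))
    dm <- if (needs_dm) build_design_matrix(d$design, task_mode = task_mode)
          else NULL
    clean <- d$clean
    for (cn in d$conditions) {
      y <- time_series(cn$series, tr)
      for (a in algorithms) {
        args <- c(list(series = y, method = a$method, design = dm,
                       task_mode = task_mode), a$params)
        res <- do.call(detrend, args)
        r <- pearson_corr(res$detrended, clean, skip = skip)
        recs[[length(recs) + 1L]] <- data.frame(
          algorithm = a$id, method = a$method,
          design_id = d$design_id,
          n_reg = d$design$n_reg, n_bl = d$design$n_bl,
          noise_kind = cn$kind, level = cn$level,
          replicate = cn$replicate, seed = cn$seed,
          r = r, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Grid search over a free detrending parameter
#'
#' Evaluates one algorithm family over a parameter grid on a generated
#' suite, aggregates the correlation per grid point, and selects the
#' maximizer (ties broken toward the smallest parameter value).
#'
#' @param method `"ema"` (grid of `alpha`), `"iglm_window"` (grid of window
#'   lengths) or `"cosine"` (grid of orders).
#' @param grid numeric parameter grid (nonempty).
#' @param suite a `noise_suite`.
#' @param aggregate `"records"` (default): plain mean over all (condition,
#'   replicate) records, each simulated series counting once — the literal
#'   optimization target of the benchmark; `"kind"`: mean per artifact kind
#'   first, then unweighted mean over kinds.
#' @param skip leading samples excluded from the correlations.
#' @return an object of class `grid_search_result` with the per-point table
#'   (`table`), per-kind breakdown (`by_kind`), `selected` parameter and a
#'   `tie` note.
#' @export
grid_search <- function(method = c("ema", "iglm_window", "cosine"),
                        grid, suite, aggregate = c("records", "kind"),
                        skip = 0L) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  grid <- as.numeric(grid)
  if (length(grid) < 1L || anyNA(grid)) {
    stop("grid_search: 'grid' must be a nonempty numeric vector", call. = FALSE)
  }
  if (sum(vapply(suite$designs, function(d) length(d$conditions), 0L)) == 0L) {
    stop("grid_search: empty suite", call. = FALSE)
  }
  par_name <- switch(method, ema = "alpha", iglm_window = "window",
                     cosine = "order")
  algos <- lapply(grid, function(g) {
    a <- list(g)
    names(a) <- par_name
    do.call(algorithm, c(list(method = method), a,
                         list(id = sprintf("%s=%g", par_name, g))))
  })
  records <- run_benchmark(suite, algos, skip = skip)
  ids <- vapply(algos, `[[`, "", "id")
  mean_r <- vapply(ids, function(id) {
    rec <- records[records$algorithm == id, ]
    if (aggregate == "records") {
      mean(rec$r)
    } else {
      mean(tapply(rec$r, rec$noise_kind, mean))
    }
  }, 0)
  tab <- data.frame(param = grid, mean_r = unname(mean_r))
  best <- max(tab$mean_r)
  cand <- tab$param[tab$mean_r == best]
  selected <- min(cand)
  by_kind <- stats::aggregate(r ~ algorithm + noise_kind, records, mean)
  structure(list(method = method, parameter = par_name, table = tab,
                 by_kind = by_kind, records = records,
                 aggregate = aggregate, selected = selected,
                 tie = if (length(cand) > 1L)
                   sprintf("%d grid points tied; smallest selected", length(cand))
                 else "none"),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search: %s over %s, selected %s = %g (aggregate: %s)>\n",
              x$method, x$parameter, x$parameter, x$selected, x$aggregate))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' GLM parameter estimates and t-values
#'
#' Ordinary least-squares fit of a series on an explicit design (typically
#' experimental paradigm plus constant), via the normal equations:
#' `beta = (X'X)^{-1} X'y`, standard errors from
#' `sigma^2 * diag((X'X)^{-1})` with `sigma^2 = RSS / (N - p)`, and
#' `t = beta / se`. An exact fit (RSS = 0) is flagged degenerate and yields
#' infinite t for nonzero coefficients.
#'
#' @param series response series.
#' @param design a numeric paradigm vector (a constant column is prepended),
#'   a plain design matrix, or a `design_matrix`.
#' @return an object of class `glm_stats`: coefficient table (`term`,
#'   `beta`, `se`, `t_value`), `dof`, `sigma2`, `residuals`, `degenerate`.
#' @export
glm_stats <- function(series, design) {
  y <- ts_values(series)
  X <- if (inherits(design, "design_matrix")) {
    design$X
  } else if (is.matrix(design)) {
    design
  } else {
    cbind(constant = 1, paradigm = as.numeric(design))
  }
  if (nrow(X) != length(y)) {
    stop("glm_stats: design and series lengths differ", call. = FALSE)
  }
  p <- ncol(X)
  n <- length(y)
  if (n <= p) stop("glm_stats: need N > p", call. = FALSE)
  if (qr(X)$rank < p) stop("glm_stats: rank-deficient design", call. = FALSE)
  xtx <- crossprod(X)
  xtx_inv <- solve(xtx)
  beta <- as.numeric(xtx_inv %*% crossprod(X, y))
  res <- y - as.numeric(X %*% beta)
  rss <- sum(res^2)
  dof <- n - p
  sigma2 <- rss / dof
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_value <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  structure(list(coefficients = data.frame(term = terms, beta = beta,
                                           se = se, t_value = t_value,
                                           stringsAsFactors = FALSE),
                 dof = dof, sigma2 = sigma2, residuals = res,
                 degenerate = rss < .Machine$double.eps * n * max(1, stats::var(y))),
            class = "glm_stats")
}

#' @export
print.glm_stats <- function(x, ...) {
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("dof = %d, sigma^2 = %g%s\n", x$dof, x$sigma2,
              if (x$degenerate) " (degenerate: exact fit)" else ""))
  invisible(x)
}

#' Summarize a benchmark table per algorithm and artifact kind
#'
#' @param records data.frame from [run_benchmark()].
#' @return data.frame with columns `algorithm`, `noise_kind`, `mean_r`,
#'   `sd_r`, `n`.
#' @export
summarize_benchmark <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("summarize_benchmark: empty benchmark table", call. = FALSE)
  }
  agg <- stats::aggregate(r ~ algorithm + noise_kind, records,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  out <- data.frame(algorithm = agg$algorithm, noise_kind = agg$noise_kind,
                    mean_r = agg$r[, "mean"], sd_r = agg$r[, "sd"],
                    n = as.integer(agg$r[, "n"]), stringsAsFactors = FALSE)
  out[order(out$algorithm, out$noise_kind), , drop = FALSE]
}

#' Write benchmark summary tables and figures
#'
#' Produces the per-artifact-type mean +/- sd correlation per algorithm,
#' written as CSV alongside the raw records, plus a dot chart of the mean
#' correlations as PNG.
#'
#' @param records data.frame from [run_benchmark()].
#' @param dir output directory; when NULL nothing is written.
#' @param config_hash optional configuration hash embedded in the CSV
#'   headers.
#' @return invisibly, a list with the `summary` data.frame and the written
#'   `files`.
#' @export
report <- function(records, dir = NULL, config_hash = NULL) {
  summary <- summarize_benchmark(records)
  files <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop(sprintf("report: cannot create '%s'", dir), call. = FALSE)
    }
    hdr <- if (!is.null(config_hash)) sprintf("# config_hash=%s", config_hash)
           else NULL
    wcsv <- function(df, name) {
      path <- file.path(dir, name)
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      if (!is.null(hdr)) writeLines(hdr, con)
      utils::write.csv(df, con, row.names = FALSE)
      path
    }
    files <- c(files, wcsv(summary, "summary.csv"),
               wcsv(records, "records.csv"))
    png_path <- file.path(dir, "performance.png")
    grDevices::png(png_path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    kinds <- unique(summary$noise_kind)
    algos <- unique(summary$algorithm)
    m <- matrix(NA_real_, length(kinds), length(algos),
                dimnames = list(kinds, algos))
    for (i in seq_len(nrow(summary))) {
      m[summary$noise_kind[i], summary$algorithm[i]] <- summary$mean_r[i]
    }
    graphics::matplot(seq_along(kinds), m, type = "b", pch = 19, lty = 1,
                      xaxt = "n", xlab = "artifact type",
                      ylab = "mean correlation with clean signal",
                      main = "Detrending performance by artifact type")
    graphics::axis(1, at = seq_along(kinds), labels = kinds)
    graphics::legend("bottomleft", legend = algos, col = seq_along(algos),
                     pch = 19, lty = 1, cex = 0.8)
    files <- c(files, png_path)
  }
  invisible(list(summary = summary, files = files))
}

#' Read back a benchmark CSV written by [report()]
#'
#' @param path CSV path (leading `#` metadata lines are skipped).
#' @return data.frame.
#' @export
read_benchmark_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
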