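# Plain-text series tables: TSV, '#'-prefixed metadata lines, one 0-based
# sample-index column plus one column per series, '.' decimal separator,
# full float precision (17 significant digits) for lossless round-trips.

#' Series table container
#'
#' @param series a named list of equal-length numeric vectors (one per VOI /
#'   series), or a single numeric vector / `time_series`.
#' @param tr_seconds repetition time metadata.
#' @param meta optional named character vector of extra metadata.
#' @return an object of class `series_table`.
#' @export
series_table <- function(series, tr_seconds = 2, meta = character(0)) {
  if (inherits(series, "time_series")) {
    tr_seconds <- series$tr_seconds
    series <- list(value = series$values)
  }
  if (is.numeric(series)) series <- list(value = series)
  if (!is.list(series) || length(series) == 0L) {
    stop("series_table: 'series' must be a nonempty named list", call. = FALSE)
  }
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    names(series) <- paste0("series", seq_along(series))
  }
  lens <- vapply(series, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("series_table: all series must have equal length", call. = FALSE)
  }
  series <- lapply(series, as.numeric)
  if (any(vapply(series, function(v) anyNA(v) || any(!is.finite(v)), TRUE))) {
    stop("series_table: series must be finite", call. = FALSE)
  }
  structure(list(series = series, tr_seconds = as.numeric(tr_seconds),
                 meta = meta),
            class = "series_table")
}

#' @export
print.series_table <- function(x, ...) {
  cat(sprintf("<series_table: %d series x %d samples, TR = %g s>\n",
              length(x$series), length(x$series[[1]]), x$tr_seconds))
  invisible(x)
}

#' Write a series table as TSV
#'
#' @param table a `series_table`, `time_series`, numeric vector, or named
#'   list of numeric vectors.
#' @param path output path.
#' @param tr_seconds TR used when `table` carries none.
#' @param extra_meta named character vector of additional `# key=value`
#'   metadata lines.
#' @return invisibly, `path`.
#' @export
write_series_table <- function(table, path, tr_seconds = 2,
                               extra_meta = character(0)) {
  if (!inherits(table, "series_table")) {
    table <- series_table(table, tr_seconds)
  }
  n <- length(table$series[[1]])
  meta <- c(table$meta, extra_meta)
  lines <- c("# rtdetrend series table",
             sprintf("# tr_seconds=%s", format(table$tr_seconds, digits = 17)),
             if (length(meta)) sprintf("# %s=%s", names(meta), meta))
  header <- paste(c("sample", names(table$series)), collapse = "\t")
  cols <- c(list(format(0:(n - 1), scientific = FALSE, trim = TRUE)),
            lapply(table$series, function(v)
              formatC(v, digits = 17, format = "g")))
  body <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, header, body), con)
  invisible(path)
}

#' Read a series table written by [write_series_table()]
#'
#' @param path TSV path.
#' @return a `series_table`. Parse failures (ragged rows, non-numeric cells,
#'   missing TR metadata, non-contiguous sample index) raise an error naming
#'   the offending line.
#' @export
read_series_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_series_table: no such file '%s'", path), call. = FALSE)
  }
  raw <- readLines(path)
  is_meta <- startsWith(raw, "#")
  meta_lines <- raw[is_meta]
  tr_line <- grep("^#\\s*tr_seconds=", meta_lines, value = TRUE)
  if (length(tr_line) == 0L) {
    stop("read_series_table: missing '# tr_seconds=' metadata", call. = FALSE)
  }
  tr <- as.numeric(sub("^#\\s*tr_seconds=", "", tr_line[1]))
  if (is.na(tr) || tr <= 0) {
    stop("read_series_table: invalid tr_seconds metadata", call. = FALSE)
  }
  meta <- character(0)
  kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z0-9_.]+)=(.*)$", meta_lines))
  for (m in kv) {
    if (length(m) == 3L && m[2] != "tr_seconds") {
      meta[m[2]] <- m[3]
    }
  }
  body_idx <- which(!is_meta & nzchar(raw))
  if (length(body_idx) < 2L) {
    stop("read_series_table: no data rows", call. = FALSE)
  }
  header <- strsplit(raw[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (header[1] != "sample" || length(header) < 2L) {
    stop(sprintf("read_series_table: line %d: header must start with 'sample'",
                 body_idx[1]), call. = FALSE)
  }
  ncol <- length(header)
  rows_idx <- body_idx[-1]
  parts <- strsplit(raw[rows_idx], "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != ncol)) {
    bad <- rows_idx[which(widths != ncol)[1]]
    stop(sprintf("read_series_table: line %d: expected %d fields, found %d",
                 bad, ncol, widths[which(widths != ncol)[1]]), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = ncol, byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1, any))[1]
    stop(sprintf("read_series_table: line %d: non-numeric cell",
                 rows_idx[bad_row]), call. = FALSE)
  }
  if (!isTRUE(all.equal(mat[, 1], 0:(nrow(mat) - 1)))) {
    stop("read_series_table: sample index must be contiguous from 0",
         call. = FALSE)
  }
  series <- lapply(2:ncol, function(j) mat[, j])
  names(series) <- header[-1]
  series_table(series, tr, meta)
}
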