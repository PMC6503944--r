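#' Configuration of the synthetic benchmark suite
#'
#' Defaults reproduce the study conditions of the benchmark: block designs
#' with regulation and baseline lengths independently varied over 10..60 TRs
#' in steps of 10 with 15 block repetitions (36 designs); Gaussian noise at
#' SNR 5..25 dB (20 seeded replicates per level); linear drifts with slopes
#' 0.05..0.3 per sample (deterministic, one replicate); seeded low-frequency
#' sinusoid-mixture drift and AR(1) colored-noise surrogates at sd 0.25, 0.5,
#' 1.0 (one trace per level); 3 random spikes and a magnitude-5 step, 20
#' seeded replicates each. All magnitudes are in clean-signal peak units.
#'
#' @param n_reg,n_bl grids of regulation / baseline block lengths (TRs).
#' @param n_blocks block repetitions per design.
#' @param tr_seconds repetition time (s).
#' @param leading_baseline prepend a baseline block to every design.
#' @param snr_db Gaussian SNR levels (dB).
#' @param slopes linear drift slopes (signal units per sample).
#' @param nonlinear_sd,colored_sd standard deviations of the drift /
#'   colored-noise surrogates (signal units).
#' @param colored_ar AR(1) coefficient of the colored-noise surrogate.
#' @param spike_count spikes per replicate.
#' @param spike_magnitude range of absolute spike heights.
#' @param step_magnitude step height.
#' @param n_replicates seeded replicates per stochastic condition.
#' @param master_seed master RNG seed; every per-replicate seed derives from
#'   it deterministically.
#' @param include_clean also emit the noise-free condition (kind `"none"`).
#' @param include_confounded also emit a fully-confounded condition
#'   combining all six artifact types at `confound_levels`.
#' @param confound_levels named list of the levels used by the confounded
#'   condition.
#' @return an object of class `suite_config`.
#' @export
suite_config <- function(n_reg = seq(10L, 60L, 10L),
                         n_bl = seq(10L, 60L, 10L),
                         n_blocks = 15L,
                         tr_seconds = 2,
                         leading_baseline = FALSE,
                         snr_db = seq(5, 25, 5),
                         slopes = seq(0.05, 0.3, 0.05),
                         nonlinear_sd = c(0.25, 0.5, 1),
                         colored_sd = c(0.25, 0.5, 1),
                         colored_ar = 0.6,
                         spike_count = 3L,
                         spike_magnitude = c(2, 10),
                         step_magnitude = 5,
                         n_replicates = 20L,
                         master_seed = 1L,
                         include_clean = FALSE,
                         include_confounded = FALSE,
                         confound_levels = list(snr_db = 15, colored_sd = 0.5,
                                                slope = 0.1, nonlinear_sd = 0.5,
                                                step_magnitude = 5)) {
  cfg <- list(n_reg = as.integer(n_reg), n_bl = as.integer(n_bl),
              n_blocks = as.integer(n_blocks), tr_seconds = tr_seconds,
              leading_baseline = isTRUE(leading_baseline),
              snr_db = snr_db, slopes = slopes,
              nonlinear_sd = nonlinear_sd, colored_sd = colored_sd,
              colored_ar = colored_ar, spike_count = as.integer(spike_count),
              spike_magnitude = spike_magnitude,
              step_magnitude = step_magnitude,
              n_replicates = as.integer(n_replicates),
              master_seed = as.integer(master_seed),
              include_clean = isTRUE(include_clean),
              include_confounded = isTRUE(include_confounded),
              confound_levels = confound_levels)
  if (length(cfg$n_reg) < 1L || any(cfg$n_reg < 1L) ||
      length(cfg$n_bl) < 1L || any(cfg$n_bl < 1L) || cfg$n_blocks < 1L) {
    stop("suite_config: invalid design grid", call. = FALSE)
  }
  if (cfg$n_replicates < 1L) stop("suite_config: n_replicates must be >= 1", call. = FALSE)
  structure(cfg, class = "suite_config")
}

#' Enumerate the design grid of a suite configuration
#'
#' @param config a `suite_config`.
#' @return data.frame with one row per design (`design_id`, `n_reg`, `n_bl`,
#'   `n_blocks`); the default grid has 36 rows.
#' @export
suite_designs <- function(config = suite_config()) {
  g <- expand.grid(n_bl = config$n_bl, n_reg = config$n_reg,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(design_id = sprintf("reg%02d_bl%02d", g$n_reg, g$n_bl),
             n_reg = g$n_reg, n_bl = g$n_bl,
             n_blocks = config$n_blocks,
             stringsAsFactors = FALSE)
}

# Enumerate (kind, level, replicate) rows for one design, in the artifact
# order of the benchmark: gaussian, linear, nonlinear, colored, spikes, step.
.condition_grid <- function(config) {
  rows <- list()
  add <- function(kind, level, reps, stochastic) {
    for (lv in level) {
      r <- if (stochastic) seq_len(reps) else 1L
      rows[[length(rows) + 1L]] <<-
        data.frame(kind = kind, level = lv, replicate = r,
                   stringsAsFactors = FALSE)
    }
  }
  if (config$include_clean) add("none", 0, 1L, FALSE)
  add("gaussian", config$snr_db, config$n_replicates, TRUE)
  add("linear_drift", config$slopes, 1L, FALSE)
  # surrogate traces stand in for a single subject's resting-state run:
  # one seeded trace per level
  add("nonlinear_drift", config$nonlinear_sd, 1L, TRUE)
  add("colored", config$colored_sd, 1L, TRUE)
  add("spikes", NA_real_, config$n_replicates, TRUE)
  add("step", config$step_magnitude, config$n_replicates, TRUE)
  if (config$include_confounded) add("confounded", NA_real_, config$n_replicates, TRUE)
  do.call(rbind, rows)
}

.condition_id <- function(kind, level, replicate) {
  lv <- ifelse(is.na(level), "na", formatC(level, format = "g"))
  sprintf("%s_l%s_r%02d", kind, lv, replicate)
}

#' Generate the synthetic benchmark suite
#'
#' Builds, for every requested design, the clean simulated BOLD signal and
#' one degraded series per (artifact condition, replicate), with exact
#' seeded reproducibility: every replicate seed is derived deterministically
#' from `config$master_seed`, and regenerating with the same configuration
#' yields identical series.
#'
#' @param config a `suite_config`.
#' @param designs optional subset: a list of `c(n_reg, n_bl)` pairs or a
#'   character vector of design ids; default is the full grid.
#' @param dir optional directory; when given, all series and the manifest
#'   are also written to disk (see [write_suite()]).
#' @return an object of class `noise_suite`: the config, the design table,
#'   and per design the clean signal plus the list of degraded conditions.
#' @export
generate_suite <- function(config = suite_config(), designs = NULL, dir = NULL) {
  grid <- suite_designs(config)
  if (!is.null(designs)) {
    keep <- if (is.character(designs)) {
      grid$design_id %in% designs
    } else {
      ids <- vapply(designs, function(d) sprintf("reg%02d_bl%02d", d[1], d[2]), "")
      grid$design_id %in% ids
    }
    if (!any(keep)) stop("generate_suite: no design matches the subset", call. = FALSE)
    grid <- grid[keep, , drop = FALSE]
  }
  cond <- .condition_grid(config)
  out <- vector("list", nrow(grid))
  names(out) <- grid$design_id
  counter <- 0L
  for (i in seq_len(nrow(grid))) {
    bd <- block_design(grid$n_reg[i], grid$n_bl[i], grid$n_blocks[i],
                       config$tr_seconds, config$leading_baseline)
    clean <- make_clean_signal(bd)
    conds <- vector("list", nrow(cond))
    for (j in seq_len(nrow(cond))) {
      counter <- counter + 1L
      seed <- derive_seed(config$master_seed, counter)
      k <- cond$kind[j]
      series <- switch(k,
        none = clean,
        gaussian = add_gaussian(clean, cond$level[j], seed),
        linear_drift = add_linear_drift(clean, cond$level[j]),
        nonlinear_drift = time_series(ts_values(clean) +
          ts_values(make_nonlinear_drift(length(clean$values),
                                         config$tr_seconds, cond$level[j], seed)),
          config$tr_seconds),
        colored = time_series(ts_values(clean) +
          ts_values(make_colored_noise(length(clean$values), config$colored_ar,
                                       cond$level[j], seed, config$tr_seconds)),
          config$tr_seconds),
        spikes = add_spikes(clean, config$spike_count, config$spike_magnitude, seed),
        step = add_step(clean, cond$level[j], seed),
        confounded = .confound(clean, config, seed)
      )
      conds[[j]] <- list(
        condition_id = .condition_id(k, cond$level[j], cond$replicate[j]),
        kind = k, level = cond$level[j], replicate = cond$replicate[j],
        seed = seed, series = ts_values(series))
    }
    out[[i]] <- list(design = bd, design_id = grid$design_id[i],
                     clean = ts_values(clean), conditions = conds)
  }
  suite <- structure(list(config = config, grid = grid, designs = out),
                     class = "noise_suite")
  if (!is.null(dir)) write_suite(suite, dir)
  suite
}

# Fully-confounded series: all six artifact types composed in canonical
# order, per-kind seeds derived from the replicate seed.
.confound <- function(clean, config, seed) {
  lv <- config$confound_levels
  specs <- list(
    noise_spec("gaussian", lv$snr_db, seed = derive_seed(seed, 1L)),
    noise_spec("colored", lv$colored_sd, seed = derive_seed(seed, 2L),
               ar_coefficient = config$colored_ar),
    noise_spec("spikes", count = config$spike_count,
               seed = derive_seed(seed, 3L),
               magnitude_range = config$spike_magnitude),
    noise_spec("linear_drift", lv$slope),
    noise_spec("nonlinear_drift", lv$nonlinear_sd, seed = derive_seed(seed, 4L)),
    noise_spec("step", lv$step_magnitude, seed = derive_seed(seed, 5L))
  )
  compose_noise(clean, specs)
}

#' @export
print.noise_suite <- function(x, ...) {
  nc <- sum(vapply(x$designs, function(d) length(d$conditions), 0L))
  cat(sprintf("<noise_suite: %d design(s), %d degraded series, master seed %d>\n",
              nrow(x$grid), nc, x$config$master_seed))
  invisible(x)
}

#' Manifest of a generated suite
#'
#' One row per generated series (clean series included, kind `"clean"`),
#' carrying the design id, artifact kind, level, replicate index, derived
#' seed and, after [write_suite()], the file each series lives in.
#'
#' @param suite a `noise_suite`.
#' @return data.frame manifest.
#' @export
suite_manifest <- function(suite) {
  stopifnot(inherits(suite, "noise_suite"))
  rows <- lapply(suite$designs, function(d) {
    base <- data.frame(design_id = d$design_id, condition_id = "clean",
                       kind = "clean", level = NA_real_, replicate = 0L,
                       seed = NA_integer_,
                       file = file.path(d$design_id, "clean.tsv"),
                       stringsAsFactors = FALSE)
    degraded <- do.call(rbind, lapply(d$conditions, function(cn) {
      data.frame(design_id = d$design_id, condition_id = cn$condition_id,
                 kind = cn$kind, level = cn$level, replicate = cn$replicate,
                 seed = cn$seed,
                 file = file.path(d$design_id, paste0(cn$condition_id, ".tsv")),
                 stringsAsFactors = FALSE)
    }))
    rbind(base, degraded)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a suite (series files plus JSON manifest) to disk
#'
#' @param suite a `noise_suite`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "noise_suite"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("write_suite: cannot create '%s'", dir), call. = FALSE)
  }
  manifest <- suite_manifest(suite)
  tr <- suite$config$tr_seconds
  hash <- config_hash(suite$config)
  for (d in suite$designs) {
    ddir <- file.path(dir, d$design_id)
    dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
    write_series_table(series_table(list(value = d$clean), tr),
                       file.path(ddir, "clean.tsv"), extra_meta = c(config_hash = hash))
    for (cn in d$conditions) {
      write_series_table(series_table(list(value = cn$series), tr),
                         file.path(ddir, paste0(cn$condition_id, ".tsv")),
                         extra_meta = c(config_hash = hash))
    }
  }
  path <- file.path(dir, "manifest.json")
  write_manifest(list(config = unclass(suite$config), config_hash = hash,
                      entries = manifest), path)
  invisible(path)
}

#' Write / read a suite manifest as JSON
#'
#' @param manifest a list with elements `config`, `config_hash`, `entries`.
#' @param path file path.
#' @return `read_manifest` returns the manifest list with `entries` as a
#'   data.frame.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_manifest: no such file '%s'", path), call. = FALSE)
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$entries <- as.data.frame(m$entries, stringsAsFactors = FALSE)
  m
}

#' Reload a suite previously written with [write_suite()]
#'
#' @param dir directory holding `manifest.json` and the series files.
#' @return a `noise_suite` equal to the one that was written.
#' @export
read_suite <- function(dir) {
  m <- read_manifest(file.path(dir, "manifest.json"))
  cfg <- m$config
  cfg$confound_levels <- as.list(cfg$confound_levels)
  config <- do.call(suite_config, cfg[names(cfg) %in% names(formals(suite_config))])
  entries <- m$entries
  ids <- unique(entries$design_id)
  grid <- suite_designs(config)
  grid <- grid[grid$design_id %in% ids, , drop = FALSE]
  designs <- lapply(ids, function(id) {
    e <- entries[entries$design_id == id, , drop = FALSE]
    g <- grid[grid$design_id == id, ]
    read_one <- function(f) {
      p <- file.path(dir, f)
      if (!file.exists(p)) {
        stop(sprintf("read_suite: manifest entry '%s' missing on disk", f),
             call. = FALSE)
      }
      tab <- read_series_table(p)
      tab$series[[1]]
    }
    clean <- read_one(e$file[e$kind == "clean"])
    degraded <- e[e$kind != "clean", , drop = FALSE]
    conds <- lapply(seq_len(nrow(degraded)), function(j) {
      list(condition_id = degraded$condition_id[j], kind = degraded$kind[j],
           level = degraded$level[j], replicate = degraded$replicate[j],
           seed = degraded$seed[j], series = read_one(degraded$file[j]))
    })
    list(design = block_design(g$n_reg, g$n_bl, g$n_blocks,
                               config$tr_seconds, config$leading_baseline),
         design_id = id, clean = clean, conditions = conds)
  })
  names(designs) <- ids
  structure(list(config = config, grid = grid, designs = designs),
            class = "noise_suite")
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; embedded in every artifact the
#' package writes so outputs can be traced to the exact configuration.
#'
#' @param config any jsonlite-serializable object.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}
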