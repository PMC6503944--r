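test_that("pearson_corr obeys the defining identities and guards", {
  set.seed(2)
  x <- stats::rnorm(50)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_equal(pearson_corr(x, 3 + 2 * x), 1)
  expect_equal(pearson_corr(x, 1 - 0.5 * x), -1)
  expect_error(pearson_corr(x, x[-1]), "lengths")
  expect_error(pearson_corr(rep(1, 10), x[1:10]), "zero variance")
  expect_error(pearson_corr(x[1:2], x[1:2]), "at least 3")
  # skip drops leading samples from both series
  y <- c(100, x[-1])
  expect_equal(pearson_corr(x, y, skip = 1), 1)
})

test_that("glm_stats matches the lm oracle on the 6-point paradigm fixture", {
  paradigm <- c(0, 0, 1, 1, 0, 0)
  y <- paradigm + c(0.1, -0.1, 0.05, -0.05, 0.02, -0.02)
  got <- glm_stats(y, paradigm)
  fit <- summary(stats::lm(y ~ paradigm))
  expect_equal(got$coefficients$beta, unname(fit$coefficients[, "Estimate"]),
               tolerance = 1e-10)
  expect_equal(got$coefficients$se, unname(fit$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(got$coefficients$t_value, unname(fit$coefficients[, "t value"]),
               tolerance = 1e-10)
  expect_equal(got$dof, 4)
  # residuals orthogonal to both regressors
  expect_lt(abs(sum(got$residuals)), 1e-8)
  expect_lt(abs(sum(got$residuals * paradigm)), 1e-8)
})

test_that("glm_stats flags exact fits as degenerate with infinite t", {
  paradigm <- c(0, 0, 1, 1, 0, 0, 1, 1)
  y <- 2 * paradigm + 1
  got <- glm_stats(y, paradigm)
  expect_true(got$degenerate)
  expect_equal(got$coefficients$beta, c(1, 2))
  expect_equal(got$coefficients$t_value[2], Inf)
  expect_error(glm_stats(y, cbind(1, paradigm, paradigm)), "rank")
  expect_error(glm_stats(y[1:2], paradigm[1:2]), "N > p")
})

test_that("run_benchmark bookkeeping: one record per condition x algorithm, deterministic", {
  s <- generate_suite(small_config())
  algos <- list(algorithm("ema", alpha = 0.995),
                algorithm("iglm"),
                algorithm("line"))
  rec <- run_benchmark(s, algos)
  ncond <- sum(vapply(s$designs, function(d) length(d$conditions), 0L))
  expect_equal(nrow(rec), ncond * 3)
  expect_true(all(is.finite(rec$r) & rec$r >= -1 & rec$r <= 1))
  rec2 <- run_benchmark(s, algos)
  expect_identical(rec, rec2)
})

test_that("every algorithm passes the noise-free condition nearly untouched", {
  # full-length 10/10/15 design: with only 3 blocks the 7th cosine term
  # reaches the task frequency and the comparison would measure aliasing,
  # not pass-through
  cfg <- small_config(include_clean = TRUE, n_reg = 10L, n_blocks = 15L,
                      snr_db = 10, slopes = 0.1)
  s <- generate_suite(cfg, designs = list(c(10, 10)))
  algos <- list(algorithm("ema", alpha = 0.995),
                algorithm("iglm"),
                algorithm("iglm_window", window = 30),
                algorithm("line"),
                algorithm("cosine", order = 7))
  rec <- run_benchmark(s, algos)
  clean_rec <- rec[rec$noise_kind == "none", ]
  expect_equal(nrow(clean_rec), 5)
  expect_true(all(clean_rec$r >= 0.95))
})

test_that("grid search selects the argmax and breaks ties toward the smallest value", {
  s <- generate_suite(small_config(), designs = list(c(10, 10)))
  g <- grid_search("ema", 0.99, s)
  expect_equal(g$selected, 0.99)
  expect_equal(nrow(g$table), 1)
  # duplicated grid point produces an exact tie; the smaller (identical)
  # value must be selected and the tie reported
  g2 <- grid_search("cosine", c(5, 5), s)
  expect_equal(g2$selected, 5)
  expect_match(g2$tie, "tied")
  expect_error(grid_search("ema", numeric(0), s), "nonempty")
})

test_that("window/block interaction: windows exceeding the block length win on 40/40", {
  s40 <- full_suite_40()
  g <- grid_search("iglm_window", c(10, 60), s40)
  tab <- g$table
  expect_gt(tab$mean_r[tab$param == 60], tab$mean_r[tab$param == 10])
})

test_that("report summarizes per algorithm and artifact kind and round-trips", {
  s <- generate_suite(small_config(), designs = list(c(10, 10)))
  algos <- list(algorithm("ema", alpha = 0.995), algorithm("iglm"))
  rec <- run_benchmark(s, algos)
  dir <- withr::local_tempdir()
  out <- report(rec, dir = dir, config_hash = "abc123")
  kinds <- length(unique(rec$noise_kind))
  expect_equal(nrow(out$summary), 2 * kinds)
  expect_true(all(out$summary$mean_r >= -1 & out$summary$mean_r <= 1))
  expect_true(all(file.exists(out$files)))
  back <- read_benchmark_csv(file.path(dir, "records.csv"))
  expect_equal(back$r, rec$r)
  expect_equal(back$algorithm, rec$algorithm)
  expect_error(report(rec[0, ]), "empty")
})
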