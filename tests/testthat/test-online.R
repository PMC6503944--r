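test_that("EMA recursion: constant input, alpha = 1 limit, and ramp lag", {
  # constant input: the running mean locks on, output identically 0
  r <- stream_run(ema_state(0.98), ema_update, rep(3.7, 50))
  expect_equal(r$detrended, rep(0, 50))

  # alpha = 1 degenerates to subtraction of the first sample
  x <- sin(1:40)
  r1 <- stream_run(ema_state(1), ema_update, x)
  expect_equal(r1$detrended, x - x[1])

  # unit-slope ramp: steady-state lag alpha / (1 - alpha) = 39 for 0.975
  # (brute-force recursion: 39 * alpha^t remains ~1e-5 at t = 600 and
  # drops below 1e-6 around t = 690)
  ramp <- as.numeric(1:700)
  rr <- stream_run(ema_state(0.975), ema_update, ramp)
  expect_equal(rr$detrended[600], 39, tolerance = 1e-4)
  expect_lt(abs(rr$detrended[700] - 39), 1e-6)

  expect_error(ema_state(0), "alpha")
  expect_error(ema_state(1.01), "alpha")
  expect_error(ema_update(ema_state(0.9), NaN), "finite")
})

test_that("iGLM equals batch OLS and removes in-model drift exactly", {
  dm <- dm_10()
  clean <- clean_10()
  y <- add_linear_drift(clean, 0.3)
  res <- detrend(y, "iglm", design = dm)
  # drift lies in the column space: post-warm-up output matches the clean
  # signal up to a constant offset
  expect_gte(pearson_corr(res$detrended, clean, skip = 14), 0.999)
  # final coefficients equal the full-series normal-equation solution
  oracle <- stats::lm(ts_values(y) ~ 0 + dm$X)
  expect_equal(res$beta_hat, unname(stats::coef(oracle)),
               tolerance = 1e-8)
  # warm-up contract
  st <- iglm_state(dm)
  sr <- stream_run(st, iglm_update, ts_values(y))
  expect_true(all(sr$warmup[1:14]))
  expect_false(any(sr$warmup[15:300]))
})

test_that("incremental accumulators equal direct products at every step", {
  dm <- build_design_matrix(block_design(5, 5, 6))
  set.seed(41)
  x <- stats::rnorm(60)
  st <- iglm_state(dm)
  for (t in 1:60) {
    st <- iglm_update(st, x[t])$state
    Xt <- dm$X[1:t, , drop = FALSE]
    expect_lt(max(abs(st$xtx - crossprod(Xt))), 1e-8)
    expect_lt(max(abs(st$xty - as.numeric(crossprod(Xt, x[1:t])))), 1e-8)
  }
})

test_that("windowed accumulators match direct recomputation over the buffer", {
  dm <- dm_10()
  set.seed(17)
  x <- stats::rnorm(300, sd = 3)
  st <- iglm_window_state(dm, window = 37)
  checkpoints <- sort(sample(38:300, 25))
  for (t in 1:300) {
    st <- iglm_window_update(st, x[t])$state
    if (t %in% checkpoints) {
      lo <- max(1, t - 37 + 1)
      Xb <- dm$X[lo:t, , drop = FALSE]
      expect_lt(max(abs(st$xtx - crossprod(Xb))), 1e-8)
      expect_lt(max(abs(st$xty - as.numeric(crossprod(Xb, x[lo:t])))), 1e-8)
    }
  }
})

test_that("window spanning the whole series reproduces the full iGLM", {
  dm <- dm_10()
  y <- ts_values(add_gaussian(clean_10(), 10, seed = 77L))
  full <- detrend(y, "iglm", design = dm)
  win <- detrend(y, "iglm_window", design = dm, window = 300)
  expect_equal(ts_values(win$detrended), ts_values(full$detrended),
               tolerance = 1e-8)
  expect_error(iglm_window_state(dm, window = 9), "window")
  expect_error(detrend(y, "iglm_window", design = dm, window = 9), "window")
})

test_that("pre-step baseline is forgotten once the step exits the window", {
  dm <- dm_10()
  n <- 300
  t0 <- 150
  w <- 30
  y1 <- add_step(clean_10(), 5, t0 = t0)
  y2 <- time_series(ts_values(y1) + 7 * (seq_len(n) < t0), 2)
  o1 <- ts_values(detrend(y1, "iglm_window", design = dm, window = w)$detrended)
  o2 <- ts_values(detrend(y2, "iglm_window", design = dm, window = w)$detrended)
  idx <- (t0 + w):n
  expect_lt(max(abs(o1[idx] - o2[idx])), 1e-8)
})

test_that("all online detrenders are strictly causal", {
  dm <- dm_10()
  set.seed(23)
  for (rep in 1:5) {
    x <- ts_values(add_gaussian(clean_10(), stats::runif(1, 5, 25),
                                seed = 100L + rep))
    tcut <- sample(20:280, 1)
    for (m in c("ema", "iglm", "iglm_window")) {
      full <- ts_values(detrend(x, m, design = dm, alpha = 0.98,
                                window = 40)$detrended)
      pre <- ts_values(detrend(x[1:tcut], m, design = dm, alpha = 0.98,
                               window = 40)$detrended)
      expect_lt(max(abs(full[1:tcut] - pre)), 1e-12)
    }
  }
})

test_that("streaming updates and batch runner agree sample-for-sample", {
  dm <- dm_10()
  x <- ts_values(add_gaussian(clean_10(), 15, seed = 3L))
  b_ema <- ts_values(detrend(x, "ema", alpha = 0.99)$detrended)
  s_ema <- stream_run(ema_state(0.99), ema_update, x)$detrended
  expect_equal(s_ema, b_ema, tolerance = 1e-12)

  b_ig <- ts_values(detrend(x, "iglm", design = dm)$detrended)
  s_ig <- stream_run(iglm_state(dm), iglm_update, x)$detrended
  expect_equal(s_ig, b_ig, tolerance = 1e-10)

  b_w <- ts_values(detrend(x, "iglm_window", design = dm, window = 40)$detrended)
  s_w <- stream_run(iglm_window_state(dm, 40), iglm_window_update, x)$detrended
  expect_equal(s_w, b_w, tolerance = 1e-10)
})

test_that("EMA at alpha = 0.995 transmits the clean block signal with low distortion", {
  r <- detrend(clean_10(), "ema", alpha = 0.995)
  expect_gte(pearson_corr(r$detrended, clean_10()), 0.95)
})
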