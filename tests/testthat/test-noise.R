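test_that("gaussian noise hits the requested empirical SNR exactly", {
  x <- clean_10()
  for (snr in c(0, 5, 10, 15, 20, 25)) {
    y <- add_gaussian(x, snr, seed = 42L)
    noise <- ts_values(y) - ts_values(x)
    ratio <- stats::var(ts_values(x)) / stats::var(noise)
    expect_equal(10 * log10(ratio), snr, tolerance = 1e-9)
  }
  expect_identical(ts_values(add_gaussian(x, 10, 7L)),
                   ts_values(add_gaussian(x, 10, 7L)))
  expect_error(add_gaussian(rep(1, 50), 10, 1L), "zero variance")
})

test_that("linear drift is an exact per-sample ramp", {
  z <- rep(0, 20)
  expect_identical(add_linear_drift(z, 0), z)
  expect_equal(add_linear_drift(z, 0.05)[11], 0.5)
  x <- ts_values(clean_10())
  y <- add_linear_drift(x, 0.2)
  n <- length(x)
  expect_equal((y[n] - y[1]) - (x[n] - x[1]), 0.2 * (n - 1))
})

test_that("non-linear drift trace is slow, seeded and scaled to the target sd", {
  expect_equal(ts_values(make_nonlinear_drift(100, 2, 0, seed = 1L)), rep(0, 100))
  tr <- make_nonlinear_drift(600, 2, 0.8, seed = 5L)
  v <- ts_values(tr)
  expect_equal(stats::sd(v), 0.8, tolerance = 1e-12)
  expect_identical(v, ts_values(make_nonlinear_drift(600, 2, 0.8, seed = 5L)))
  # periodogram: fraction of power at periods < 128 s must be negligible
  for (seed in 1:5) {
    v <- ts_values(make_nonlinear_drift(600, 2, 0.8, seed = seed))
    n <- length(v)
    sp <- Mod(stats::fft(v - mean(v)))[2:(n %/% 2)]^2
    freq <- (1:(n %/% 2 - 1)) / (n * 2)   # cycles per second, TR = 2 s
    frac_fast <- sum(sp[freq > 1 / 128]) / sum(sp)
    expect_lte(frac_fast, 0.01)
  }
  expect_error(make_nonlinear_drift(4, 2, 1, 1L), ">= 8")
})

test_that("colored noise is a stationary AR(1) with the requested autocorrelation", {
  w <- ts_values(make_colored_noise(2000, 0, sd = 1, seed = 3L))
  expect_lt(abs(stats::cor(w[-1], w[-length(w)])), 0.1)
  e <- ts_values(make_colored_noise(5000, 0.5, sd = 1, seed = 9L))
  expect_equal(stats::cor(e[-1], e[-length(e)]), 0.5, tolerance = 0.05)
  expect_equal(stats::sd(e), 1, tolerance = 1e-12)
  expect_identical(e, ts_values(make_colored_noise(5000, 0.5, 1, seed = 9L)))
  expect_error(make_colored_noise(100, 1.0, 1, 1L), "ar_coefficient")
})

test_that("spikes are distinct single-sample deltas within bounds", {
  x <- clean_10()
  y <- add_spikes(x, seed = 21L)
  diffidx <- which(ts_values(y) != ts_values(x))
  expect_length(diffidx, 3)
  expect_true(all(diffidx >= 1 & diffidx <= 300))
  mags <- abs(ts_values(y)[diffidx] - ts_values(x)[diffidx])
  expect_true(all(mags >= 2 & mags <= 10))
  expect_identical(ts_values(add_spikes(x, count = 0, seed = 1L)), ts_values(x))
  expect_error(add_spikes(1:5, count = 6, seed = 1L), "exceeds")
})

test_that("step adds a single baseline shift of the stated magnitude", {
  x <- clean_10()
  y <- add_step(x, magnitude = 5, seed = 13L)
  jump <- diff(ts_values(y) - ts_values(x))
  expect_equal(sum(jump != 0), 1)
  expect_equal(jump[jump != 0], 5)
  t0 <- which(jump != 0) + 1
  n <- length(ts_values(x))
  expect_gte(t0, ceiling(0.1 * n))
  expect_lte(t0, floor(0.9 * n))
  expect_identical(ts_values(add_step(x, magnitude = 0, seed = 1L)), ts_values(x))
  expect_error(add_step(x, 5, t0 = 1), "t0")
})

test_that("every generator is a pure function of (inputs, seed)", {
  x <- clean_10()
  specs <- list(noise_spec("gaussian", 10, seed = 5L),
                noise_spec("linear_drift", 0.1),
                noise_spec("nonlinear_drift", 0.5, seed = 5L),
                noise_spec("colored", 0.5, seed = 5L),
                noise_spec("spikes", seed = 5L),
                noise_spec("step", 5, seed = 5L))
  for (sp in specs) {
    expect_identical(ts_values(apply_noise(x, sp)),
                     ts_values(apply_noise(x, sp)), label = sp$kind)
  }
})

test_that("composed confounded series equals clean plus the sum of additive traces", {
  x <- clean_10()
  specs <- list(noise_spec("gaussian", 15, seed = 1L),
                noise_spec("colored", 0.5, seed = 2L),
                noise_spec("spikes", seed = 3L),
                noise_spec("linear_drift", 0.1),
                noise_spec("nonlinear_drift", 0.5, seed = 4L),
                noise_spec("step", 5, seed = 6L))
  composed <- ts_values(compose_noise(x, specs))
  traces <- lapply(specs, function(sp) ts_values(apply_noise(x, sp)) - ts_values(x))
  expect_equal(composed, ts_values(x) + Reduce(`+`, traces), tolerance = 1e-10)
  expect_error(compose_noise(x, c(specs, specs[1])), "one condition per")
})
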