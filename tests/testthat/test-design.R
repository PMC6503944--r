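test_that("boxcar construction follows the block layout", {
  expect_equal(ts_values(make_boxcar(block_design(1, 1, 2))), c(0, 1, 0, 1))

  b <- make_boxcar(block_design(10, 10, 15))
  expect_length(ts_values(b), 300)
  expect_equal(sum(ts_values(b)), 150)

  withlead <- make_boxcar(block_design(5, 3, 2, leading_baseline = TRUE))
  expect_equal(ts_values(withlead)[1:3], rep(0, 3))
  expect_length(ts_values(withlead), 2 * 8 + 3)

  expect_error(block_design(10, 10, 0), "positive integer")
  expect_error(block_design(0, 10, 5), "positive integer")
})

test_that("boxcar length formula holds over random valid designs", {
  set.seed(11)
  for (i in 1:30) {
    nr <- sample(1:60, 1)
    nb <- sample(1:60, 1)
    k <- sample(1:20, 1)
    lead <- sample(c(TRUE, FALSE), 1)
    d <- block_design(nr, nb, k, leading_baseline = lead)
    expect_equal(length(ts_values(make_boxcar(d))),
                 k * (nr + nb) + if (lead) nb else 0)
    expect_equal(n_samples(d), length(ts_values(make_boxcar(d))))
  }
})

test_that("canonical HRF peaks near 5 s, starts at 0 and is max-normalized", {
  h <- canonical_hrf(0.1)
  v <- ts_values(h)
  tt <- seq(0, 32, by = 0.1)
  expect_equal(v[1], 0)
  expect_equal(max(v), 1)
  # mode of the peak gamma component is (shape - 1) * scale = 5 s
  expect_gte(tt[which.max(v)], 4.5)
  expect_lte(tt[which.max(v)], 5.5)
  # late undershoot is negative
  expect_lt(min(v[tt > 10]), 0)
  expect_error(hrf_params(peak_delay = -1), "positive")
  expect_error(hrf_params(kernel_length = 10), "kernel_length")
})

test_that("clean signal is the truncated, max-1 convolution of boxcar and kernel", {
  # convolution of an all-zero boxcar is zero
  z <- make_clean_signal(time_series(rep(0, 50)))
  expect_equal(ts_values(z), rep(0, 50))

  # impulse boxcar reproduces the kernel (truncated)
  h <- canonical_hrf(2)
  imp <- time_series(c(1, rep(0, 49)))
  got <- ts_values(make_clean_signal(imp, h))
  expect_equal(got[seq_along(ts_values(h))], ts_values(h), tolerance = 1e-12)

  # independent direct-sum convolution oracle on a small design
  d <- block_design(3, 4, 2)
  box <- ts_values(make_boxcar(d))
  ker <- ts_values(h)
  n <- length(box)
  oracle <- vapply(seq_len(n), function(i) {
    js <- seq_len(min(i, length(ker)))
    sum(ker[js] * box[i - js + 1])
  }, 0)
  oracle <- oracle / max(oracle)
  expect_equal(ts_values(make_clean_signal(d, h)), oracle, tolerance = 1e-10)

  s <- make_clean_signal(block_design(10, 10, 15))
  expect_length(ts_values(s), 300)
  expect_identical(max(ts_values(s)), 1)

  expect_error(make_clean_signal(time_series(c(0, 1), tr_seconds = 1),
                                 canonical_hrf(2)), "TR differ")
})

test_that("interior repetitions of a symmetric design reach a periodic steady state", {
  d <- block_design(10, 10, 15)
  s <- ts_values(make_clean_signal(d))
  period <- 20
  blocks <- vapply(3:(15 - 1), function(k) s[((k - 1) * period + 1):(k * period)],
                   numeric(period))
  ref <- blocks[, 1]
  expect_lt(max(abs(blocks - ref)), 1e-10)
})

test_that("cosine basis is orthonormal and orthogonal to the constant", {
  G <- cosine_basis(4, 2)
  expect_lt(max(abs(crossprod(G) - diag(2))), 1e-12)
  expect_lt(abs(sum(cosine_basis(17, 1))), 1e-12)
  expect_error(cosine_basis(5, 5), "order")

  set.seed(7)
  for (i in 1:8) {
    n <- sample(20:2000, 1)
    k <- sample(1:20, 1)
    B <- cosine_basis(n, k)
    expect_lt(max(abs(crossprod(B) - diag(k))), 1e-10)
    expect_lt(max(abs(colSums(B))), 1e-10)
  }
})

test_that("design matrix has the documented columns, rank and linear convention", {
  dm <- dm_10()
  expect_equal(dm$p, 10)
  expect_equal(dm$column_roles,
               c("constant", "task", "linear", paste0("cosine_", 1:7)))
  lin <- dm$X[, "linear"]
  expect_equal(mean(lin), 0)
  expect_equal(lin[length(lin)] - lin[1], 1)
  expect_equal(qr(dm$X)$rank, 10)

  dmb <- build_design_matrix(design_10(), task_mode = "boxcar")
  expect_equal(sort(unique(dmb$X[, "task"])), c(0, 1))

  expect_error(build_design_matrix(block_design(2, 2, 2)), "n_samples >= p")
})

test_that("schedule duration sums segment durations", {
  segs <- c(list(list("baseline", 20)),
            rep(list(list("reg", 20), list("fb", 4), list("bl", 16)), 7))
  expect_equal(schedule_duration(schedule(segs)), 300)
  expect_equal(schedule_duration(schedule(list(list("x", 12.5)))), 12.5)
  expect_error(schedule(list()), "nonempty")
  expect_error(schedule(list(list("", 3))), "nonempty|labels")
  expect_error(schedule(list(list("a", -1))), "positive")
})
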