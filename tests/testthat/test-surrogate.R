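test_that("phase shuffling preserves the amplitude spectrum bin-wise", {
  set.seed(3)
  x <- matrix(rnorm(250 * 4), 250, 4)
  set.seed(11)
  y <- phase_shuffle(x)
  expect_equal(abs(mvfft(y)), abs(mvfft(x)), tolerance = 1e-9)
  expect_false(identical(x, y))
})

test_that("a pure on-grid sinusoid is invariant under phase shuffling up to its own phase", {
  fs <- 100
  t <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 4 * t)  # 10 cycles: a single positive-frequency bin
  set.seed(5)
  y <- phase_shuffle(x)
  # single non-DC component: still a pure 4 Hz sinusoid of the same
  # amplitude (only that bin's phase can change)
  expect_equal(abs(fft(y)), abs(fft(x)), tolerance = 1e-9)
  base <- cbind(sin(2 * pi * 4 * t), cos(2 * pi * 4 * t))
  resid <- y - base %*% solve(crossprod(base), crossprod(base, y))
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("time shuffling permutes the sample multiset per channel", {
  set.seed(9)
  x <- matrix(rnorm(200 * 3), 200, 3)
  set.seed(21)
  y <- time_shuffle(x)
  for (j in 1:3) {
    expect_equal(sort(y[, j]), sort(x[, j]))
    expect_equal(var(y[, j]), var(x[, j]))
  }
  expect_false(identical(x, y))
})

test_that("surrogates destroy planted coupling", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 30, seed = 19)
  cp <- planted_coupling(rbind(c("C5", "CP3")), kappa = 1, lag = pi / 3)
  rec <- bandpass_theta(generate_epochs(cfg, list(cp), "Sleep", "L"))
  tens <- windowed_connectivity(rec, metrics = "plv")
  i <- which(tens$pairs$chan_i == "C5" & tens$pairs$chan_j == "CP3")
  for (meth in c("phase", "time")) {
    nul <- build_null(rec, metrics = "plv", n = 30, method = meth, seed = 4)
    # the planted pair's surrogate PLVs sit at the uncoupled background level
    null_planted <- as.vector(nul$null$plv[i, , , ])
    bg <- as.vector(tens$values$plv[-i, , ])
    expect_lt(abs(mean(null_planted) - mean(bg)), 0.08)
    expect_gt(mean(tens$values$plv[i, , ]) - mean(null_planted), 0.3)
  }
})

test_that("build_null bookkeeping: dimensions, determinism, and the standalone equivalence", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 3, seed = 8)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "L"))
  expect_warning(build_null(rec, n = 10, seed = 2), "unstable")
  nul <- build_null(rec, n = 25, method = "phase", seed = 6)
  expect_equal(dim(nul$null$plv), c(78, 3, 3, 25))
  expect_equal(dim(nul$null$wpli), c(78, 3, 3, 25))
  nul2 <- build_null(rec, n = 25, method = "phase", seed = 6)
  expect_identical(nul$null, nul2$null)

  # first surrogate equals phase_shuffle + windowed_connectivity by hand
  d <- dim(rec$data)
  m <- matrix(aperm(rec$data, c(3, 1, 2)), nrow = d[3])
  set.seed(6)
  xs <- phase_shuffle(m)
  rec_s <- rec
  rec_s$data <- aperm(array(xs, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  tens_s <- windowed_connectivity(rec_s)
  expect_equal(nul$null$plv[, , , 1], unname(tens_s$values$plv), tolerance = 1e-9)
  expect_equal(nul$null$wpli[, , , 1], unname(tens_s$values$wpli), tolerance = 1e-9)
})

test_that("real uncoupled values fall uniformly in their null CDF (PIT)", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 12, seed = 33)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "L"))
  tens <- windowed_connectivity(rec, metrics = "plv")
  nul <- build_null(rec, metrics = "plv", n = 60, method = "phase", seed = 34)
  nm <- matrix(nul$null$plv, nrow = length(tens$values$plv))
  pit <- (rowSums(nm < as.vector(tens$values$plv)) +
            runif(nrow(nm)) * (1 + rowSums(nm == as.vector(tens$values$plv)))) / (60 + 1)
  ks <- suppressWarnings(stats::ks.test(pit, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pruning keeps extreme ranks, zeroes sub-centile cells, and reports empirical p", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 4, seed = 14)
  cp <- planted_coupling(rbind(c("C5", "CP3")), kappa = 0.95, lag = pi / 3)
  rec <- bandpass_theta(generate_epochs(cfg, list(cp), "Sleep", "L"))
  tens <- windowed_connectivity(rec, metrics = "plv")
  nul <- build_null(rec, metrics = "plv", n = 100, method = "phase", seed = 15)
  pr <- significance_prune(tens, nul)
  i <- which(tens$pairs$chan_i == "C5" & tens$pairs$chan_j == "CP3")
  # the planted pair beats (essentially) all 100 surrogates: kept, p ~ 1/101
  expect_true(all(pr$mask$keep$plv[i, , ]))
  expect_equal(median(pr$mask$p$plv[i, , ]), 1 / 101, tolerance = 1e-12)
  expect_lte(max(pr$mask$p$plv[i, , ]), 2 / 101)
  expect_equal(pr$pruned$values$plv[i, , ], tens$values$plv[i, , ])
  # zeroed cells are exactly the non-kept ones
  expect_true(all(pr$pruned$values$plv[!pr$mask$keep$plv] == 0))
  expect_true(all(pr$pruned$values$plv[pr$mask$keep$plv] > 0))
  # a cell at its null median is zeroed
  med_cell <- which.min(abs(pr$mask$p$plv - 0.5))
  expect_false(pr$mask$keep$plv[med_cell])
  expect_equal(pr$pruned$values$plv[med_cell], 0)
  # shape mismatch errors
  nul_bad <- nul
  nul_bad$null$plv <- nul$null$plv[, , 1:2, , drop = FALSE]
  expect_error(significance_prune(tens, nul_bad), "shape")
})

test_that("degenerate wPLI cells are excluded from significance testing", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 2, seed = 26)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "L"))
  rec$data[2, , ] <- rec$data[1, , ]  # exact zero-lag duplicate
  tens <- windowed_connectivity(rec)
  nul <- build_null(rec, n = 25, seed = 27)
  pr <- significance_prune(tens, nul)
  i <- which(tens$pairs$chan_i == "Fz" & tens$pairs$chan_j == "Cz")
  expect_true(all(tens$degenerate[i, , ]))
  expect_false(any(pr$mask$keep$wpli[i, , ]))
  expect_true(all(is.na(pr$mask$p$wpli[i, , ])))
})

test_that("phase and time shuffling give statistically compatible keep decisions", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 30, seed = 44)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "L"))
  tens <- windowed_connectivity(rec, metrics = "plv")
  kp <- significance_prune(tens, build_null(rec, metrics = "plv", n = 60,
                                            method = "phase", seed = 45))$mask$keep$plv
  kt <- significance_prune(tens, build_null(rec, metrics = "plv", n = 60,
                                            method = "time", seed = 46))$mask$keep$plv
  # both are ~alpha-level on null data and agree far above chance
  expect_lt(abs(mean(kp) - mean(kt)), 0.03)
  expect_gt(mean(kp == kt), 0.9)
})
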