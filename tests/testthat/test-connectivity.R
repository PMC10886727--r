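test_that("instantaneous phase of a cosine advances at the carrier rate", {
  fs <- 250
  t <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  # 5 Hz is on the FFT grid of a 2.5 s epoch? 12.5 cycles -> no; use 4.8 Hz (12 cycles)
  f0 <- 12 / 2.5
  ph <- instantaneous_phase(cos(2 * pi * f0 * t))
  mid <- 100:500
  slope <- diff(ph[mid])
  slope <- Arg(exp(1i * slope)) * fs      # unwrap increments
  expect_equal(mean(slope), 2 * pi * f0, tolerance = 0.01 * 2 * pi * f0)

  # quadrature: sin lags cos by pi/2
  phs <- instantaneous_phase(sin(2 * pi * f0 * t))
  d <- Arg(exp(1i * (ph[mid] - phs[mid])))
  expect_equal(mean(d), pi / 2, tolerance = 1e-6)
  expect_lt(stats::sd(d), 1e-6)

  expect_error(instantaneous_phase(rep(0, 100)), "all-zero")
})

test_that("analytic transform matches an independent FFT oracle sample-wise", {
  set.seed(42)
  fs <- 100
  n <- 250
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 2, fs = fs, seed = 17)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "L"))
  x <- rec$data[4, 1, ]
  a_pkg <- phaseconn:::analytic_signal(matrix(x, ncol = 1))[, 1]
  a_ref <- ref_analytic(x)
  expect_lt(max(Mod(a_pkg - a_ref)), 1e-9)
  expect_equal(instantaneous_phase(x), Arg(a_ref), tolerance = 1e-9)
})

test_that("plv matches its defining formula on hand values and random phases", {
  expect_equal(plv(rep(0.7, 123)), 1)
  expect_equal(plv(rep(c(0, pi), 50)), 0, tolerance = 1e-12)
  expect_error(plv(numeric(0)))
  set.seed(7)
  for (i in 1:5) {
    th <- runif(200, -pi, pi)
    expect_equal(plv(th), ref_plv(th), tolerance = 1e-12)
  }
})

test_that("null PLV of i.i.d. uniform phases follows the Rayleigh mean", {
  set.seed(101)
  T <- 1e4
  reps <- 1000
  vals <- vapply(seq_len(reps), function(i) plv(runif(T, 0, 2 * pi)), 0)
  expect_equal(mean(vals), 0.5 * sqrt(pi / T), tolerance = 0.05)
})

test_that("wpli matches direct evaluation, sign cases and the degenerate rule", {
  w <- wpli(complex(imaginary = c(3, 1, -1)))
  expect_equal(w$value, 0.6)
  expect_false(w$degenerate)
  expect_equal(wpli(complex(imaginary = c(2, 5, 0.1)))$value, 1)
  z <- wpli(complex(real = c(1, 2, 3), imaginary = c(0, 0, 0)))
  expect_equal(z$value, 0)
  expect_true(z$degenerate)
  set.seed(8)
  im <- rnorm(300)
  expect_equal(wpli(im)$value, ref_wpli(im)$value, tolerance = 1e-12)
})

test_that("windows are the fixed 1 s / 50% overlap layout", {
  w <- analysis_windows(100)
  expect_equal(w$label, c("w1", "w2", "w3"))
  expect_equal(w$start_s, c(0, 0.5, 1))
  expect_equal(w$start_sample, c(50, 100, 150))
  expect_equal(w$n_samples, rep(100L, 3))
})

test_that("a perfectly locked lagged pair scores ~1 on both metrics in all windows", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 6, snr = Inf, seed = 3)
  cp <- planted_coupling(rbind(c("C5", "CP3")), kappa = 1, lag = pi / 2)
  tens <- windowed_connectivity(bandpass_theta(generate_epochs(cfg, list(cp), "Sleep", "L")))
  i <- which(tens$pairs$chan_i == "C5" & tens$pairs$chan_j == "CP3")
  expect_gte(min(tens$values$plv[i, , ]), 0.99)
  expect_gte(min(tens$values$wpli[i, , ]), 0.99)
})

test_that("duplicated channels give PLV 1 and degenerate wPLI 0", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 2, seed = 9)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "L"))
  rec$data[2, , ] <- rec$data[1, , ]  # Cz := Fz
  tens <- windowed_connectivity(rec)
  i <- which(tens$pairs$chan_i == "Fz" & tens$pairs$chan_j == "Cz")
  expect_equal(min(tens$values$plv[i, , ]), 1, tolerance = 1e-9)
  expect_equal(max(tens$values$wpli[i, , ]), 0)
  expect_true(all(tens$degenerate[i, , ]))
})

test_that("vectorised tensor equals the straight-line reference element-wise", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 3, seed = 23)
  cp <- planted_coupling(rbind(c("F3", "C5"), c("C6", "P8")), kappa = 0.6, lag = pi / 4)
  rec <- bandpass_theta(generate_epochs(cfg, list(cp), "Sleep", "L"))
  tens <- windowed_connectivity(rec)
  ref <- ref_windowed_connectivity(rec)
  expect_lt(max(abs(tens$values$plv - ref$plv)), 1e-9)
  expect_lt(max(abs(tens$values$wpli - ref$wpli)), 1e-9)
})

test_that("metrics are bounded, symmetric in pair order, and amplitude invariant", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 4, seed = 31)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Pre", "R"))
  tens <- windowed_connectivity(rec)
  for (mm in c("plv", "wpli")) {
    expect_true(all(tens$values[[mm]] >= 0 & tens$values[[mm]] <= 1))
  }
  # swapping channel order only flips the sign of Im(Pxy): metrics unchanged
  rec_swap <- rec
  rec_swap$data <- rec$data[c(2, 1, 3:13), , ]
  rec_swap$channel_labels <- rec$channel_labels[c(2, 1, 3:13)]
  dimnames(rec_swap$data) <- list(rec_swap$channel_labels, NULL, NULL)
  tens_swap <- windowed_connectivity(rec_swap)
  i <- which(tens$pairs$chan_i == "Fz" & tens$pairs$chan_j == "Cz")
  j <- which(tens_swap$pairs$chan_i == "Cz" & tens_swap$pairs$chan_j == "Fz")
  expect_equal(tens_swap$values$plv[j, , ], tens$values$plv[i, , ], tolerance = 1e-12)
  expect_equal(tens_swap$values$wpli[j, , ], tens$values$wpli[i, , ], tolerance = 1e-12)
  # amplitude invariance
  rec_amp <- rec
  rec_amp$data[5, , ] <- 17 * rec_amp$data[5, , ]
  tens_amp <- windowed_connectivity(rec_amp)
  expect_equal(tens_amp$values$plv, tens$values$plv, tolerance = 1e-9)
  expect_equal(tens_amp$values$wpli, tens$values$wpli, tolerance = 1e-9)
})

test_that("a coupling confined to [1, 2) s elevates w3 but not w1", {
  set.seed(55)
  fs <- 100
  n <- 250
  n_tr <- 40
  a <- array(0, c(2, n_tr, n))
  late <- 151:250  # [1, 2) s with onset at 0.5 s
  for (tr in seq_len(n_tr)) {
    common <- phaseconn:::cx_band_oscillator(n, fs, c(3, 8))
    x <- Re(phaseconn:::cx_band_oscillator(n, fs, c(3, 8)))
    y <- Re(phaseconn:::cx_band_oscillator(n, fs, c(3, 8)))
    y[late] <- Re(common * exp(-1i * pi / 3))[late]
    x[late] <- Re(common)[late]
    a[1, tr, ] <- x; a[2, tr, ] <- y
  }
  rec <- epoched_recording(a, fs, c("C5", "CP3"), meta = list(edge = "periodic"))
  tens <- suppressWarnings(windowed_connectivity(rec, metrics = "plv"))
  m <- apply(tens$values$plv[1, , ], 1, mean)
  expect_gt(m[["w3"]], m[["w1"]] + 0.3)
  expect_gt(m[["w2"]], m[["w1"]] + 0.1)
})

test_that("the long-format view carries one row per cell with matching values", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 2, seed = 12)
  tens <- windowed_connectivity(bandpass_theta(generate_epochs(cfg, list(), "Pre", "L")))
  df <- as.data.frame(tens)
  expect_equal(nrow(df), 78 * 3 * 2 * 2)  # pairs x windows x trials x metrics
  row <- df[df$metric == "plv" & df$window == "w2" & df$trial == 2 &
              df$chan_i == "Fz" & df$chan_j == "Cz", ]
  i <- which(tens$pairs$chan_i == "Fz" & tens$pairs$chan_j == "Cz")
  expect_equal(row$value, unname(tens$values$plv[i, 2, 2]))
})
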