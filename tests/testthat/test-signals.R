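test_that("detrend removes constants and ramps exactly and matches a least-squares oracle", {
  expect_equal(detrend(make_series(rep(5, 4)))$values, rep(0, 4))
  t <- (0:999) / 2000
  ramp <- make_series(2 + 3 * t)
  expect_equal(detrend(ramp)$values, rep(0, 1000), tolerance = 1e-12)
  # ramp + full-period sine: sine survives, amplitude preserved
  n_per <- 10
  tt <- (0:(2000 * n_per / 10 - 1)) / 2000 # whole periods of a 10 Hz sine
  y <- 1 + 0.5 * tt + 0.3 * sin(2 * pi * 10 * tt)
  det <- detrend(make_series(y))$values
  oracle <- stats::lm.fit(cbind(1, seq_along(y)), y)$residuals
  expect_equal(det, unname(oracle), tolerance = 1e-12)
  # a finite record's least-squares line correlates slightly with the
  # sine; the amplitude distortion shrinks with the number of periods
  expect_equal(max(det), 0.3, tolerance = 0.1)
  expect_lt(abs(mean(det)), 1e-9)
  expect_error(uniform_series(5, 2000), "2 samples")
})

test_that("rectify is the elementwise absolute value and idempotent", {
  s <- make_series(c(-1, 2, -3, 4))
  expect_equal(rectify(s)$values, c(1, 2, 3, 4))
  expect_equal(rectify(rectify(s))$values, rectify(s)$values)
  nonneg <- make_series(c(0, 1, 2, 3))
  expect_identical(rectify(nonneg)$values, nonneg$values)
})

test_that("zero-phase Butterworth low-pass has unit DC gain and the analytic band behavior", {
  expect_lt(max(abs(lowpass(make_series(rep(3.7, 5000)))$values - 3.7)), 1e-6)
  t <- (0:9999) / 2000
  interior <- 3000:7000
  # 1 Hz at fc = 6 Hz: |H|^2 = 1/(1+(1/6)^8) ~ 1 within well under 2 %
  lo <- lowpass(make_series(sin(2 * pi * 1 * t)))$values
  expect_equal(max(abs(lo[interior])), 1, tolerance = 0.02)
  # 100 Hz: |H|^2 = 1/(1+(100/6)^8) < 1e-9
  hi <- lowpass(make_series(sin(2 * pi * 100 * t)))$values
  expect_lt(max(abs(hi[interior])), 1e-4)
  expect_error(lowpass(make_series(rnorm(100), fs = 10), cutoff = 6), "Nyquist")
})

test_that("low-pass filtering is linear", {
  withr_seed <- 42; set.seed(withr_seed)
  x <- make_series(rnorm(4000))
  y <- make_series(rnorm(4000))
  axby <- make_series(2.5 * x$values - 1.3 * y$values)
  lhs <- lowpass(axby)$values
  rhs <- 2.5 * lowpass(x)$values - 1.3 * lowpass(y)$values
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("emg_envelope self-normalizes over the baseline window and is scale invariant", {
  set.seed(7)
  s <- make_series(rnorm(6000))
  full <- c(0, (length(s$values) - 1) / s$sample_rate)
  env <- emg_envelope(s, baseline_window = full)
  expect_equal(mean(env$values), 1.0, tolerance = 1e-12)
  s2 <- make_series(13.7 * s$values)
  expect_equal(emg_envelope(s2, full)$values, env$values, tolerance = 1e-9)
  expect_error(emg_envelope(s, c(10, 20)), "window")
})

test_that("emg_envelope recovers a prescribed 2x plateau from a synthetic burst", {
  # carrier with constant rectified mean, amplitude 1 in the baseline
  # half and 2 in the burst half
  fs <- 2000
  t <- (0:(6 * fs - 1)) / fs
  mod <- ifelse(t < 3, 1, 2)
  x <- make_series(mod * sin(2 * pi * 80 * t))
  env <- emg_envelope(x, baseline_window = c(0.5, 2.5))
  plateau <- env$values[t > 3.5 & t < 5.5]
  expect_equal(mean(plateau), 2, tolerance = 0.05)
})

test_that("clip_resample is exact on linear data and keeps the rate bookkeeping", {
  t <- (0:1999) / 2000
  ramp <- make_series(1 + 4 * t)
  out <- clip_resample(ramp, window = c(0, t[2000]), duration = 0.25,
                       n_out = 250)
  expect_equal(out$sample_rate, 1000)
  expect_equal(out$values[1], 1)
  expect_equal(out$values[250], 1 + 4 * t[2000], tolerance = 1e-12)
  expect_lte(abs(series_duration(out) - 0.25), 1 / out$sample_rate + 1e-12)
  # linear interpolation error bound h^2 w^2 / 8 on a sine segment
  w <- 2 * pi * 40
  sine <- make_series(sin(w * t))
  res <- clip_resample(sine, window = c(0.1, 0.6), n_out = 250)
  src_t <- 0.1 + 0.5 * (0:249) / 249
  h <- 1 / 2000
  expect_lt(max(abs(res$values - sin(w * src_t))), h^2 * w^2 / 8 + 1e-12)
  # monotone segment: min/max preserved
  expect_equal(range(out$values), range(ramp$values))
  expect_error(clip_resample(ramp, window = c(0.5, 0.2)), "window")
})

test_that("ic_ratio reproduces trivial and prescribed ratios", {
  set.seed(3)
  base <- abs(rnorm(2000)) + 0.5
  a <- make_series(base)
  expect_equal(ic_ratio(a, a), 1.0)
  b <- make_series(3 * base)
  expect_equal(ic_ratio(b, a), 3.0, tolerance = 1e-12)
  # generator ground truth at the Class I left-bite temporalis value
  g <- gen_bite_recording(ic_temporalis = 1.52, ic_masseter = 1.43, seed = 11)
  pt <- process_recording(g$recording, g$truth$bite_window,
                          g$truth$baseline_window)
  expect_equal(pt$ic_temporalis, 1.52, tolerance = 0.05)
  expect_error(ic_ratio(a, make_series(rep(0, 2000))), "positive")
})

test_that("process_recording recovers prescribed ratios and plateau force", {
  g <- gen_bite_recording(plateau_N = 50, ic_temporalis = 1.5,
                          ic_masseter = 1.4, noise_sd = 0.05, seed = 2)
  pt <- process_recording(g$recording, g$truth$bite_window,
                          g$truth$baseline_window, g$truth$rest_window)
  expect_equal(pt$ic_temporalis, 1.5, tolerance = 0.05)
  expect_equal(pt$ic_masseter, 1.4, tolerance = 0.05)
  expect_equal(pt$final_bite_force, 50, tolerance = 50 * 0.02)
  expect_equal(pt$final_bite_force,
               pt$force_curve$values[length(pt$force_curve$values)])
  expect_lte(abs(series_duration(pt$force_curve) - 0.25),
             1 / pt$force_curve$sample_rate + 1e-12)
})

test_that("a noiseless constant-force recording keeps its absolute level", {
  fs <- 2000
  n <- 6 * fs
  flat <- uniform_series(rep(50, n), fs, units = "N")
  set.seed(5)
  emg <- lapply(1:4, function(i) uniform_series(rnorm(n), fs))
  names(emg) <- c("LT", "RT", "LM", "RM")
  rec <- bite_recording(flat, emg, task_side = "left")
  pt <- process_recording(rec, bite_window = c(2, 2.8),
                          baseline_window = c(0.5, 1.5))
  expect_equal(pt$final_bite_force, 50, tolerance = 1e-4)
})

test_that("swapping the task side inverts IC ratios to reciprocals", {
  g <- gen_bite_recording(ic_temporalis = 1.5, ic_masseter = 1.4, seed = 4)
  rec_sw <- g$recording
  rec_sw$task_side <- "right"
  pt_l <- process_recording(g$recording, g$truth$bite_window,
                            g$truth$baseline_window)
  pt_r <- process_recording(rec_sw, g$truth$bite_window,
                            g$truth$baseline_window)
  expect_equal(pt_r$ic_temporalis, 1 / pt_l$ic_temporalis, tolerance = 1e-9)
  expect_equal(pt_r$ic_masseter, 1 / pt_l$ic_masseter, tolerance = 1e-9)
})

test_that("IC ratios are invariant to a common rescaling of all EMG channels", {
  g <- gen_bite_recording(seed = 6, noise_sd = 0.02)
  rec2 <- g$recording
  for (ch in names(rec2$emg)) rec2$emg[[ch]]$values <- 7.3 * rec2$emg[[ch]]$values
  p1 <- process_recording(g$recording, g$truth$bite_window, g$truth$baseline_window)
  p2 <- process_recording(rec2, g$truth$bite_window, g$truth$baseline_window)
  expect_equal(p2$ic_temporalis, p1$ic_temporalis, tolerance = 1e-9)
  expect_equal(p2$ic_masseter, p1$ic_masseter, tolerance = 1e-9)
})
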