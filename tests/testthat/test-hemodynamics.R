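test_that("Beer-Lambert forward/inverse round trip is exact", {
  opt <- optics_config()
  hemo <- noise_hemo(n = 500L, p = 8L, seed = 2)
  od <- forward_optics(hemo, opt)
  back <- beer_lambert_invert(od, opt)
  expect_equal(back$hbo2, hemo$hbo2, tolerance = 1e-12)
  expect_equal(back$hb, hemo$hb, tolerance = 1e-12)
  # zero input maps to zero both ways
  z <- hemo_series(matrix(0, 10, 3), matrix(0, 10, 3), fs = 10)
  expect_true(all(forward_optics(z, opt)$data == 0))
  # linearity in path length
  opt2 <- optics_config(distance = 6)
  expect_equal(forward_optics(hemo, opt2)$data, 2 * od$data)
})

test_that("diagonal extinction matrix decouples the chromophores", {
  opt <- optics_config(ext_hb = c(2, 0), ext_hbo2 = c(0, 1),
                       dpf = c(5, 5), distance = 3)
  hemo <- noise_hemo(n = 100L, p = 2L, seed = 3)
  od <- forward_optics(hemo, opt)
  expect_equal(od$data[, , 1L], 2 * 5 * 3 * hemo$hb)
  expect_equal(od$data[, , 2L], 1 * 5 * 3 * hemo$hbo2)
  back <- beer_lambert_invert(od, opt)
  expect_equal(back$hb, od$data[, , 1L] / (2 * 5 * 3))
})

test_that("singular or ill-conditioned optics are rejected", {
  expect_error(optics_config(ext_hb = c(1, 2), ext_hbo2 = c(2, 4)),
               "singular|ill-conditioned")
})

test_that("CAR removes common series, is idempotent, fixes zero-mean input", {
  hemo <- noise_hemo(n = 400L, p = 6L, seed = 4)
  common <- sin(seq_len(400) / 7)
  bumped <- hemo_series(hemo$hbo2 + common, hemo$hb + 2 * common, fs = 10)
  expect_equal(car_filter(bumped)$hbo2, car_filter(hemo)$hbo2)
  expect_equal(unname(rowMeans(car_filter(hemo)$hbo2)), rep(0, 400))
  expect_equal(car_filter(car_filter(hemo))$hbo2, car_filter(hemo)$hbo2)
  # identical channels cancel entirely
  same <- hemo_series(matrix(common, 400, 5), matrix(common, 400, 5), fs = 10)
  expect_true(all(abs(car_filter(same)$hbo2) < 1e-14))
  # {x, -x} is already zero-mean: a fixed point
  anti <- hemo_series(cbind(common, -common), cbind(common, -common), fs = 10)
  expect_equal(car_filter(anti)$hbo2, anti$hbo2, ignore_attr = TRUE)
  one <- hemo_series(matrix(common), matrix(common), fs = 10)
  expect_error(car_filter(one), "single channel")
})

test_that("band-pass keeps in-band tones and rejects out-of-band content", {
  fs <- 10; t <- seq(0, 180 - 1 / fs, by = 1 / fs)
  tone <- function(f) sin(2 * pi * f * t)
  mk <- function(x) hemo_series(matrix(x, ncol = 1), matrix(x, ncol = 1), fs)
  amp <- function(h) stats::sd(h$hbo2[200:1600, 1]) * sqrt(2)
  # 0.05 Hz passband tone preserved within 10%
  expect_equal(amp(bandpass_filter(mk(tone(0.05)))), 1, tolerance = 0.1)
  # 1.1 Hz cardiac tone: residual < 10% of input
  expect_lt(amp(bandpass_filter(mk(tone(1.1)))), 0.1)
  # constant (DC) removed
  dc <- bandpass_filter(mk(rep(2, length(t))))
  expect_lt(max(abs(dc$hbo2)), 0.05)
  # linear drift attenuated by >= 20 dB
  drift <- 0.01 * t
  filt <- bandpass_filter(mk(drift))
  expect_lt(stats::sd(filt$hbo2), stats::sd(drift) / 10)
  expect_error(bandpass_filter(mk(tone(0.05)), low = 0.1, high = 6),
               "band edges")
})

test_that("band-pass is linear and zero-phase", {
  fs <- 10; t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x1 <- sin(2 * pi * 0.04 * t); x2 <- sin(2 * pi * 0.07 * t + 1)
  mk <- function(x) hemo_series(matrix(x, ncol = 1), matrix(x, ncol = 1), fs)
  f <- function(x) bandpass_filter(mk(x))$hbo2
  # exact in theory; IIR recursion round-off leaves ~1e-6 relative residue
  expect_equal(f(x1 + 2 * x2), f(x1) + 2 * f(x2), tolerance = 1e-4)
  # zero phase: in-band tone keeps its phase (max cross-correlation at lag 0)
  y <- f(x1)[, 1]
  ccf_vals <- stats::ccf(y[300:900], x1[300:900], lag.max = 10, plot = FALSE)
  expect_equal(which.max(ccf_vals$acf), 11L)   # lag 0 of -10..10
})

test_that("trimming and window selection honour length, strategy, and mask", {
  fs <- 10
  hemo <- noise_hemo(n = 3600L, p = 4L, fs = fs, seed = 6)
  w <- trim_and_window(hemo, trim = 3, window = 180)
  expect_equal(nrow(w$hbo2), 1800L)
  wf <- trim_and_window(hemo, trim = 3, window = 180, strategy = "fixed_start")
  expect_equal(attr(wf, "window_start"), 31L)
  # stationary-ish input: fixed_start equals the first candidate
  # burst in the first half is avoided by min_variance
  burst <- hemo
  burst$hbo2[500:700, ] <- burst$hbo2[500:700, ] * 25
  wb <- trim_and_window(burst, trim = 3, window = 180)
  s <- attr(wb, "window_start")
  expect_true(s > 700L)
  # exhaustive-scan oracle: no other admissible window has lower cost
  starts <- seq(31L, 3600L - 30L - 1800L + 1L, by = 10L)
  costs <- vapply(starts, function(st)
    sum(apply(burst$hbo2[st:(st + 1799L), ], 2, stats::var)), numeric(1))
  expect_equal(s, starts[which.min(costs)])
  # exclusion mask removes flagged windows
  mask <- rep(FALSE, 3600L); mask[2000:2100] <- TRUE
  wm <- trim_and_window(hemo, trim = 3, window = 180, exclude = mask)
  sm <- attr(wm, "window_start")
  expect_true(sm + 1799L < 2000L || sm > 2100L)
  expect_error(trim_and_window(hemo, trim = 3, window = 400), "too short")
})

test_that("preprocessing recovers the connectivity pattern better than none", {
  # With nuisance on, full preprocessing must recover the model's
  # connectivity pattern better than windowing alone. The comparison is on
  # pattern correlation with the model's pairwise values, not absolute
  # error: CAR is a projection that compresses correlation levels by
  # construction, and every downstream step (proportional thresholding)
  # consumes the ranking, not the scale.
  spec <- cohort_spec(seed = 30)   # study-scale: 22 channels, 360 s
  fid <- sapply(1:30, function(i) {
    net <- generate_topology(spec$n_channels, spec$topology_a, seed = 500 + i)
    s <- simulate_subject(net, spec, seed = 700 + i)
    sigma <- s$model_sigma
    full <- preprocess_subject(s$optical, spec$optics)
    raw <- trim_and_window(beer_lambert_invert(s$optical, spec$optics))
    off <- upper.tri(sigma)
    c(full = stats::cor(stats::cor(full$hbo2)[off], sigma[off]),
      raw = stats::cor(stats::cor(raw$hbo2)[off], sigma[off]))
  })
  expect_gt(mean(fid["full", ]) - mean(fid["raw", ]), 0.05)
  expect_gte(sum(fid["full", ] > fid["raw", ]), 21)   # sign test at 5%
})
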