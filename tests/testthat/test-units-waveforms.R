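test_that("mmHg conversion is exact, invertible and matches the preload scale", {
  expect_identical(mmhg_to_canonical(0), 0)
  expect_equal(mmhg_to_canonical(120), 15998.4)
  # the packaged atrial preload of 533.320 g/(mm s^2) is 4 mmHg
  expect_equal(mmhg_to_canonical(4), 533.320, tolerance = 1e-3)
  expect_equal(canonical_to_mmhg(533.320), 4, tolerance = 1e-3)
  for (p in c(1e-6, 0.3, 71, 159, 1e4))
    expect_equal(canonical_to_mmhg(mmhg_to_canonical(p)), p,
                 tolerance = 1e-12)
  expect_equal(canonical_to_joule(1e9), 1)
  expect_equal(ml_per_s_to_canonical(51.4), 51400)
})

test_that("waveform construction enforces its contract", {
  expect_error(waveform(0, 1), "at least 2 samples")
  expect_error(waveform(c(0, 0.1, 0.05), c(1, 2, 3)),
               "strictly increasing.*row 3")
  expect_error(waveform(c(0.1, 0.2), c(1, 2)), "start at 0")
  expect_error(waveform(c(0, 0.5), c(1, NA)), "NA")
  expect_error(waveform(c(0, 2), c(1, 1), period = 1.3), "exceeds the period")
})

test_that("waveform mean integrates the periodic extension", {
  w <- constant_waveform(5)
  expect_equal(waveform_mean(w), 5)
  # synthetic inflow: mean = stroke volume / period
  expect_equal(waveform_mean(default_inflow()), 94000 / 1.3,
               tolerance = 1e-12)
  # 94 mL at 47 beats/min is a cardiac output of 4.4 L/min
  w47 <- generate_inflow(period = 60 / 47)
  co_l_min <- waveform_mean(w47) * 60 / 1e6
  expect_equal(round(co_l_min, 1), 4.4)
})

test_that("waveform metrics report peak, min and pulse", {
  p <- waveform(seq(0, 1.275, by = 0.025),
                mmhg_to_canonical(115 + 44 * sin(2 * pi * seq(0, 1.275, 0.025) / 1.3)),
                period = 1.3)
  m <- waveform_metrics(p)
  expect_equal(canonical_to_mmhg(m$pulse), 88, tolerance = 0.01)
  expect_equal(waveform_metrics(constant_waveform(3))$pulse, 0)
  # sinusoid: pulse equals twice the amplitude
  tt <- seq(0, 0.99, by = 0.01)
  s <- waveform(tt, 7 + 2 * sin(2 * pi * tt), period = 1)
  expect_equal(waveform_metrics(s)$pulse, 4, tolerance = 1e-3)
})

test_that("waveform evaluation is periodic and piecewise linear", {
  w <- default_inflow()
  t <- seq(-2, 3, by = 0.173)
  expect_equal(waveform_eval(w, t), waveform_eval(w, t + w$period))
  expect_equal(waveform_eval(w, t), waveform_eval(w, t - 5 * w$period))
  # midpoint of a linear segment is the mean of its endpoints
  mid <- (w$times[3] + w$times[4]) / 2
  expect_equal(waveform_eval(w, mid), (w$values[3] + w$values[4]) / 2)
})

test_that("resampling preserves the mean of band-limited signals", {
  tt <- seq(0, 1.275, by = 0.025)
  w <- waveform(tt, 10 + 3 * sin(2 * pi * tt / 1.3) + cos(4 * pi * tt / 1.3),
                period = 1.3)
  w10 <- waveform_resample(w, 10L * length(tt))
  expect_equal(waveform_mean(w10), waveform_mean(w), tolerance = 5e-3)
})

test_that("waveform CSV round-trips and rejects malformed files", {
  w <- default_inflow()
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  w2 <- read_waveform_csv(path)
  expect_identical(w2$values, w$values)
  expect_identical(w2$times, w$times)
  expect_equal(w2$period, w$period)
  # 25 gated phases over 1.3 s: 52 ms spacing
  expect_equal(unique(round(diff(w2$times), 10)), 0.052)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0,1", "0.2,2", "0.1,3"), bad)
  expect_error(read_waveform_csv(bad), "non-increasing.*row 3")
  writeLines(c("time_s,value", "0,1", "0.1,NA"), bad)
  expect_error(read_waveform_csv(bad), "NA.*row 2")
  writeLines(character(0), bad)
  expect_error(read_waveform_csv(bad), "empty")
})

test_that("waveform CSV honours unit comments", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# period=1.3", "# units=mmHg", "time_s,value",
               "0,80", "0.5,120", "1.0,90"), path)
  w <- read_waveform_csv(path)
  expect_equal(w$values, mmhg_to_canonical(c(80, 120, 90)))
  expect_equal(w$period, 1.3)
})
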