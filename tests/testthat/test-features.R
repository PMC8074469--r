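test_that("signal RMS matches closed forms", {
  expect_equal(signal_rms(rep(-2.5, 10)), 2.5)
  expect_equal(signal_rms(c(3, -3, 3, -3)), 3)
  t <- (0:999) / 100
  expect_equal(signal_rms(sin(2 * pi * 10 * t)), 1 / sqrt(2),
               tolerance = 1e-3)
  expect_error(signal_rms(numeric(0)), "empty")
})

test_that("signal period recovers sinusoid periods from mean crossings", {
  t <- (0:999) / 100
  expect_equal(signal_period(sin(2 * pi * 10 * t), 100), 0.1,
               tolerance = 0.01)
  expect_equal(signal_period(sin(2 * pi * 8 * t), 100), 0.125,
               tolerance = 0.01)
  expect_true(is.na(signal_period(rep(1, 100), 100)))
})

test_that("wavelet-packet spectrum localizes tones and conserves energy", {
  t <- (0:3199) / 100
  x <- sin(2 * pi * 9 * t)
  sp <- wavelet_spectrum(x, 100)
  expect_equal(nrow(sp), 32)
  expect_true(all(diff(sp$center) > 0))
  expect_true(all(sp$energy >= 0))
  # the maximal-energy band contains 9 Hz
  bw <- sp$center[2] - sp$center[1]
  top <- sp$center[which.max(sp$energy)]
  expect_true(abs(top - 9) <= bw / 2)
  expect_true(dominant_frequency(sp) >= 8 && dominant_frequency(sp) <= 10)
  # Parseval on the analysed window
  expect_equal(sum(sp$energy), sum(x[seq_len(attr(sp, "n_used"))]^2),
               tolerance = 0.01)
  # amplitude homogeneity
  expect_equal(dominant_magnitude(wavelet_spectrum(3 * x, 100)),
               3 * dominant_magnitude(sp), tolerance = 1e-9)
  # stronger of two tones wins
  x2 <- 2 * sin(2 * pi * 8 * t) + sin(2 * pi * 11 * t)
  sp2 <- wavelet_spectrum(x2, 100)
  top2 <- sp2$center[which.max(sp2$energy)]
  expect_true(abs(top2 - 8) <= bw / 2)

  expect_error(wavelet_spectrum(rnorm(20), 100), "need >= 32")
})

test_that("white noise spreads energy across wavelet bands", {
  worst <- vapply(1:20, function(s) {
    set.seed(s)
    sp <- wavelet_spectrum(rnorm(2048), 100)
    max(sp$energy) / mean(sp$energy)
  }, numeric(1))
  expect_lt(mean(worst), 3)
})

test_that("power growth equals the OLS slope of windowed power", {
  rate <- 100
  t <- (0:1499) / rate
  x <- (0.2 + 0.5 * t / max(t)) * sin(2 * pi * 9 * t)

  # independent brute-force OLS oracle on the same window/power pairs
  wlen <- 100L; step <- 50L
  starts <- seq(1L, length(x) - wlen + 1L, by = step)
  p <- vapply(starts, function(s) mean(x[s:(s + wlen - 1)]^2), numeric(1))
  tm <- (starts - 1 + (wlen - 1) / 2) / rate
  oracle <- unname(coef(lm(p ~ tm))[2])
  expect_equal(power_growth(x, rate), oracle, tolerance = 1e-9)
  expect_gt(power_growth(x, rate), 0)

  xs <- sin(2 * pi * 9 * t)
  expect_lt(abs(power_growth(xs, rate)), 0.01 * mean(xs^2))
  expect_true(is.na(power_growth(rnorm(50), rate)))
})

test_that("stationary features are time-reversal invariant, power growth negates", {
  set.seed(3)
  t <- (0:999) / 100
  x <- sin(2 * pi * 9 * t) + 0.1 * rnorm(1000)
  xr <- rev(x)
  expect_equal(signal_rms(x), signal_rms(xr))
  expect_equal(signal_period(x, 100), signal_period(xr, 100),
               tolerance = 0.02)
  expect_equal(dominant_frequency(wavelet_spectrum(x, 100)),
               dominant_frequency(wavelet_spectrum(xr, 100)))
  expect_equal(power_growth(xr, 100), -power_growth(x, 100),
               tolerance = 1e-9)
})

test_that("a complete patient yields 50 deterministic, ordered features", {
  cfg <- quick_cfg()
  set.seed(5)
  recs <- list()
  for (test in c("rest", "postural1", "postural2", "glass", "finger_nose"))
    for (hand in c("left", "right"))
      recs[[paste(test, hand)]] <-
        preprocess_recording(gen_recording(0.6, test, hand, cfg))
  fv <- extract_features(recs)
  expect_length(fv, 50)
  expect_true(all(is.finite(fv)))
  # deterministic key order, and bit-identical on re-extraction
  expect_identical(fv, extract_features(recs))
  expect_match(names(fv)[1], "^rest\\.left\\.")
  # the reference-model variables are reachable under the default policy
  expect_true(all(c("postural1.left.rot_speed.signal_rms",
                    "postural2.right.rot_speed.dominant_magnitude",
                    "postural1.left.rot_speed.power_growth",
                    "postural2.left.accel.dominant_frequency")
                  %in% names(fv)))

  # both-sensor policy doubles the candidate count
  expect_length(extract_features(recs, sensor_policy = "both"), 100)
})

test_that("missing tests produce flagged entries and duplicates are rejected", {
  cfg <- quick_cfg()
  set.seed(6)
  recs <- list()
  for (test in c("rest", "postural1", "postural2", "glass"))
    for (hand in c("left", "right"))
      recs[[paste(test, hand)]] <-
        preprocess_recording(gen_recording(0.4, test, hand, cfg))
  fv <- extract_features(recs)
  expect_length(fv, 50)
  expect_equal(sum(is.na(fv)), 10)
  expect_true(all(grepl("^finger_nose", names(fv)[is.na(fv)])))

  expect_error(extract_features(c(recs, recs["rest left"])), "duplicate")
  expect_error(extract_features(list()), "empty")
})
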