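#' Configuration for the synthetic tremor cohort generator
#'
#' The defaults emulate the clinical study conditions the pipeline targets:
#' one-minute recordings at 100 Hz, tremor oscillation in the 7-12 Hz
#' Essential-Tremor band with amplitude tied (linearly, by default) to a
#' latent severity in \[0, 1\], broadband sensor noise, screen-tap bursts in
#' the first and last 50 samples, a constant gravity component on the
#' accelerometer, and large slow voluntary-movement excursions (below 1.5 Hz,
#' three per recording, mirroring a thrice-repeated protocol) in the glass and
#' finger-nose tests.
#'
#' @param n_patients Cohort size (default 20).
#' @param tremor_band Tremor frequency interval in Hz (default `c(7, 12)`).
#' @param amplitude_map Monotone function from latent severity in \[0, 1\] to
#'   tremor acceleration amplitude in g.
#' @param movement_amplitude Amplitude (g) of the voluntary-movement term in
#'   the glass/finger-nose tests.
#' @param tap_burst_len Length in samples of the tap-artifact bursts.
#' @param tap_burst_sd Standard deviation (g) of the burst noise.
#' @param noise_sd Broadband noise standard deviation (g).
#' @param duration Recording length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param rot_scale Rotation-speed amplitude per unit acceleration amplitude.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 20L, tremor_band = c(7, 12),
                             amplitude_map = function(s) 0.01 + 0.25 * s,
                             movement_amplitude = 0.5, tap_burst_len = 50L,
                             tap_burst_sd = 0.3, noise_sd = 0.01,
                             duration = 60, sample_rate = 100,
                             rot_scale = 3, seed = 1L) {
  stopifnot(tremor_band[1] > 0, tremor_band[2] < sample_rate / 2,
            tremor_band[1] < tremor_band[2], duration > 0, sample_rate > 0,
            is.function(amplitude_map))
  structure(list(n_patients = as.integer(n_patients),
                 tremor_band = tremor_band, amplitude_map = amplitude_map,
                 movement_amplitude = movement_amplitude,
                 tap_burst_len = as.integer(tap_burst_len),
                 tap_burst_sd = tap_burst_sd, noise_sd = noise_sd,
                 duration = duration, sample_rate = sample_rate,
                 rot_scale = rot_scale, seed = as.integer(seed)),
            class = "generator_config")
}

# raised-cosine bumps: slow (< 1.5 Hz) voluntary-movement excursions
.movement_term <- function(time, amplitude, n_bumps = 3L) {
  span <- diff(range(time))
  width <- min(2, span / (n_bumps + 1))       # 2 s bumps: energy below 1 Hz
  centers <- min(time) + span * (seq_len(n_bumps) - 0.5) / n_bumps
  out <- numeric(length(time))
  for (ct in centers) {
    inside <- abs(time - ct) < width / 2
    out[inside] <- out[inside] +
      amplitude * 0.5 * (1 + cos(2 * pi * (time[inside] - ct) / width))
  }
  out
}

#' Generate one synthetic tremor recording
#'
#' @param severity Latent severity in \[0, 1\].
#' @param test,hand Recording slot (see [recording()]).
#' @param cfg A [generator_config()].
#' @param patient_id Patient identifier.
#' @param tap_bursts Set `FALSE` to omit the edge bursts (used to verify they
#'   stay confined to the edges).
#' @return A [recording()].
#' @export
gen_recording <- function(severity, test, hand, cfg = generator_config(),
                          patient_id = "p1", tap_bursts = TRUE) {
  test <- match.arg(test, TESTS)
  hand <- match.arg(hand, HANDS)
  stopifnot(inherits(cfg, "generator_config"))
  n <- round(cfg$duration * cfg$sample_rate)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  f <- stats::runif(1, cfg$tremor_band[1], cfg$tremor_band[2])
  amp <- cfg$amplitude_map(severity)
  w <- abs(stats::rnorm(3)); w <- w / sqrt(sum(w^2))   # axis distribution
  gravity <- c(0.05, -0.05, 1)                          # phone roughly flat
  mk <- function(scale) {
    m <- vapply(1:3, function(ax)
      scale * amp * w[ax] * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n, sd = scale * cfg$noise_sd), numeric(n))
    m
  }
  accel <- mk(1)
  accel <- sweep(accel, 2, gravity, "+")
  rot <- mk(cfg$rot_scale)
  if (test %in% c("glass", "finger_nose")) {
    mv <- .movement_term(t, cfg$movement_amplitude)
    for (ax in 1:3) accel[, ax] <- accel[, ax] + mv * w[ax]
    for (ax in 1:3) rot[, ax] <- rot[, ax] + cfg$rot_scale * mv * w[ax]
  }
  if (tap_bursts && cfg$tap_burst_len > 0 && n > 2 * cfg$tap_burst_len) {
    edge <- c(seq_len(cfg$tap_burst_len),
              (n - cfg$tap_burst_len + 1L):n)
    accel[edge, ] <- accel[edge, ] +
      matrix(stats::rnorm(length(edge) * 3, sd = cfg$tap_burst_sd),
             ncol = 3)
    rot[edge, ] <- rot[edge, ] +
      matrix(stats::rnorm(length(edge) * 3, sd = cfg$rot_scale * cfg$tap_burst_sd),
             ncol = 3)
  }
  recording(patient_id, test, hand, t, accel, rot,
            sample_rate = cfg$sample_rate)
}

#' Generate a synthetic cohort of recordings with severity scores
#'
#' Draws one latent severity per patient and produces all five tests for both
#' hands (optionally dropping the finger-nose test for the first
#' `missing_fingernose` patients, emulating a protocol extended mid-study).
#' ETRS- and QUEST-scale scores are two noisy monotone transforms of the same
#' latent severity, so the two targets share structure the way clinical scores
#' do.
#'
#' @param cfg A [generator_config()].
#' @param missing_fingernose Number of leading patients lacking the
#'   finger-nose test (default 0).
#' @param dir Optional directory: when given, recordings are written as CSV
#'   files `<patient>_<test>_<hand>.csv` plus `cohort.csv` and `manifest.csv`.
#' @return List with `recordings` (named list per patient), `cohort` (data
#'   frame `patient_id`, `etrs`, `quest`, `severity`), and `dir`.
#' @export
gen_cohort <- function(cfg = generator_config(), missing_fingernose = 0L,
                       dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    ids <- sprintf("p%02d", seq_len(cfg$n_patients))
    sev <- stats::runif(cfg$n_patients)
    etrs <- pmax(0, round(10 + 58 * sev + stats::rnorm(cfg$n_patients, 0, 2)))
    quest <- pmax(0, 3 + 65 * sev + stats::rnorm(cfg$n_patients, 0, 3))
    recordings <- lapply(seq_along(ids), function(i) {
      recs <- list()
      for (test in TESTS) {
        if (test == "finger_nose" && i <= missing_fingernose) next
        for (hand in HANDS)
          recs[[paste(test, hand)]] <-
            gen_recording(sev[i], test, hand, cfg, patient_id = ids[i])
      }
      recs
    })
    names(recordings) <- ids
    cohort <- data.frame(patient_id = ids, etrs = etrs, quest = quest,
                         severity = sev)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- NULL
    for (pid in names(recordings)) for (rec in recordings[[pid]]) {
      fn <- sprintf("%s_%s_%s.csv", pid, rec$test, rec$hand)
      write_recording(rec, file.path(dir, fn))
      manifest <- rbind(manifest,
                        data.frame(file = fn, patient_id = pid,
                                   test = rec$test, hand = rec$hand))
    }
    utils::write.csv(cohort[c("patient_id", "etrs", "quest")],
                     file.path(dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recordings, cohort = cohort, dir = dir)
}

#' Sample a feature-space dataset from a known Takagi-Sugeno model
#'
#' Parameter-recovery harness: inputs uniform on the unit hypercube, targets
#' equal to the model's inference output plus Gaussian noise.
#'
#' @param truth A [ts_model()].
#' @param n Number of rows.
#' @param noise_sd Target noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with the model's input variables and a column named
#'   after the model's target; the generating model is attached as attribute
#'   `"truth"`.
#' @export
gen_ts_dataset <- function(truth, n, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "ts_model"), n >= 1L)
  withr::with_seed(seed, {
    X <- matrix(stats::runif(n * length(truth$variables)), nrow = n,
                dimnames = list(NULL, truth$variables))
    y <- infer(truth, X) + stats::rnorm(n, sd = noise_sd)
  })
  out <- as.data.frame(X)
  out[[truth$target]] <- y
  attr(out, "truth") <- truth
  out
}
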