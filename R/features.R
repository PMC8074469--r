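FEATURES <- c("signal_rms", "signal_period", "dominant_frequency",
              "dominant_magnitude", "power_growth")

# Daubechies-8 (16-tap) orthonormal decomposition filters, standard published
# coefficients; the high-pass is the quadrature mirror of the low-pass.
DB8_LO <- c(-0.00011747678412476953, 0.0006754494064505693,
            -0.00039174037337694705, -0.004870352993451574,
            0.008746094047405777, 0.013981027917398282,
            -0.044088253930794755, -0.017369301001807547,
            0.12874742662047847, 0.0004724845739132828,
            -0.2840155429615469, -0.015829105256349306,
            0.5853546836542067, 0.6756307362972898,
            0.31287159091429995, 0.05441584224310401)
DB8_HI <- rev(DB8_LO) * rep_len(c(-1, 1), length(DB8_LO))

# one analysis step: circular correlation with the filter, decimated by two
.wp_step <- function(x, h) {
  n <- length(x)
  idx <- (outer(seq.int(0L, n - 2L, by = 2L), seq_along(h) - 1L, "+") %% n) + 1L
  drop(matrix(x[idx], ncol = length(h)) %*% h)
}

#' Root-mean-square of a signal
#'
#' @param signal Non-empty numeric vector.
#' @return `sqrt(mean(signal^2))`.
#' @export
signal_rms <- function(signal) {
  if (!length(signal)) stop("empty signal", call. = FALSE)
  sqrt(mean(signal^2))
}

#' Average oscillation period of a signal
#'
#' The mean time between successive upward crossings of the signal mean: a
#' robust estimate of "the average duration of one wave". Signals with fewer
#' than two upward mean-crossings (e.g. constants) have no defined period and
#' yield `NA`, which downstream imputation treats as missing.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate in Hz.
#' @return Period in seconds, or `NA_real_`.
#' @export
signal_period <- function(signal, rate) {
  stopifnot(rate > 0)
  if (length(signal) < 3L) return(NA_real_)
  centered <- signal - mean(signal)
  up <- which(centered[-length(centered)] < 0 & centered[-1] >= 0)
  if (length(up) < 2L) return(NA_real_)
  mean(diff(up)) / rate
}

#' Daubechies-8 wavelet-packet spectrum
#'
#' Full wavelet-packet decomposition with the db8 filter pair to the given
#' depth, with the terminal nodes rearranged into frequency (sequency) order.
#' Each of the `2^depth` uniform bands reports its ideal center frequency, the
#' total coefficient energy, and the peak absolute coefficient. The transform
#' is orthonormal on the analysed window, so band energies sum to the signal
#' energy (Parseval). Signals are truncated to the largest multiple of
#' `2^depth` samples.
#'
#' @param signal Numeric vector, length at least `2^depth`.
#' @param rate Sampling rate in Hz.
#' @param depth Decomposition depth (default 5: 1.5625 Hz bands at 100 Hz).
#' @return Object of class `wavelet_spectrum`: a data frame with columns
#'   `center`, `energy`, `peak`.
#' @export
wavelet_spectrum <- function(signal, rate, depth = 5L) {
  stopifnot(rate > 0, depth >= 1L)
  block <- 2L^depth
  if (length(signal) < block)
    stop(sprintf("signal too short for depth %d: need >= %d samples", depth,
                 block), call. = FALSE)
  n_use <- (length(signal) %/% block) * block
  x <- signal[seq_len(n_use)]
  # nodes as (frequency-order index, coefficients); split level by level
  nodes <- list(list(f = 0L, coef = x))
  for (d in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      lo <- .wp_step(nd$coef, DB8_LO)
      hi <- .wp_step(nd$coef, DB8_HI)
      # sequency ordering: decimation mirrors the spectrum of odd-index bands
      if (nd$f %% 2L == 0L) {
        nxt[[2L * i - 1L]] <- list(f = 2L * nd$f,      coef = lo)
        nxt[[2L * i]]      <- list(f = 2L * nd$f + 1L, coef = hi)
      } else {
        nxt[[2L * i - 1L]] <- list(f = 2L * nd$f + 1L, coef = lo)
        nxt[[2L * i]]      <- list(f = 2L * nd$f,      coef = hi)
      }
    }
    nodes <- nxt
  }
  ord <- order(vapply(nodes, `[[`, integer(1), "f"))
  nodes <- nodes[ord]
  bw <- rate / 2 / length(nodes)
  out <- data.frame(
    center = (seq_along(nodes) - 0.5) * bw,
    energy = vapply(nodes, function(nd) sum(nd$coef^2), numeric(1)),
    peak = vapply(nodes, function(nd) max(abs(nd$coef)), numeric(1)))
  attr(out, "rate") <- rate
  attr(out, "depth") <- depth
  attr(out, "n_used") <- n_use
  class(out) <- c("wavelet_spectrum", "data.frame")
  out
}

#' Dominant frequency and magnitude of a wavelet spectrum
#'
#' The center frequency of the maximal-energy band, and the peak coefficient
#' magnitude within that band. An all-zero spectrum has no dominant band and
#' yields `NA`.
#'
#' @param spec A [wavelet_spectrum()].
#' @return A frequency in Hz / a magnitude in signal units.
#' @export
dominant_frequency <- function(spec) {
  stopifnot(inherits(spec, "wavelet_spectrum"), nrow(spec) >= 1L)
  if (all(spec$energy <= 0)) return(NA_real_)
  spec$center[which.max(spec$energy)]
}

#' @rdname dominant_frequency
#' @export
dominant_magnitude <- function(spec) {
  stopifnot(inherits(spec, "wavelet_spectrum"), nrow(spec) >= 1L)
  if (all(spec$energy <= 0)) return(NA_real_)
  spec$peak[which.max(spec$energy)]
}

#' Power growth of a signal
#'
#' Mean power is computed in sliding windows and regressed (ordinary least
#' squares) on the window mid-times; the slope captures tremor
#' intensification over the course of a recording. Fewer than two windows
#' yield `NA`.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param window Window length in seconds (default 1).
#' @param overlap Fractional window overlap in \[0, 1) (default 0.5).
#' @return Slope in signal-units^2 per second, or `NA_real_`.
#' @export
power_growth <- function(signal, rate, window = 1.0, overlap = 0.5) {
  stopifnot(rate > 0, window > 0, overlap >= 0, overlap < 1)
  wlen <- max(2L, round(window * rate))
  step <- max(1L, round(wlen * (1 - overlap)))
  if (length(signal) < wlen + step) return(NA_real_)
  starts <- seq.int(1L, length(signal) - wlen + 1L, by = step)
  p <- vapply(starts, function(s) mean(signal[s:(s + wlen - 1L)]^2),
              numeric(1))
  t_mid <- (starts - 1 + (wlen - 1) / 2) / rate
  tc <- t_mid - mean(t_mid)
  sum(tc * (p - mean(p))) / sum(tc^2)
}

# default sensor policy: one sensor per (test, feature); accelerometer
# everywhere except the rotation-speed picks used by the reference severity
# models (postural1 signal RMS / power growth, postural2 dominant magnitude)
.primary_sensor <- function(test, feature) {
  if (test == "postural1" && feature %in% c("signal_rms", "power_growth"))
    return("rot_speed")
  if (test == "postural2" && feature == "dominant_magnitude")
    return("rot_speed")
  "accel"
}

feature_key <- function(test, hand, sensor, feature) {
  paste(test, hand, sensor, feature, sep = ".")
}

.signal_features <- function(sig, rate, depth, window, overlap) {
  sp <- tryCatch(wavelet_spectrum(sig, rate, depth), error = function(e) NULL)
  c(signal_rms = signal_rms(sig),
    signal_period = signal_period(sig, rate),
    dominant_frequency = if (is.null(sp)) NA_real_ else dominant_frequency(sp),
    dominant_magnitude = if (is.null(sp)) NA_real_ else dominant_magnitude(sp),
    power_growth = power_growth(sig, rate, window, overlap))
}

#' Extract the per-patient feature vector
#'
#' Reduces a patient's (preprocessed) recordings to named scalar features:
#' for each test and hand, the five features `signal_rms`, `signal_period`,
#' `dominant_frequency`, `dominant_magnitude`, `power_growth`, computed on the
#' orientation-invariant magnitude signal of the policy-selected sensor. The
#' default `per_test_primary` policy picks one sensor per (test, feature) and
#' yields exactly 50 features (2 hands x 5 tests x 5 features); `"both"`
#' computes every feature for both sensors (100 candidates). Missing
#' recordings produce `NA` entries for later imputation.
#'
#' @param recordings List of [recording()]s of one patient, already trimmed
#'   and filtered (see [preprocess_recording()]).
#' @param sensor_policy `"per_test_primary"` or `"both"`.
#' @param signal Scalar signal the features are computed on:
#'   `"principal"` (default, [principal_signal()]; linear, preserves the
#'   tremor frequency) or `"magnitude"` ([vector_magnitude()]).
#' @param depth Wavelet-packet depth passed to [wavelet_spectrum()].
#' @param window,overlap Power-growth window settings.
#' @return Named numeric vector with attribute `patient_id`; key format
#'   `test.hand.sensor.feature`.
#' @export
extract_features <- function(recordings,
                             sensor_policy = c("per_test_primary", "both"),
                             signal = c("principal", "magnitude"),
                             depth = 5L, window = 1.0, overlap = 0.5) {
  sensor_policy <- match.arg(sensor_policy)
  signal <- match.arg(signal)
  scalar_signal <- if (signal == "principal") principal_signal
                   else vector_magnitude
  if (!length(recordings)) stop("empty recording set", call. = FALSE)
  stopifnot(all(vapply(recordings, inherits, logical(1), "tremor_recording")))
  pid <- unique(vapply(recordings, `[[`, character(1), "patient_id"))
  if (length(pid) != 1L)
    stop("recordings belong to more than one patient", call. = FALSE)
  slot <- vapply(recordings, function(r) paste(r$test, r$hand), character(1))
  if (anyDuplicated(slot))
    stop("duplicate (test, hand) recording: ", slot[duplicated(slot)][1],
         call. = FALSE)
  by_slot <- stats::setNames(recordings, slot)

  out <- numeric(0)
  for (test in TESTS) for (hand in HANDS) {
    rec <- by_slot[[paste(test, hand)]]
    # all five features per sensor in one pass over the scalar signal
    feats <- if (is.null(rec)) NULL else
      lapply(stats::setNames(nm = c("accel", "rot_speed")), function(sensor)
        .signal_features(scalar_signal(rec, sensor), rec$sample_rate, depth,
                         window, overlap))
    for (feature in FEATURES) {
      sensors <- if (sensor_policy == "both") c("accel", "rot_speed")
                 else .primary_sensor(test, feature)
      for (sensor in sensors) {
        key <- feature_key(test, hand, sensor, feature)
        out[key] <- if (is.null(rec)) NA_real_
                    else feats[[sensor]][[feature]]
      }
    }
  }
  attr(out, "patient_id") <- pid
  out
}

#' Assemble a cohort feature table
#'
#' @param recordings_by_patient Named list: per patient, a list of
#'   preprocessed [recording()]s.
#' @param cohort Cohort severity table from [read_cohort()] (or with the same
#'   columns); row order defines patient order.
#' @param ... Passed to [extract_features()].
#' @return Data frame: one row per patient, feature columns plus the cohort's
#'   severity columns.
#' @export
feature_table <- function(recordings_by_patient, cohort, ...) {
  stopifnot(is.data.frame(cohort), "patient_id" %in% names(cohort))
  rows <- lapply(cohort$patient_id, function(pid) {
    recs <- recordings_by_patient[[pid]]
    if (is.null(recs)) stop("no recordings for patient ", pid, call. = FALSE)
    extract_features(recs, ...)
  })
  keys <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[keys]))
  df <- as.data.frame(mat, check.names = FALSE)
  df <- cbind(data.frame(patient_id = cohort$patient_id,
                         stringsAsFactors = FALSE), df)
  for (s in intersect(c("etrs", "quest"), names(cohort))) df[[s]] <- cohort[[s]]
  rownames(df) <- NULL
  df
}
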