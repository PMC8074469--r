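#' Trim tap-artifact edges
#'
#' Starting and stopping a capture requires tapping the phone screen, which
#' contaminates the first and last ~50 samples of every file; those edges are
#' discarded before any analysis.
#'
#' @param rec A [recording()].
#' @param n_edge Samples removed from each end (default 50).
#' @return The shortened recording (time stamps of retained samples are kept).
#' @export
trim_edges <- function(rec, n_edge = 50L) {
  stopifnot(inherits(rec, "tremor_recording"), n_edge >= 0L)
  n <- length(rec$time)
  if (n_edge == 0L) return(rec)
  if (n <= 2L * n_edge)
    stop(sprintf("recording too short to trim: %d samples <= 2 x %d", n,
                 n_edge), call. = FALSE)
  keep <- (n_edge + 1L):(n - n_edge)
  rec$time <- rec$time[keep]
  rec$accel <- rec$accel[keep, , drop = FALSE]
  rec$rot_speed <- rec$rot_speed[keep, , drop = FALSE]
  rec
}

#' Design an equiripple FIR band-pass for the tremor band
#'
#' Parks-McClellan (Remez exchange) linear-phase design isolating the
#' Essential-Tremor band, 7-12 Hz by default. The tap count comes from the
#' Kaiser estimate for the requested transition width and stop attenuation,
#' forced odd so the filter is type I.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param pass_low,pass_high Pass-band edges in Hz.
#' @param transition_width Width of each transition band in Hz.
#' @param pass_ripple Maximum pass-band ripple in dB.
#' @param stop_attenuation Minimum stop-band attenuation in dB.
#' @param n_taps Optional explicit tap count (odd); overrides the estimate.
#' @return A `filter_spec` list with the design parameters and the symmetric
#'   coefficient vector.
#' @export
design_bandpass <- function(sample_rate, pass_low = 7, pass_high = 12,
                            transition_width = 1.5, pass_ripple = 1,
                            stop_attenuation = 40, n_taps = NULL) {
  nyq <- sample_rate / 2
  if (!(pass_low > 0 && pass_low < pass_high && pass_high < nyq))
    stop(sprintf("infeasible band: need 0 < %g < %g < Nyquist (%g Hz)",
                 pass_low, pass_high, nyq), call. = FALSE)
  stop_low <- pass_low - transition_width
  stop_high <- pass_high + transition_width
  if (stop_low <= 0 || stop_high >= nyq)
    stop("transition bands fall outside (0, Nyquist); reduce transition_width",
         call. = FALSE)
  if (is.null(n_taps)) {
    # Kaiser order estimate N ~ (A - 7.95) / (2.285 * delta_omega)
    domega <- 2 * pi * transition_width / sample_rate
    n_taps <- ceiling((stop_attenuation - 7.95) / (2.285 * domega)) + 1
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  }
  stopifnot(n_taps %% 2L == 1L, n_taps >= 3L)
  delta_p <- (10^(pass_ripple / 20) - 1) / (10^(pass_ripple / 20) + 1)
  delta_s <- 10^(-stop_attenuation / 20)
  coefs <- signal::remez(n_taps - 1L,
                         c(0, stop_low, pass_low, pass_high, stop_high, nyq) / nyq,
                         c(0, 0, 1, 1, 0, 0),
                         w = c(delta_p / delta_s, 1, delta_p / delta_s))
  coefs <- as.numeric(coefs)
  spec <- list(pass_low = pass_low, pass_high = pass_high,
               transition_width = transition_width, pass_ripple = pass_ripple,
               stop_attenuation = stop_attenuation, sample_rate = sample_rate,
               n_taps = as.integer(n_taps), coefficients = coefs)
  class(spec) <- "filter_spec"
  # verify the achieved magnitude response against the requested spec
  fr <- filter_response(spec, c(seq(0.1, stop_low, by = 0.1),
                                seq(pass_low, pass_high, by = 0.1),
                                seq(stop_high, nyq - 0.05, by = 0.1)))
  pass <- fr$frequency >= pass_low & fr$frequency <= pass_high
  if (max(abs(20 * log10(fr$gain[pass]))) > pass_ripple + 0.1)
    warning("achieved pass-band ripple exceeds the requested spec",
            call. = FALSE)
  if (max(20 * log10(fr$gain[!pass])) > -stop_attenuation + 0.5)
    warning("achieved stop-band attenuation misses the requested spec",
            call. = FALSE)
  spec
}

#' Magnitude response of a designed filter
#'
#' @param spec A `filter_spec` from [design_bandpass()].
#' @param frequency Frequencies (Hz) at which to evaluate the response.
#' @return Data frame with `frequency` and linear `gain`.
#' @export
filter_response <- function(spec, frequency) {
  stopifnot(inherits(spec, "filter_spec"))
  h <- spec$coefficients
  k <- seq_along(h) - 1
  gain <- vapply(frequency, function(f)
    Mod(sum(h * exp(-2i * pi * f / spec$sample_rate * k))), numeric(1))
  data.frame(frequency = frequency, gain = gain)
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "Equiripple FIR band-pass: %g-%g Hz (+/- %g Hz transitions), %d taps @ %g Hz\n",
    x$pass_low, x$pass_high, x$transition_width, x$n_taps, x$sample_rate))
  invisible(x)
}

#' Zero-phase band-pass filtering of a recording
#'
#' Applies the designed FIR filter forward and backward ([signal::filtfilt()])
#' to all six sensor channels, so the output has no group delay and feature
#' timing is undistorted; the effective stop attenuation doubles. Filtering is
#' per axis, before any magnitude computation.
#'
#' @param rec A [recording()].
#' @param spec A `filter_spec`; designed on the fly for the recording's sample
#'   rate when `NULL`.
#' @return The filtered recording (same length).
#' @export
apply_filter <- function(rec, spec = NULL) {
  stopifnot(inherits(rec, "tremor_recording"))
  if (is.null(spec)) spec <- design_bandpass(rec$sample_rate)
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(rec$time)
  if (n <= 3L * spec$n_taps)
    stop(sprintf(
      "recording too short to filter: %d samples <= 3 x %d taps", n,
      spec$n_taps), call. = FALSE)
  h <- spec$coefficients
  # odd-reflection padding suppresses the start/end transients that plain
  # forward-backward filtering of a finite record would otherwise ring with
  zp_filter <- function(x) {
    p <- min(3L * spec$n_taps, length(x) - 1L)
    xp <- c(2 * x[1] - x[(p + 1):2], x,
            2 * x[length(x)] - x[(length(x) - 1):(length(x) - p)])
    y <- signal::filtfilt(h, 1, xp)
    y[(p + 1):(p + length(x))]
  }
  for (ch in c("accel", "rot_speed"))
    for (j in 1:3)
      rec[[ch]][, j] <- zp_filter(rec[[ch]][, j])
  rec
}

#' Orientation-invariant magnitude signal
#'
#' Per-sample Euclidean norm of the three axes of one sensor, removing the
#' dependence on how the phone was strapped to the wrist.
#'
#' @param rec A [recording()].
#' @param sensor `"accel"` or `"rot_speed"`.
#' @return Numeric vector of per-sample magnitudes.
#' @export
vector_magnitude <- function(rec, sensor = c("accel", "rot_speed")) {
  stopifnot(inherits(rec, "tremor_recording"))
  sensor <- match.arg(sensor)
  sqrt(rowSums(rec[[sensor]]^2))
}

#' Principal-axis projection of one sensor
#'
#' Projects the three (filtered) axes onto their first principal component:
#' a linear, orientation-invariant scalar signal that preserves the tremor
#' oscillation frequency. The Euclidean norm, by contrast, rectifies a
#' zero-mean band-passed oscillation and moves its energy to DC and twice the
#' tremor frequency, which distorts frequency-domain features; the projection
#' is therefore the default signal for feature extraction. The projection
#' sign is fixed by requiring a non-negative loading sum.
#'
#' @inheritParams vector_magnitude
#' @return Numeric vector of projected samples (mean removed).
#' @export
principal_signal <- function(rec, sensor = c("accel", "rot_speed")) {
  stopifnot(inherits(rec, "tremor_recording"))
  sensor <- match.arg(sensor)
  M <- sweep(rec[[sensor]], 2, colMeans(rec[[sensor]]), "-")
  v <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  drop(M %*% v)
}

#' Preprocess a recording for feature extraction
#'
#' Convenience chain: [trim_edges()] then [apply_filter()].
#'
#' @inheritParams trim_edges
#' @inheritParams apply_filter
#' @return The conditioned recording.
#' @export
preprocess_recording <- function(rec, n_edge = 50L, spec = NULL) {
  apply_filter(trim_edges(rec, n_edge), spec)
}
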