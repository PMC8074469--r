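TESTS <- c("rest", "postural1", "postural2", "glass", "finger_nose")
HANDS <- c("left", "right")

#' Inertial tremor recording
#'
#' One sensor capture for a (patient, test, hand): time stamps plus triaxial
#' acceleration (g) and rotation speed (rad/s), nominally sampled at 100 Hz.
#'
#' @param patient_id Patient identifier.
#' @param test One of `"rest"`, `"postural1"`, `"postural2"`, `"glass"`,
#'   `"finger_nose"`.
#' @param hand `"left"` or `"right"`.
#' @param time Numeric vector of time stamps in seconds, strictly increasing.
#' @param accel,rot_speed Numeric n x 3 matrices (columns x, y, z).
#' @param sample_rate Nominal sampling rate in Hz; inferred from the median
#'   time-stamp spacing when `NULL`.
#' @return Object of class `tremor_recording`.
#' @export
recording <- function(patient_id, test, hand, time, accel, rot_speed,
                      sample_rate = NULL) {
  test <- match.arg(test, TESTS)
  hand <- match.arg(hand, HANDS)
  accel <- as.matrix(accel); rot_speed <- as.matrix(rot_speed)
  n <- length(time)
  if (n < 1L) stop("a recording needs at least one sample", call. = FALSE)
  if (nrow(accel) != n || nrow(rot_speed) != n ||
      ncol(accel) != 3L || ncol(rot_speed) != 3L)
    stop("accel and rot_speed must be n x 3 with n = length(time)",
         call. = FALSE)
  if (n > 1L) {
    dt <- diff(time)
    bad <- which(dt <= 0)
    if (length(bad))
      stop("time stamps are not strictly increasing at row ", bad[1] + 1L,
           call. = FALSE)
  }
  if (is.null(sample_rate)) {
    if (n < 2L) stop("cannot infer sample_rate from a single sample",
                     call. = FALSE)
    sample_rate <- 1 / stats::median(diff(time))
  }
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (n > 1L) {
    med <- stats::median(diff(time))
    if (abs(med - 1 / sample_rate) > 0.2 / sample_rate)
      stop(sprintf(
        "median sample interval %.4g s deviates more than 20%% from 1/%g Hz",
        med, sample_rate), call. = FALSE)
  }
  colnames(accel) <- colnames(rot_speed) <- c("x", "y", "z")
  structure(list(patient_id = as.character(patient_id), test = test,
                 hand = hand, time = as.numeric(time), accel = accel,
                 rot_speed = rot_speed, sample_rate = sample_rate),
            class = "tremor_recording")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf(
    "Tremor recording: patient %s, %s test, %s hand\n  %d samples @ %.4g Hz (%.3g s)\n",
    x$patient_id, x$test, x$hand, length(x$time), x$sample_rate,
    length(x$time) / x$sample_rate))
  invisible(x)
}

# fixed CSV column order for write_recording; read_recording accepts any
# names through col_map
REC_COLUMNS <- c("timestamp", "accel_x", "accel_y", "accel_z",
                 "rot_x", "rot_y", "rot_z")

#' Read a TREMOR12-style recording CSV
#'
#' Expects a comma-separated file with one header row, a time-stamp column
#' (seconds) and six sensor columns (triaxial acceleration in g and rotation
#' speed in rad/s). Column names are configurable via `col_map` to absorb
#' export-dialect drift; a gravity column, if present, is ignored.
#'
#' @param path CSV file path.
#' @param patient_id,test,hand Recording metadata (taken from the caller or a
#'   manifest, not from file contents).
#' @param col_map Named character vector mapping the canonical names
#'   `timestamp, accel_x, accel_y, accel_z, rot_x, rot_y, rot_z` to the file's
#'   header names.
#' @return A [recording()] with `sample_rate` inferred from the median
#'   time-stamp spacing.
#' @export
read_recording <- function(path, patient_id, test, hand,
                           col_map = stats::setNames(REC_COLUMNS, REC_COLUMNS)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(setequal(names(col_map), REC_COLUMNS))
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(unname(col_map), names(df))
  if (length(miss))
    stop("recording file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  acc_cols <- unname(col_map[paste0("accel_", c("x", "y", "z"))])
  rot_cols <- unname(col_map[paste0("rot_", c("x", "y", "z"))])
  recording(patient_id, test, hand,
            time = df[[col_map[["timestamp"]]]],
            accel = as.matrix(df[acc_cols]),
            rot_speed = as.matrix(df[rot_cols]))
}

#' Write a recording as CSV
#'
#' Columns, in fixed order: `timestamp, accel_x, accel_y, accel_z, rot_x,
#' rot_y, rot_z`. Round-trips through [read_recording()].
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tremor_recording"))
  df <- data.frame(timestamp = rec$time,
                   accel_x = rec$accel[, 1], accel_y = rec$accel[, 2],
                   accel_z = rec$accel[, 3],
                   rot_x = rec$rot_speed[, 1], rot_y = rec$rot_speed[, 2],
                   rot_z = rec$rot_speed[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort severity table
#'
#' CSV with a patient-id column and at least one of the severity columns
#' `etrs` / `quest` (case-insensitive). Row order is preserved.
#'
#' @param path CSV file path.
#' @return Data frame with columns `patient_id`, and `etrs` and/or `quest`
#'   (an absent score column is reported in the `"scores"` attribute).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  idcol <- intersect(c("patient_id", "patient", "id"), names(df))[1]
  if (is.na(idcol)) stop("no patient-id column found", call. = FALSE)
  scores <- intersect(c("etrs", "quest"), names(df))
  if (!length(scores))
    stop("cohort table needs at least one of the columns 'etrs'/'quest'",
         call. = FALSE)
  out <- data.frame(patient_id = as.character(df[[idcol]]))
  for (s in scores) {
    if (any(df[[s]] < 0, na.rm = TRUE))
      stop("severity scores must be non-negative", call. = FALSE)
    out[[s]] <- df[[s]]
  }
  dup <- out$patient_id[duplicated(out$patient_id)]
  if (length(dup))
    stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  attr(out, "scores") <- scores
  out
}
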