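feature_columns <- function(tab) {
  setdiff(names(tab), c("patient_id", "etrs", "quest"))
}

#' Impute missing feature values
#'
#' Fills missing cells of each feature column by interpolating over the
#' patient row index with a cubic spline (default) or by the column median.
#' Observed cells are never altered. Spline interpolation over exchangeable
#' patient rows is statistically debatable but mirrors common practice for
#' short clinical series; the `method` switch makes the choice explicit.
#'
#' @param tab Feature table (data frame; non-numeric and target columns are
#'   passed through untouched).
#' @param method `"spline"` (default) or `"median"`.
#' @return The table with no missing feature values.
#' @export
impute_missing <- function(tab, method = c("spline", "median")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(tab))
  for (col in feature_columns(tab)) {
    x <- tab[[col]]
    if (!is.numeric(x) || !anyNA(x)) next
    obs <- which(!is.na(x))
    if (length(obs) < 4L)
      stop(sprintf(
        "column '%s' has only %d observed value(s) (< 4); drop the column",
        col, length(obs)), call. = FALSE)
    if (method == "spline") {
      fill <- stats::spline(obs, x[obs], xout = which(is.na(x)),
                            method = "fmm")$y
      x[is.na(x)] <- fill
    } else {
      x[is.na(x)] <- stats::median(x[obs])
    }
    tab[[col]] <- x
  }
  tab
}

#' Min-max normalization fitted on training data
#'
#' `fit_normalizer` records per-column minima and maxima from the training
#' table; `apply_normalizer` maps columns to \[0, 1\] using those training
#' statistics only. Test values falling outside the training range are clipped
#' to \[-0.1, 1.1\] with a warning. Constant columns are flagged and mapped to
#' 0.5. `denormalize` inverts the mapping for a single column (used to report
#' predictions on the original score scale).
#'
#' @param train Training feature table.
#' @param columns Columns to normalize; defaults to all feature columns plus
#'   any severity columns present.
#' @return `fit_normalizer`: a `normalizer` object (per-column min and max).
#' @export
fit_normalizer <- function(train, columns = NULL) {
  stopifnot(is.data.frame(train), nrow(train) >= 1L)
  if (is.null(columns))
    columns <- c(feature_columns(train),
                 intersect(c("etrs", "quest"), names(train)))
  lo <- vapply(columns, function(cl) min(train[[cl]], na.rm = TRUE), numeric(1))
  hi <- vapply(columns, function(cl) max(train[[cl]], na.rm = TRUE), numeric(1))
  const <- hi - lo <= .Machine$double.eps * pmax(1, abs(hi))
  if (any(const))
    warning("constant column(s) mapped to 0.5: ",
            paste(columns[const], collapse = ", "), call. = FALSE)
  structure(list(columns = columns, min = lo, max = hi, constant = const),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param tab Table to transform.
#' @param params A `normalizer` from `fit_normalizer`.
#' @param clip Clip range for out-of-training-range values.
#' @export
apply_normalizer <- function(tab, params, clip = c(-0.1, 1.1)) {
  stopifnot(inherits(params, "normalizer"))
  clipped <- FALSE
  for (i in seq_along(params$columns)) {
    cl <- params$columns[i]
    if (!cl %in% names(tab)) next
    if (params$constant[i]) {
      tab[[cl]] <- rep(0.5, nrow(tab))
      next
    }
    z <- (tab[[cl]] - params$min[i]) / (params$max[i] - params$min[i])
    if (any(z < clip[1] | z > clip[2], na.rm = TRUE)) clipped <- TRUE
    tab[[cl]] <- pmin(pmax(z, clip[1]), clip[2])
  }
  if (clipped)
    warning("values outside the training range were clipped to [",
            clip[1], ", ", clip[2], "]", call. = FALSE)
  tab
}

#' @rdname fit_normalizer
#' @param x Normalized values of one column.
#' @param column Column name.
#' @export
denormalize <- function(x, params, column) {
  stopifnot(inherits(params, "normalizer"))
  i <- match(column, params$columns)
  if (is.na(i)) stop("column '", column, "' not in normalizer", call. = FALSE)
  if (params$constant[i]) return(rep(params$min[i], length(x)))
  x * (params$max[i] - params$min[i]) + params$min[i]
}

#' Split a feature table into training and test sets
#'
#' Disjoint, exhaustive partition with `round(train_frac * n)` training rows,
#' reproducible under a fixed seed.
#'
#' @param tab Feature table.
#' @param train_frac Training fraction in (0, 1) (default 0.75).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(tab, train_frac = 0.75, seed = 1L) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 4L)
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must be in (0, 1)", call. = FALSE)
  n <- nrow(tab)
  n_train <- round(train_frac * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = tab[sort(idx), , drop = FALSE],
       test = tab[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

.cv_mse <- function(tab, target, vars, folds) {
  errs <- numeric(0)
  for (k in unique(folds)) {
    tr <- tab[folds != k, , drop = FALSE]
    te <- tab[folds == k, , drop = FALSE]
    fit <- rpart::rpart(
      stats::reformulate(sprintf("`%s`", vars), response = sprintf("`%s`", target)),
      data = tr, method = "anova",
      control = rpart::rpart.control(minsplit = 4, minbucket = 2, cp = 1e-4,
                                     xval = 0, maxcompete = 0,
                                     maxsurrogate = 0))
    pred <- stats::predict(fit, te)
    errs <- c(errs, (te[[target]] - pred)^2)
  }
  mean(errs)
}

#' Sequential forward feature selection with a CART wrapper
#'
#' Greedy forward selection: starting from the empty set, the candidate
#' feature whose addition minimizes the cross-validated mean squared error of
#' a CART regression tree is added, if and only if it strictly decreases the
#' incumbent CV MSE; selection stops otherwise. The incumbent MSE for the
#' empty set is the CV MSE of the constant (mean) predictor.
#'
#' @param train Training feature table.
#' @param target Target column name (`"etrs"` or `"quest"`).
#' @param candidates Candidate feature columns (default: all feature columns).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @return Object of class `selection_result`: `selected` (ordered keys) and
#'   `mse_trace` (incumbent CV MSE after each accepted step, starting at the
#'   null model).
#' @export
select_features <- function(train, target, candidates = NULL, cv_folds = 5L,
                            seed = 1L) {
  stopifnot(is.data.frame(train))
  if (!target %in% names(train))
    stop("target column '", target, "' not found", call. = FALSE)
  if (is.null(candidates)) candidates <- feature_columns(train)
  if (!length(candidates)) stop("no candidate features", call. = FALSE)
  if (nrow(train) < cv_folds)
    stop("fewer rows than CV folds", call. = FALSE)
  folds <- withr::with_seed(seed,
    sample(rep_len(seq_len(cv_folds), nrow(train))))
  # null-model CV MSE: fold-mean predictor
  null_mse <- mean(unlist(lapply(unique(folds), function(k) {
    mu <- mean(train[[target]][folds != k])
    (train[[target]][folds == k] - mu)^2
  })))
  selected <- character(0)
  trace <- null_mse
  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    mses <- vapply(pool, function(v)
      .cv_mse(train, target, c(selected, v), folds), numeric(1))
    best <- which.min(mses)
    if (mses[best] < trace[length(trace)]) {
      selected <- c(selected, pool[best])
      trace <- c(trace, mses[best])
    } else break
  }
  structure(list(selected = selected, mse_trace = trace, target = target,
                 cv_folds = cv_folds, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Forward CART-wrapper selection for '%s' (%d-fold CV)\n",
              x$target, x$cv_folds))
  if (!length(x$selected)) {
    cat("  no feature decreased the CV MSE\n")
  } else {
    cat(sprintf("  %d. %s (CV MSE %.4g)\n", seq_along(x$selected),
                x$selected, x$mse_trace[-1]), sep = "")
  }
  invisible(x)
}

#' Reference variable presets for the severity models
#'
#' The (test, sensor, feature) combinations used to train the reference ETRS
#' and QUEST fuzzy models: for ETRS, power growth of the accelerometer at
#' rest, dominant magnitude (accelerometer) and signal RMS (rotation speed)
#' during the first postural test, and dominant frequency (accelerometer) and
#' dominant magnitude (rotation speed) during the second postural test; for
#' QUEST, power growth of the rotation speed during the first postural test
#' and dominant frequency of the accelerometer during the second. Because a
#' severity score is one value per patient while features are per hand, preset
#' columns are the mean of the left- and right-hand values (see
#' [collapse_hands()]).
#'
#' @param target `"etrs"` or `"quest"`.
#' @return Data frame with columns `test`, `sensor`, `feature`, `key`.
#' @export
preset_variables <- function(target = c("etrs", "quest")) {
  target <- match.arg(target)
  v <- if (target == "etrs") data.frame(
    test = c("rest", "postural1", "postural1", "postural2", "postural2"),
    sensor = c("accel", "accel", "rot_speed", "accel", "rot_speed"),
    feature = c("power_growth", "dominant_magnitude", "signal_rms",
                "dominant_frequency", "dominant_magnitude"))
  else data.frame(
    test = c("postural1", "postural2"),
    sensor = c("rot_speed", "accel"),
    feature = c("power_growth", "dominant_frequency"))
  v$key <- paste(v$test, v$sensor, v$feature, sep = ".")
  v
}

#' Collapse left/right hand features to per-patient columns
#'
#' Adds, for every (test, sensor, feature) present for both hands, a column
#' `test.sensor.feature` holding the mean of the two hands' values.
#'
#' @param tab Feature table with `test.hand.sensor.feature` columns.
#' @return The table with the hand-collapsed columns appended.
#' @export
collapse_hands <- function(tab) {
  keys <- feature_columns(tab)
  parts <- strsplit(keys, ".", fixed = TRUE)
  four <- lengths(parts) == 4L
  base <- vapply(parts[four], function(p) paste(p[c(1, 3, 4)], collapse = "."),
                 character(1))
  for (b in unique(base)) {
    members <- keys[four][base == b]
    if (length(members) == 2L)
      tab[[b]] <- rowMeans(tab[, members, drop = FALSE])
  }
  tab
}
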