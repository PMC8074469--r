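test_that("spline imputation recovers cubic trends and keeps observed cells", {
  n <- 12
  x <- seq_len(n)
  cubic <- 0.5 * x^3 - 2 * x^2 + x + 3
  tab <- data.frame(patient_id = sprintf("p%d", x),
                    a = cubic, b = rnorm(n), etrs = rnorm(n),
                    check.names = FALSE)
  tab$a[c(4, 7, 9)] <- NA
  out <- impute_missing(tab)
  expect_false(anyNA(out$a))
  expect_equal(out$a[c(4, 7, 9)], cubic[c(4, 7, 9)], tolerance = 1e-6)
  expect_identical(out$a[-c(4, 7, 9)], cubic[-c(4, 7, 9)])
  expect_identical(out$b, tab$b)  # untouched column

  # identity on complete tables
  full <- data.frame(a = rnorm(5), b = rnorm(5))
  expect_identical(impute_missing(full), full)

  # too little information
  tab$a[-c(1, 2)] <- NA
  expect_error(impute_missing(tab), "drop the column")

  # median alternative
  tab2 <- data.frame(a = c(1, 2, NA, 4, 8, 100))
  expect_equal(impute_missing(tab2, method = "median")$a[3], 4)
})

test_that("min-max normalization uses training statistics and inverts exactly", {
  train <- data.frame(a = c(0, 5, 10), b = c(2, 4, 6))
  norm <- fit_normalizer(train, columns = c("a", "b"))
  out <- apply_normalizer(train, norm)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(range(out$b), c(0, 1))
  expect_equal(denormalize(out$a, norm, "a"), train$a, tolerance = 1e-9)

  # test rows outside the training range are clipped, with a warning
  test <- data.frame(a = c(-5, 20), b = c(4, 4))
  expect_warning(res <- apply_normalizer(test, norm), "clipped")
  expect_equal(res$a, c(-0.1, 1.1))

  # constant column flagged and centred
  cst <- data.frame(a = rep(2, 4))
  expect_warning(nc <- fit_normalizer(cst, columns = "a"), "constant")
  expect_equal(apply_normalizer(cst, nc)$a, rep(0.5, 4))
})

test_that("train/test split is a reproducible 75/25 partition", {
  tab <- data.frame(patient_id = sprintf("p%02d", 1:20), x = rnorm(20),
                    etrs = rnorm(20))
  sp <- split_train_test(tab, seed = 3)
  expect_equal(nrow(sp$train), 15)
  expect_equal(nrow(sp$test), 5)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id), tab$patient_id)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  sp2 <- split_train_test(tab, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(tab, seed = 4)))
  expect_error(split_train_test(tab, train_frac = 1.0), "train_frac")
})

test_that("forward CART selection recovers the informative feature", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    tab <- data.frame(A = runif(n), N1 = runif(n), N2 = runif(n),
                      N3 = runif(n), N4 = runif(n), N5 = runif(n))
    tab$etrs <- 3 * tab$A
    sel <- select_features(tab, "etrs", seed = s)
    length(sel$selected) >= 1 && sel$selected[1] == "A" &&
      length(sel$selected) <= 2
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("selection stopping and degenerate cases behave", {
  set.seed(1)
  tab <- data.frame(A = runif(30), etrs = numeric(30))
  # zero-variance target: nothing can decrease the CV MSE below zero
  sel <- select_features(tab, "etrs", seed = 1)
  expect_length(sel$selected, 0)

  tab$etrs <- 2 * tab$A
  sel1 <- select_features(tab, "etrs", candidates = "A", seed = 1)
  expect_true(length(sel1$selected) <= 1)
  expect_true(all(diff(sel1$mse_trace) < 0))   # strictly decreasing

  expect_error(select_features(tab, "quest"), "not found")
})

test_that("reference presets map to hand-collapsed feature columns", {
  pv_e <- preset_variables("etrs")
  pv_q <- preset_variables("quest")
  expect_equal(nrow(pv_e), 5)
  expect_equal(nrow(pv_q), 2)
  expect_true("postural1.rot_speed.power_growth" %in% pv_q$key)
  expect_true("postural2.accel.dominant_frequency" %in% pv_q$key)

  tab <- data.frame(`rest.left.accel.signal_rms` = c(1, 3),
                    `rest.right.accel.signal_rms` = c(3, 5),
                    check.names = FALSE)
  out <- collapse_hands(tab)
  expect_equal(out$`rest.accel.signal_rms`, c(2, 4))
})
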