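test_that("FCM objective matches a direct brute-force summation", {
  set.seed(11)
  data <- matrix(runif(40), 20, 2)
  centers <- matrix(runif(4), 2, 2)
  m <- 2
  # independent oracle: explicit loops over the standard closed form
  oracle <- 0
  for (i in 1:20) {
    d2 <- c(sum((data[i, ] - centers[1, ])^2),
            sum((data[i, ] - centers[2, ])^2))
    u <- (1 / d2)^(1 / (m - 1)); u <- u / sum(u)
    oracle <- oracle + sum(u^m * d2)
  }
  expect_equal(fcm_objective(data, centers, m), oracle, tolerance = 1e-10)
})

test_that("FCM objective degenerate cases", {
  data <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(fcm_objective(data, data), 0)     # every point on a center
  one <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(fcm_objective(data, one), sum((data - rep(1, 2) %o% c(0.5, 0.5))^2))
  expect_error(fcm_objective(matrix(numeric(0), 0, 2), one), "empty")
})

test_that("partition columns sum to one", {
  set.seed(2)
  data <- matrix(runif(60), 30, 2)
  U <- fcm_partition(data, matrix(runif(6), 3, 2))
  expect_equal(colSums(U), rep(1, 30), tolerance = 1e-9)
  expect_true(all(U >= 0 & U <= 1))
})

test_that("FST-PSO recovers planted blob centers and beats random-restart FCM", {
  blob_data <- function(s) {
    set.seed(s)
    rbind(matrix(rnorm(100, 0.25, 0.02), 50, 2),
          matrix(rnorm(100, 0.75, 0.02), 50, 2))
  }
  hits <- ok_vs_fcm <- logical(5)
  for (s in 1:5) {
    data <- blob_data(s)
    res <- fstpso_cluster(data, 2, seed = s)
    cen <- res$centers[order(res$centers[, 1]), ]
    hits[s] <- max(abs(cen - rbind(c(0.25, 0.25), c(0.75, 0.75)))) < 0.05
    restarts <- vapply(1:20, function(k)
      fcm_cluster(data, 2, seed = 1000 * s + k)$objective, numeric(1))
    ok_vs_fcm[s] <- res$objective <= min(restarts) + 1e-6
    expect_true(all(diff(res$trace) <= 1e-12))   # best-so-far non-increasing
    expect_equal(colSums(res$partition), rep(1, 100), tolerance = 1e-9)
  }
  expect_gte(sum(hits), 5)
  expect_gte(sum(ok_vs_fcm), 4)
})

test_that("more clusters attain a lower objective", {
  set.seed(9)
  data <- matrix(runif(20), 10, 2)
  res_n <- fstpso_cluster(data, nrow(data), seed = 9, max_iter = 50)
  single <- fstpso_cluster(data, 1, seed = 9, max_iter = 50)
  expect_lt(res_n$objective, single$objective)
  expect_error(fstpso_cluster(data, 11), "at least as many")
})

test_that("antecedent fitting recovers cluster moments", {
  set.seed(4)
  n <- 200
  x1 <- rnorm(n / 2, 0.3, 0.05)
  x2 <- rnorm(n / 2, 0.7, 0.05)
  X <- matrix(c(x1, x2), ncol = 1, dimnames = list(NULL, "x"))
  U <- rbind(c(rep(1, n / 2), rep(0, n / 2)),
             c(rep(0, n / 2), rep(1, n / 2)))   # crisp partition
  ants <- fit_antecedents(X, U)
  expect_equal(ants[[1]]$x$mu, 0.3, tolerance = 0.02)
  expect_lt(abs(ants[[1]]$x$sigma - 0.05) / 0.05, 0.3)
  # mirror symmetry
  expect_equal(ants[[1]]$x$mu + ants[[2]]$x$mu, 1, tolerance = 0.02)

  # degenerate single-point cluster: floor sigma, centre on the point
  U1 <- rbind(c(1, rep(0, n - 1)), c(0, rep(1, n - 1)))
  a1 <- fit_antecedents(X, U1)
  expect_equal(a1[[1]]$x$mu, as.numeric(X[1, 1]))
  expect_equal(a1[[1]]$x$sigma, 1e-3)
})

test_that("consequent WLS matches OLS closed forms and normal equations", {
  # two points, unit weights: exact line through them
  X <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "x"))
  cons <- fit_consequents(X, c(1, 3), matrix(1, 1, 2))
  expect_equal(unname(cons[[1]]$coefficients), 2, tolerance = 1e-6)
  expect_equal(cons[[1]]$intercept, 1, tolerance = 1e-6)

  # crisp two-regime recovery within 5%
  set.seed(12)
  n <- 200
  x <- runif(n)
  left <- x < 0.5
  y <- ifelse(left, 1 + 2 * x, 4 - 3 * x) + rnorm(n, sd = 0.01)
  B <- rbind(as.numeric(left), as.numeric(!left))
  Xm <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  cons <- fit_consequents(Xm, y, B)
  expect_equal(unname(cons[[1]]$coefficients), 2, tolerance = 0.05)
  expect_equal(cons[[1]]$intercept, 1, tolerance = 0.05)
  expect_equal(unname(cons[[2]]$coefficients), -3, tolerance = 0.05)
  expect_equal(cons[[2]]$intercept, 4, tolerance = 0.05)

  # weighted residual orthogonality per rule
  set.seed(13)
  Bz <- rbind(runif(n), runif(n))
  cons2 <- fit_consequents(Xm, y, Bz)
  for (j in 1:2) {
    r <- y - (Xm[, 1] * cons2[[j]]$coefficients + cons2[[j]]$intercept)
    expect_lt(abs(sum(Bz[j, ] * r * Xm[, 1])), 1e-6)
    expect_lt(abs(sum(Bz[j, ] * r)), 1e-6)
  }

  expect_error(fit_consequents(Xm, y, rbind(rep(0, n))), "never fires")
})

test_that("model building yields two rules and collapses to a line for C = 1", {
  d <- gen_ts_dataset(tent_truth(), 150, noise_sd = 0.05, seed = 21)
  m <- build_ts_model(as.matrix(d["x"]), d$y, seed = 21)
  expect_length(m$rules, 2)

  m1 <- build_ts_model(as.matrix(d["x"]), d$y, n_clusters = 1, seed = 21)
  lmfit <- lm(y ~ x, data = d)
  expect_equal(unname(infer(m1, as.matrix(d["x"]))),
               unname(predict(lmfit)), tolerance = 1e-6)
})

test_that("the full build recovers planted tent parameters (quick check)", {
  errs <- vapply(1:5, function(s) {
    d <- gen_ts_dataset(tent_truth(), 200, noise_sd = 0.01, seed = s)
    m <- build_ts_model(as.matrix(d["x"]), d$y, seed = s)
    ints <- vapply(m$rules, `[[`, numeric(1), "intercept")
    mus <- vapply(m$rules, function(r) r$sets$x$mu, numeric(1))
    max(abs(ints[order(mus)] - c(1, 2)) / c(1, 2))
  }, numeric(1))
  expect_lt(median(errs), 0.12)
})
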