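test_that("Gaussian membership has unit mode and exp(-1/2) at one sigma", {
  s <- gaussian_set(0.4, 0.2, "low")
  expect_equal(membership(s, 0.4), 1)
  expect_equal(membership(s, 0.4 + 0.2), exp(-0.5))
  expect_equal(membership(s, 0.4 - 0.2), exp(-0.5))
  far <- membership(s, seq(1, 10, by = 1))
  expect_true(all(diff(far) <= 0))
  expect_lt(far[10], 1e-9)
  expect_error(gaussian_set(0, -1), "positive")
})

test_that("firing degree is the minimum over non-don't-care clauses", {
  sets <- list(a = gaussian_set(0, 1), b = gaussian_set(0, 0.5),
               c = gaussian_set(0, 2))
  r <- ts_rule(sets, c(a = 0, b = 0, c = 0), 0)
  set.seed(1)
  for (i in 1:100) {
    x <- runif(3, -2, 2)
    names(x) <- c("a", "b", "c")
    manual <- min(membership(sets$a, x["a"]), membership(sets$b, x["b"]),
                  membership(sets$c, x["c"]))
    expect_equal(firing_degree(r, x), unname(manual), tolerance = 1e-12)
  }
  # don't-care clauses are excluded; all-don't-care fires fully
  r2 <- ts_rule(list(a = NULL, b = NULL), c(a = 1, b = 1), 0)
  expect_equal(firing_degree(r2, c(a = 99, b = -99)), 1)
  expect_error(firing_degree(r, c(1, 2)), "3 variables")
})

test_that("rule outputs are affine and reproduce the reference intercepts", {
  quest <- parse_rules(fixture_path("rules_quest.txt"))
  x0 <- setNames(numeric(2), quest$variables)
  expect_equal(rule_output(quest$rules[[1]], x0), 11.70)
  expect_equal(rule_output(quest$rules[[2]], x0), 47.00)

  r <- ts_rule(list(u = NULL, v = NULL), c(u = 1, v = 1), 0)
  expect_equal(rule_output(r, c(u = 2, v = 3)), 5)
  x <- c(u = 0.3, v = -1.2)
  expect_equal(rule_output(r, 2 * x) - rule_output(r, x),
               unname(sum(r$coefficients * x)))
})

test_that("inference is the firing-weighted average of rule outputs", {
  # equal firing averages the consequents
  m <- ts_model("x", list(
    ts_rule(list(x = gaussian_set(0.3, 0.1)), c(x = 0), 10),
    ts_rule(list(x = gaussian_set(0.7, 0.1)), c(x = 0), 20)))
  expect_equal(infer(m, c(x = 0.5)), 15)

  # brute-force oracle on random three-rule models
  set.seed(42)
  for (rep in 1:5) {
    vars <- c("a", "b")
    rules <- lapply(1:3, function(j)
      ts_rule(list(a = gaussian_set(runif(1), runif(1, 0.05, 0.5)),
                   b = gaussian_set(runif(1), runif(1, 0.05, 0.5))),
              c(a = rnorm(1), b = rnorm(1)), rnorm(1)))
    mm <- ts_model(vars, rules)
    X <- matrix(runif(80), ncol = 2, dimnames = list(NULL, vars))
    manual <- apply(X, 1, function(x) {
      beta <- vapply(rules, function(r)
        min(membership(r$sets$a, x["a"]), membership(r$sets$b, x["b"])),
        numeric(1))
      y <- vapply(rules, function(r)
        sum(r$coefficients * x) + r$intercept, numeric(1))
      sum(beta * y) / sum(beta)
    })
    expect_equal(infer(mm, X), manual, tolerance = 1e-12)
    # convex combination bound
    Y <- vapply(rules, rule_output, numeric(nrow(X)), x = X)
    out <- infer(mm, X)
    expect_true(all(out >= apply(Y, 1, min) - 1e-9 &
                    out <= apply(Y, 1, max) + 1e-9))
  }
})

test_that("zero total firing falls back to the unweighted rule mean", {
  m <- ts_model("x", list(
    ts_rule(list(x = gaussian_set(100, 0.01)), c(x = 0), 10),
    ts_rule(list(x = gaussian_set(-100, 0.01)), c(x = 0), 30)))
  expect_warning(out <- infer(m, c(x = 0)), "zero")
  expect_equal(out, 20)
})

test_that("a never-firing rule does not change inference", {
  m <- ts_model("x", list(
    ts_rule(list(x = gaussian_set(0.4, 0.2)), c(x = 1), 1)))
  g <- matrix(seq(0, 1, length.out = 101), dimnames = list(NULL, "x"))
  base <- infer(m, g)
  m2 <- ts_model("x", c(m$rules, list(
    ts_rule(list(x = gaussian_set(1e6, 1e-3)), c(x = 5), -99))))
  expect_equal(infer(m2, g), base, tolerance = 1e-12)
})

test_that("inference is continuous on a dense grid", {
  quest <- parse_rules(fixture_path("rules_quest.txt"))
  g <- as.matrix(expand.grid(dominantFrequency = seq(0, 1, length.out = 60),
                             powerGrowth = 0.5))
  out <- infer(quest, g)
  expect_lt(max(abs(diff(out))), 0.1 * diff(range(out)) + 1e-9)
})

test_that("rule text export/parse round-trips the reference models", {
  for (f in c("rules_quest.txt", "rules_etrs_full.txt",
              "rules_etrs_reduced.txt")) {
    lines <- readLines(fixture_path(f))
    lines <- trimws(lines[nzchar(trimws(lines)) &
                            !startsWith(trimws(lines), "#")])
    model <- parse_rules(lines)
    expect_identical(export_rules(model), lines)          # fixed point
    expect_length(model$rules, 2)
  }
  etrs <- parse_rules(fixture_path("rules_etrs_full.txt"))
  expect_equal(unname(etrs$rules[[1]]$coefficients["dominantFrequency"]), 60.4)
  expect_equal(unname(etrs$rules[[1]]$coefficients["dominantMagnitude"]), -87)
  expect_equal(etrs$rules[[1]]$intercept, -2.19)
  expect_equal(etrs$rules[[2]]$intercept, 55.7)
  # the merged-away variable is don't-care in every rule
  expect_null(etrs$rules[[1]]$sets$signalRMS)
  expect_null(etrs$rules[[2]]$sets$signalRMS)
  # its clause renders as "any value"
  expect_match(export_rules(etrs)[1], "\\(signalRMS IS any value\\)")

  one <- parse_rules("RULE 1: IF (x IS low) THEN (y = 1 * x + 0.5)")
  expect_length(export_rules(one), 1)
})

test_that("model JSON serialization round-trips", {
  m <- parse_rules(fixture_path("rules_quest.txt"))
  path <- withr::local_tempfile(fileext = ".json")
  write_ts_model(m, path)
  back <- read_ts_model(path)
  expect_identical(export_rules(back), export_rules(m))
  X <- matrix(runif(20), ncol = 2,
              dimnames = list(NULL, m$variables))
  expect_equal(infer(back, X), infer(m, X), tolerance = 1e-12)
})
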