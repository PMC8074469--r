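test_that("Jaccard similarity matches fine-grid quadrature", {
  a <- gaussian_set(0, 1); b <- gaussian_set(0.5, 1)
  uni <- c(-5, 5.5)
  coarse <- jaccard_similarity(a, b, universe = uni)
  g <- seq(uni[1], uni[2], length.out = 1e6)
  fine <- sum(pmin(membership(a, g), membership(b, g))) /
    sum(pmax(membership(a, g), membership(b, g)))
  expect_equal(coarse, fine, tolerance = 1e-3)

  expect_equal(jaccard_similarity(a, a), 1)
  expect_lt(jaccard_similarity(gaussian_set(0, 0.01),
                               gaussian_set(10, 0.01),
                               universe = c(-1, 11)), 1e-6)
  expect_error(jaccard_similarity(gaussian_set(0, 1e-3),
                                  gaussian_set(100, 1e-3),
                                  universe = c(40, 60)), "zero")
})

two_set_model <- function(mu2, sigma = 0.1, extra_var = FALSE) {
  v1 <- list(x = gaussian_set(0.4, sigma, "low"))
  v2 <- list(x = gaussian_set(mu2, sigma, "high"))
  if (extra_var) {
    v1$z <- gaussian_set(0.2, 0.1, "low")
    v2$z <- gaussian_set(0.8, 0.1, "high")
    ts_model(c("x", "z"),
             list(ts_rule(v1, c(x = 1, z = 0), 0),
                  ts_rule(v2, c(x = -1, z = 0), 1)))
  } else {
    ts_model("x", list(ts_rule(v1, c(x = 1), 0),
                       ts_rule(v2, c(x = -1), 1)))
  }
}

test_that("similarity graph links only same-variable, similar sets", {
  # far-apart sets: edgeless, each node its own component
  g1 <- build_similarity_graph(two_set_model(0.9))
  expect_equal(nrow(g1$edges), 0)
  expect_equal(length(unique(g1$components$component[
    g1$components$variable == "x"])), 2)

  # near-identical pair: one two-node component
  g2 <- build_similarity_graph(two_set_model(0.405))
  expect_equal(nrow(g2$edges), 1)
  expect_gte(g2$edges$similarity[1], 0.9)
  comp_x <- g2$components[g2$components$variable == "x", ]
  expect_equal(length(unique(comp_x$component)), 1)
})

test_that("similarity chaining joins a component across a weak end pair", {
  m3 <- ts_model("x", list(
    ts_rule(list(x = gaussian_set(0.400, 0.1, "low")), c(x = 1), 0),
    ts_rule(list(x = gaussian_set(0.413, 0.1, "medium")), c(x = 1), 0),
    ts_rule(list(x = gaussian_set(0.426, 0.1, "high")), c(x = 1), 0)))
  # adjacent pairs sit just above 0.9, the end pair well below it
  s12 <- jaccard_similarity(gaussian_set(0.400, 0.1), gaussian_set(0.413, 0.1),
                            universe = c(0, 1))
  s13 <- jaccard_similarity(gaussian_set(0.400, 0.1), gaussian_set(0.426, 0.1),
                            universe = c(0, 1))
  expect_gte(s12, 0.9)
  expect_lt(s13, 0.9)
  g <- build_similarity_graph(m3, threshold = 0.9)
  comp <- g$components[g$components$variable == "x", ]
  expect_equal(length(unique(comp$component)), 1)   # A-B-C chained
  expect_lt(comp$min_similarity[1], g$threshold)    # reported honestly
})

test_that("simplification merges similar sets and renders shared sets don't-care", {
  m <- two_set_model(0.405, extra_var = TRUE)
  out <- simplify_rules(m, threshold = 0.9)
  expect_length(out$rules, length(m$rules))          # rule count unchanged
  # x collapsed to a single shared set -> don't-care in every rule
  expect_null(out$rules[[1]]$sets$x)
  expect_null(out$rules[[2]]$sets$x)
  expect_match(export_rules(out)[1], "\\(x IS any value\\)")
  # the discriminative variable z is untouched
  expect_equal(out$rules[[1]]$sets$z$mu, 0.2)
  merged <- attr(out, "merged_pairs")
  expect_true(all(merged$similarity >= 0.9))
})

test_that("simplification is idempotent and the identity below threshold", {
  m <- two_set_model(0.405, extra_var = TRUE)
  s1 <- simplify_rules(m, 0.9)
  s2 <- simplify_rules(s1, 0.9)
  expect_identical(export_rules(s1), export_rules(s2))
  expect_identical(lapply(s1$rules, `[[`, "sets"),
                   lapply(s2$rules, `[[`, "sets"))

  # theta = 1 on distinct sets changes nothing
  m2 <- two_set_model(0.6)
  out2 <- simplify_rules(m2, threshold = 1.0)
  expect_identical(lapply(out2$rules, `[[`, "sets"),
                   lapply(m2$rules, `[[`, "sets"))
})

test_that("lowering the threshold never merges fewer pairs", {
  mus <- c(0.42, 0.5, 0.65, 0.9)
  counts <- vapply(c(0.95, 0.9, 0.7, 0.5, 0.3), function(th) {
    n_merged <- 0L
    for (mu2 in mus) {
      out <- simplify_rules(two_set_model(mu2), threshold = th)
      n_merged <- n_merged + nrow(attr(out, "merged_pairs"))
    }
    n_merged
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("simplification at 0.95 barely moves the inference surface", {
  # x discriminates the rules; the near-duplicate z sets are merged away
  m <- ts_model(c("x", "z"), list(
    ts_rule(list(x = gaussian_set(0.25, 0.15, "low"),
                 z = gaussian_set(0.498, 0.1, "low")), c(x = 1, z = 0), 0),
    ts_rule(list(x = gaussian_set(0.75, 0.15, "high"),
                 z = gaussian_set(0.502, 0.1, "high")), c(x = -1, z = 0), 2)))
  out <- simplify_rules(m, threshold = 0.95)
  expect_gte(nrow(attr(out, "merged_pairs")), 1)
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 100), z = 0.4))
  before <- infer(m, g)
  after <- infer(out, g)
  expect_lt(mean(abs(before - after)), 0.05 * diff(range(before)))
})
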