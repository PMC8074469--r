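#' Fit a Takagi-Sugeno fuzzy severity model
#'
#' The package's main fitting function. Inputs are min-max normalized on the
#' training data; the joint (input, target) space is clustered with fuzzy
#' c-means driven by fuzzy self-tuning particle swarm optimization; each
#' cluster becomes one rule, with Gaussian antecedent sets fitted from the
#' projected partition and affine consequents estimated by firing-weighted
#' least squares on the original target scale. The rule base is then
#' simplified by merging near-duplicate fuzzy sets (Jaccard similarity at
#' `simplify_threshold`; see [simplify_rules()]).
#'
#' @param formula Model formula, e.g. `etrs ~ .` or
#'   `quest ~ dominant_frequency + power_growth`.
#' @param data Data frame with the target and feature columns.
#' @param rules Number of rules/clusters (default 2).
#' @param fuzziness Fuzzy c-means exponent m (default 2).
#' @param max_iter Swarm iterations (default 100).
#' @param seed Integer seed for the stochastic clustering stage.
#' @param simplify_threshold Jaccard threshold for rule-base simplification;
#'   `NULL` disables simplification (default 0.9).
#' @param weighting,consequent_fit,antecedent_method,polish Passed to
#'   [build_ts_model()].
#' @return Object of class `ts_fuzzy`: the fitted [ts_model()] (`$model`),
#'   the input `normalizer` (`$normalizer`), fitted values and residuals, and
#'   the call. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' truth <- parse_rules(c(
#'   "RULE 1: IF (x IS low) THEN (y = 1 * x + 0)",
#'   "RULE 2: IF (x IS high) THEN (y = -1 * x + 3)"))
#' d <- gen_ts_dataset(truth, 80, noise_sd = 0.05, seed = 7)
#' fit <- ts_fuzzy(y ~ x, d, seed = 7)
#' fit
#' @export
ts_fuzzy <- function(formula, data, rules = 2L, fuzziness = 2,
                     max_iter = 100L, seed = 1L, simplify_threshold = 0.9,
                     weighting = "antecedent", consequent_fit = "global",
                     antecedent_method = "moments", polish = FALSE) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  target <- names(mf)[1]
  vars <- attr(stats::terms(mf), "term.labels")
  if (!length(vars)) stop("the model needs at least one input variable",
                          call. = FALSE)
  X <- as.matrix(mf[, vars, drop = FALSE])

  norm <- fit_normalizer(as.data.frame(X, check.names = FALSE),
                         columns = vars)
  Xn <- as.matrix(apply_normalizer(as.data.frame(X, check.names = FALSE),
                                   norm))
  model <- build_ts_model(Xn, y, n_clusters = rules, m = fuzziness,
                          max_iter = max_iter, seed = seed,
                          weighting = weighting,
                          consequent_fit = consequent_fit, target = target,
                          antecedent_method = antecedent_method,
                          polish = polish)
  if (!is.null(simplify_threshold))
    model <- simplify_rules(model, threshold = simplify_threshold)
  model$normalization <- list(
    columns = norm$columns, min = as.list(norm$min), max = as.list(norm$max))

  fitted_vals <- infer(model, Xn)
  obj <- structure(list(model = model, normalizer = norm, target = target,
                        variables = vars, fitted.values = fitted_vals,
                        residuals = y - fitted_vals, y = y,
                        n = length(y), seed = seed, call = cl),
                   class = "ts_fuzzy")
  obj
}

#' @export
print.ts_fuzzy <- function(x, digits = 4, ...) {
  cat("Takagi-Sugeno fuzzy severity model\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(export_rules(x$model, digits = digits), sep = "\n")
  cat(sprintf("\nTraining: n = %d, MAE = %.4g, RMSE = %.4g\n", x$n,
              mean(abs(x$residuals)), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
summary.ts_fuzzy <- function(object, ...) {
  sets <- do.call(rbind, lapply(seq_along(object$model$rules), function(j) {
    r <- object$model$rules[[j]]
    do.call(rbind, lapply(object$variables, function(v) {
      s <- r$sets[[v]]
      data.frame(rule = j, variable = v,
                 term = if (is.null(s)) "any value" else s$label,
                 mu = if (is.null(s)) NA_real_ else s$mu,
                 sigma = if (is.null(s)) NA_real_ else s$sigma)
    }))
  }))
  out <- list(call = object$call, rules = export_rules(object$model),
              sets = sets, coef = stats::coef(object),
              n = object$n, mae = mean(abs(object$residuals)),
              rmse = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.ts_fuzzy"
  out
}

#' @export
print.summary.ts_fuzzy <- function(x, ...) {
  cat("Takagi-Sugeno fuzzy severity model\n")
  cat("Call: ", deparse(x$call), "\n\nRules:\n")
  cat(x$rules, sep = "\n")
  cat("\nAntecedent sets (normalized units):\n")
  print(x$sets, row.names = FALSE)
  cat("\nConsequent coefficients:\n")
  print(x$coef)
  cat(sprintf("\nTraining: n = %d, MAE = %.4g, RMSE = %.4g\n",
              x$n, x$mae, x$rmse))
  invisible(x)
}

#' @export
coef.ts_fuzzy <- function(object, ...) {
  t(vapply(object$model$rules,
           function(r) c(r$coefficients, `(Intercept)` = r$intercept),
           numeric(length(object$variables) + 1L)))
}

#' @export
predict.ts_fuzzy <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss))
    stop("newdata lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  Xn <- as.matrix(apply_normalizer(
    as.data.frame(newdata, check.names = FALSE)[object$variables],
    object$normalizer))
  infer(object$model, Xn)
}

#' @export
fitted.ts_fuzzy <- function(object, ...) object$fitted.values

#' @export
residuals.ts_fuzzy <- function(object, ...) object$residuals

#' @export
simulate.ts_fuzzy <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) object$fitted.values
        else predict(object, newdata)
  sd_res <- stats::sd(object$residuals)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         sd_res)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the membership functions of a fitted model
#'
#' One panel per input variable, showing each rule's Gaussian set over the
#' normalized \[0, 1\] universe; don't-care clauses are omitted.
#'
#' @param x A `ts_fuzzy` fit (or pass a bare [ts_model()] to
#'   `plot_memberships`).
#' @param ... Unused.
#' @export
plot.ts_fuzzy <- function(x, ...) plot_memberships(x$model)

#' @rdname plot.ts_fuzzy
#' @param model A [ts_model()].
#' @export
plot_memberships <- function(model, ...) {
  stopifnot(inherits(model, "ts_model"))
  nv <- length(model$variables)
  old <- graphics::par(mfrow = c(ceiling(nv / 2), min(nv, 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in model$variables) {
    u <- model$universe[[v]]
    g <- seq(u[1], u[2], length.out = 400)
    graphics::plot(NULL, xlim = u, ylim = c(0, 1), xlab = v,
                   ylab = "membership", main = v)
    for (j in seq_along(model$rules)) {
      s <- model$rules[[j]]$sets[[v]]
      if (is.null(s)) next
      graphics::lines(g, membership(s, g), col = j, lwd = 2)
    }
    graphics::legend("topright", bty = "n", cex = 0.8,
                     legend = vapply(seq_along(model$rules), function(j) {
                       s <- model$rules[[j]]$sets[[v]]
                       if (is.null(s)) sprintf("rule %d: any value", j)
                       else sprintf("rule %d: %s", j, s$label)
                     }, character(1)),
                     col = seq_along(model$rules), lty = 1)
  }
  invisible(model)
}
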