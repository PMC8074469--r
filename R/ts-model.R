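#' First-order Takagi-Sugeno rule
#'
#' A rule of the form
#' `IF x1 is A_1 AND ... AND xN is A_N THEN y = a' x + b`,
#' where each antecedent clause is either a Gaussian fuzzy set or a don't-care
#' marker (`NULL`), and the consequent is affine in all model variables.
#'
#' @param sets Named list over the model variables; each element is a
#'   [gaussian_set()] or `NULL` for a don't-care clause.
#' @param coefficients Named numeric vector of consequent slopes, aligned to
#'   the model variables.
#' @param intercept Consequent intercept.
#' @return An object of class `ts_rule`.
#' @export
ts_rule <- function(sets, coefficients, intercept) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            is.numeric(coefficients), is.numeric(intercept),
            length(intercept) == 1L)
  if (is.null(names(coefficients)))
    names(coefficients) <- names(sets)
  if (!setequal(names(sets), names(coefficients)))
    stop("antecedent and consequent variable names disagree", call. = FALSE)
  coefficients <- coefficients[names(sets)]
  ok <- vapply(sets, function(s) is.null(s) || inherits(s, "gaussian_set"),
               logical(1))
  if (!all(ok))
    stop("each antecedent clause must be a gaussian_set or NULL (don't-care)",
         call. = FALSE)
  structure(list(sets = sets, coefficients = coefficients,
                 intercept = unname(intercept)),
            class = "ts_rule")
}

#' First-order Takagi-Sugeno fuzzy model
#'
#' An ordered set of input variables and rules sharing that ordering. Inference
#' uses the minimum t-norm for the degree of fulfillment and a firing-weighted
#' average of the affine rule outputs.
#'
#' @param variables Character vector of input variable names (order matters).
#' @param rules List of [ts_rule()] objects.
#' @param universe Per-variable universe of discourse used for set similarity;
#'   either a length-2 interval shared by all variables (default `c(0, 1)`,
#'   matching min-max normalized inputs) or a named list of intervals.
#' @param target Name of the output variable (used when printing rules).
#' @param normalization Optional list recording the input/target scaling
#'   contract the consequents were fitted under (see [fit_normalizer()]).
#' @return An object of class `ts_model`.
#' @export
ts_model <- function(variables, rules, universe = c(0, 1), target = "y",
                     normalization = NULL) {
  stopifnot(is.character(variables), length(variables) >= 1L,
            !anyDuplicated(variables), is.list(rules), length(rules) >= 1L)
  for (r in rules) {
    if (!inherits(r, "ts_rule"))
      stop("all rules must be ts_rule objects", call. = FALSE)
    if (!identical(names(r$sets), variables))
      stop("rule variables must match the model's variable ordering",
           call. = FALSE)
  }
  if (!is.list(universe)) {
    stopifnot(length(universe) == 2L, universe[1] < universe[2])
    universe <- stats::setNames(rep(list(universe), length(variables)),
                                variables)
  }
  stopifnot(setequal(names(universe), variables))
  structure(list(variables = variables, rules = rules,
                 universe = universe[variables], target = target,
                 normalization = normalization),
            class = "ts_model")
}

#' @export
print.ts_model <- function(x, digits = 4, ...) {
  cat(sprintf("Takagi-Sugeno fuzzy model: %d rule(s), %d input(s) -> %s\n",
              length(x$rules), length(x$variables), x$target))
  cat(export_rules(x, digits = digits), sep = "\n")
  invisible(x)
}

align_input <- function(x, variables) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (!is.null(colnames(x))) {
      miss <- setdiff(variables, colnames(x))
      if (length(miss))
        stop("input is missing variable(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      x <- x[, variables, drop = FALSE]
    } else if (ncol(x) != length(variables)) {
      stop(sprintf("input has %d columns but the model has %d variables",
                   ncol(x), length(variables)), call. = FALSE)
    }
    return(x)
  }
  if (!is.null(names(x))) {
    miss <- setdiff(variables, names(x))
    if (length(miss))
      stop("input is missing variable(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[variables]
  } else if (length(x) != length(variables)) {
    stop(sprintf("input has length %d but the model has %d variables",
                 length(x), length(variables)), call. = FALSE)
  }
  matrix(as.numeric(x), nrow = 1L, dimnames = list(NULL, variables))
}

#' Degree of fulfillment of a rule
#'
#' Minimum t-norm over the antecedent clause memberships; don't-care clauses
#' contribute membership 1 (equivalently, they are excluded from the minimum).
#'
#' @param rule A [ts_rule()].
#' @param x Input vector aligned to the rule's variables (named or positional),
#'   or a matrix/data frame of inputs (one row per case).
#' @return Firing degree(s) in \[0, 1\].
#' @export
firing_degree <- function(rule, x) {
  stopifnot(inherits(rule, "ts_rule"))
  xm <- align_input(x, names(rule$sets))
  beta <- rep(1, nrow(xm))
  for (v in names(rule$sets)) {
    s <- rule$sets[[v]]
    if (!is.null(s)) beta <- pmin(beta, membership(s, xm[, v]))
  }
  beta
}

#' Affine consequent output of a rule
#'
#' @inheritParams firing_degree
#' @return `a' x + b` for each input row.
#' @export
rule_output <- function(rule, x) {
  stopifnot(inherits(rule, "ts_rule"))
  xm <- align_input(x, names(rule$sets))
  drop(xm %*% rule$coefficients) + rule$intercept
}

#' Takagi-Sugeno inference
#'
#' Computes the model output `y* = sum_j beta_j y_j / sum_j beta_j`, the
#' firing-weighted average of the rule outputs. Where the total firing is
#' numerically zero the weighted average is undefined; the unweighted mean of
#' the rule outputs is returned for those inputs with a warning.
#'
#' @param model A [ts_model()].
#' @param x Input vector (one case) or matrix/data frame (one row per case),
#'   on the scale the model's antecedents were defined on.
#' @return Numeric vector of model outputs.
#' @examples
#' r1 <- ts_rule(list(x = gaussian_set(0, 0.3, "low")),  c(x = 1), 0)
#' r2 <- ts_rule(list(x = gaussian_set(1, 0.3, "high")), c(x = -1), 2)
#' m <- ts_model("x", list(r1, r2))
#' infer(m, c(x = 0.5))
#' @export
infer <- function(model, x) {
  stopifnot(inherits(model, "ts_model"))
  xm <- align_input(x, model$variables)
  J <- length(model$rules)
  B <- vapply(model$rules, firing_degree, numeric(nrow(xm)), x = xm)
  Y <- vapply(model$rules, rule_output, numeric(nrow(xm)), x = xm)
  B <- matrix(B, nrow = nrow(xm))
  Y <- matrix(Y, nrow = nrow(xm))
  tot <- rowSums(B)
  dead <- tot <= .Machine$double.xmin * J
  out <- numeric(nrow(xm))
  if (any(!dead))
    out[!dead] <- rowSums(B[!dead, , drop = FALSE] * Y[!dead, , drop = FALSE]) /
      tot[!dead]
  if (any(dead)) {
    warning("total firing degree is zero for ", sum(dead),
            " input(s); returning the unweighted mean of rule outputs",
            call. = FALSE)
    out[dead] <- rowMeans(Y[dead, , drop = FALSE])
  }
  out
}

#' @export
predict.ts_model <- function(object, newdata, ...) {
  infer(object, newdata)
}

#' Replace one antecedent clause of a model
#'
#' Convenience for constructing worked examples and fixtures: sets the fuzzy
#' set (or don't-care) of a single rule/variable clause.
#'
#' @param model A [ts_model()].
#' @param rule Rule index.
#' @param variable Variable name.
#' @param set A [gaussian_set()] or `NULL` for don't-care.
#' @return The modified model.
#' @export
set_rule_antecedent <- function(model, rule, variable, set) {
  stopifnot(inherits(model, "ts_model"),
            rule >= 1L, rule <= length(model$rules),
            variable %in% model$variables,
            is.null(set) || inherits(set, "gaussian_set"))
  # assignment via [<- so a NULL set marks don't-care instead of dropping the slot
  model$rules[[rule]]$sets[variable] <- list(set)
  model
}
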