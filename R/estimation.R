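#' Fit Gaussian antecedent sets from a fuzzy partition
#'
#' Projects each cluster onto each input variable and fits a Gaussian fuzzy
#' set to the membership profile. The default estimator uses
#' membership-weighted moments (weights `u^m`): the weighted mean gives the
#' set center and the weighted standard deviation the spread — for a crisp
#' partition these coincide with the cluster's empirical moments.
#' `method = "nls"` refines the moment fit by nonlinear least squares on the
#' `(x, u)` scatter (Levenberg-Marquardt), falling back to the moment
#' estimates with a warning if the fit fails. Spreads are floored at
#' `sigma_floor` so degenerate (single-point) clusters stay valid sets.
#'
#' @param inputs n x N matrix or data frame of (normalized) input variables.
#' @param partition C x n membership matrix (e.g. from [fstpso_cluster()]).
#' @param m Fuzziness exponent used for the weights (default 2).
#' @param method `"moments"` (default) or `"nls"`.
#' @param sigma_floor Minimum spread, in normalized units (default 1e-3).
#' @return List over clusters; each element a named list of [gaussian_set()]s
#'   over the variables.
#' @export
fit_antecedents <- function(inputs, partition, m = 2,
                            method = c("moments", "nls"), sigma_floor = 1e-3) {
  method <- match.arg(method)
  inputs <- as.matrix(inputs)
  stopifnot(ncol(partition) == nrow(inputs), all(partition >= 0),
            all(partition <= 1 + 1e-9))
  vars <- colnames(inputs)
  if (is.null(vars)) vars <- paste0("x", seq_len(ncol(inputs)))
  lapply(seq_len(nrow(partition)), function(cl) {
    u <- partition[cl, ]
    w <- u^m
    if (sum(w) <= 0) stop("cluster ", cl, " has zero total membership",
                          call. = FALSE)
    sets <- lapply(seq_along(vars), function(v) {
      x <- inputs[, v]
      mu <- sum(w * x) / sum(w)
      sg <- sqrt(sum(w * (x - mu)^2) / sum(w))
      if (method == "nls") {
        fit <- tryCatch({
          st <- list(mu = mu, sg = max(sg, sigma_floor))
          co <- stats::coef(minpack.lm::nlsLM(
            u ~ exp(-(x - mu)^2 / (2 * sg^2)), start = st,
            lower = c(-Inf, sigma_floor),
            control = minpack.lm::nls.lm.control(maxiter = 100)))
          list(mu = unname(co[["mu"]]), sg = abs(unname(co[["sg"]])))
        }, error = function(e) NULL)
        if (is.null(fit)) {
          warning("NLS antecedent fit failed for cluster ", cl,
                  ", variable '", vars[v], "'; using moment estimates",
                  call. = FALSE)
        } else {
          mu <- fit$mu; sg <- fit$sg
        }
      }
      gaussian_set(mu, max(sg, sigma_floor))
    })
    stats::setNames(sets, vars)
  })
}

# rank cluster centers per variable and attach linguistic labels
.label_sets <- function(antecedents) {
  if (!length(antecedents)) return(antecedents)
  vars <- names(antecedents[[1]])
  J <- length(antecedents)
  labels_for <- function(k) {
    if (k == 1) "medium"
    else if (k == 2) c("low", "high")
    else if (k == 3) c("low", "medium", "high")
    else paste0("term", seq_len(k))
  }
  for (v in vars) {
    mus <- vapply(antecedents, function(a) a[[v]]$mu, numeric(1))
    lab <- labels_for(J)[rank(mus, ties.method = "first")]
    for (j in seq_len(J)) antecedents[[j]][[v]]$label <- lab[j]
  }
  antecedents
}

#' Weighted least-squares consequent estimation
#'
#' Fits each rule's affine consequent `y_j = a_j' x + b_j` by least squares
#' weighted with that rule's firing degrees; a small ridge term stabilizes the
#' normal equations against rank deficiency.
#'
#' @param inputs n x N matrix or data frame of inputs.
#' @param y Length-n target vector (original score scale).
#' @param firing J x n matrix of per-rule firing degrees.
#' @param ridge Ridge added to the normal-equation diagonal (default 1e-8).
#' @return List over rules with elements `coefficients` (named) and
#'   `intercept`.
#' @export
fit_consequents <- function(inputs, y, firing, ridge = 1e-8) {
  inputs <- as.matrix(inputs)
  firing <- matrix(firing, ncol = nrow(inputs))
  stopifnot(length(y) == nrow(inputs))
  vars <- colnames(inputs)
  if (is.null(vars)) vars <- paste0("x", seq_len(ncol(inputs)))
  X <- cbind(inputs, `(Intercept)` = 1)
  lapply(seq_len(nrow(firing)), function(j) {
    w <- firing[j, ]
    if (sum(w) <= 0)
      stop("rule ", j, " never fires on the training data", call. = FALSE)
    A <- crossprod(X * w, X) + diag(ridge, ncol(X))
    b <- crossprod(X * w, y)
    beta <- drop(solve(A, b))
    list(coefficients = stats::setNames(beta[seq_along(vars)], vars),
         intercept = unname(beta[length(beta)]))
  })
}

#' Learn a Takagi-Sugeno model from prepared data
#'
#' The estimation engine behind [ts_fuzzy()]: clusters the joint input-output
#' space with [fstpso_cluster()] (one rule per cluster), fits Gaussian
#' antecedents to the projected partition, computes firing degrees from the
#' fitted antecedents (so the final model is self-consistent), and estimates
#' the consequents by firing-weighted least squares. Inputs are expected
#' min-max normalized; `y` is used normalized for clustering but on its
#' original scale for the consequents, so model outputs are on the score
#' scale.
#'
#' @param inputs n x N matrix or data frame of normalized inputs in \[0, 1\].
#' @param y Length-n target on its original scale.
#' @param n_clusters Number of rules/clusters (default 2).
#' @param m Fuzziness exponent (default 2).
#' @param max_iter FST-PSO iterations (default 100).
#' @param seed Integer seed.
#' @param weighting `"antecedent"` (default) computes consequent weights from
#'   the fitted Gaussian antecedents; `"partition"` uses the raw fuzzy
#'   partition.
#' @param consequent_fit `"global"` (default) estimates all rules' consequents
#'   jointly by least squares on the firing-normalized mixture
#'   `y ~ sum_j gamma_j(x) (a_j' x + b_j)`, which recovers the generating
#'   parameters when the model class matches the data; `"local"` fits each
#'   rule separately by firing-weighted least squares ([fit_consequents()]),
#'   which yields more autonomous per-rule local models but biases the
#'   parameters wherever rules overlap.
#' @param target Output variable name.
#' @param antecedent_method Passed to [fit_antecedents()].
#' @param polish Passed to [fstpso_cluster()].
#' @return A [ts_model()] with `n_clusters` rules; the cluster result is
#'   attached as attribute `"clustering"`.
#' @export
build_ts_model <- function(inputs, y, n_clusters = 2L, m = 2, max_iter = 100L,
                           seed = NULL, weighting = c("antecedent", "partition"),
                           consequent_fit = c("global", "local"), target = "y",
                           antecedent_method = "moments", polish = FALSE) {
  weighting <- match.arg(weighting)
  consequent_fit <- match.arg(consequent_fit)
  inputs <- as.matrix(inputs)
  vars <- colnames(inputs)
  if (is.null(vars)) {
    vars <- paste0("x", seq_len(ncol(inputs)))
    colnames(inputs) <- vars
  }
  stopifnot(length(y) == nrow(inputs))
  yr <- range(y)
  y_norm <- if (diff(yr) > 0) (y - yr[1]) / diff(yr) else rep(0.5, length(y))
  joint <- cbind(inputs, .target = y_norm)
  cl <- fstpso_cluster(joint, n_clusters = n_clusters, m = m,
                       max_iter = max_iter, seed = seed, polish = polish)
  antecedents <- .label_sets(
    fit_antecedents(inputs, cl$partition, m = m, method = antecedent_method))
  firing <- if (weighting == "antecedent") {
    t(vapply(antecedents, function(sets) {
      b <- rep(1, nrow(inputs))
      for (v in vars) b <- pmin(b, membership(sets[[v]], inputs[, v]))
      b
    }, numeric(nrow(inputs))))
  } else cl$partition
  consequents <- if (consequent_fit == "local") {
    fit_consequents(inputs, y, firing)
  } else {
    tot <- colSums(firing)
    if (any(tot <= 0))
      stop("some observations fire no rule; cannot normalize", call. = FALSE)
    G <- sweep(firing, 2, tot, "/")
    Xi <- cbind(inputs, `(Intercept)` = 1)
    D <- do.call(cbind, lapply(seq_len(n_clusters), function(j) Xi * G[j, ]))
    beta <- drop(solve(crossprod(D) + diag(1e-8, ncol(D)), crossprod(D, y)))
    p <- ncol(Xi)
    lapply(seq_len(n_clusters), function(j) {
      bj <- beta[((j - 1) * p + 1):(j * p)]
      list(coefficients = stats::setNames(bj[seq_along(vars)], vars),
           intercept = unname(bj[p]))
    })
  }
  rules <- lapply(seq_len(n_clusters), function(j)
    ts_rule(antecedents[[j]], consequents[[j]]$coefficients,
            consequents[[j]]$intercept))
  model <- ts_model(vars, rules, universe = c(0, 1), target = target)
  attr(model, "clustering") <- cl
  model
}
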