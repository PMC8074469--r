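#' Gaussian fuzzy set
#'
#' A linguistic term over one (usually normalized) input variable, with the
#' standard Gaussian membership function
#' \deqn{\mu(x) = \exp\{-(x - \mu_0)^2 / (2\sigma^2)\}.}
#'
#' @param mu Center of the set (membership 1).
#' @param sigma Spread, must be strictly positive.
#' @param label Linguistic label, e.g. `"low"` or `"high"`.
#' @return An object of class `gaussian_set`.
#' @examples
#' s <- gaussian_set(0.5, 0.1, "medium")
#' membership(s, c(0.5, 0.4, 0.6))
#' @export
gaussian_set <- function(mu, sigma, label = "") {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single strictly positive number", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, label = as.character(label)),
            class = "gaussian_set")
}

#' @export
print.gaussian_set <- function(x, ...) {
  cat(sprintf("Gaussian fuzzy set%s: mu = %.4g, sigma = %.4g\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$mu, x$sigma))
  invisible(x)
}

#' Membership degree of a Gaussian fuzzy set
#'
#' @param set A [gaussian_set()].
#' @param x Numeric vector of input values.
#' @return Membership degrees in \[0, 1\], vectorized over `x`.
#' @export
membership <- function(set, x) {
  stopifnot(inherits(set, "gaussian_set"), is.numeric(x))
  exp(-(x - set$mu)^2 / (2 * set$sigma^2))
}

#' Jaccard similarity of two fuzzy sets
#'
#' Ratio of the integral of the pointwise minimum to the integral of the
#' pointwise maximum of the two membership functions, evaluated on a uniform
#' grid over the variable's universe of discourse. A value of 1 means the sets
#' are identical on the universe; values near 0 mean they barely overlap.
#'
#' @param a,b [gaussian_set()] objects.
#' @param universe Length-2 numeric interval. Defaults to the union of both
#'   sets' effective supports (centers +/- 4 sigma).
#' @param n_grid Number of grid points (default 1000).
#' @return Similarity in \[0, 1\].
#' @examples
#' jaccard_similarity(gaussian_set(0, 1), gaussian_set(0.5, 1))
#' @export
jaccard_similarity <- function(a, b, universe = NULL, n_grid = 1000L) {
  stopifnot(inherits(a, "gaussian_set"), inherits(b, "gaussian_set"))
  if (is.null(universe)) {
    universe <- c(min(a$mu - 4 * a$sigma, b$mu - 4 * b$sigma),
                  max(a$mu + 4 * a$sigma, b$mu + 4 * b$sigma))
  }
  stopifnot(length(universe) == 2L, universe[1] < universe[2], n_grid >= 2L)
  g <- seq(universe[1], universe[2], length.out = n_grid)
  ma <- membership(a, g)
  mb <- membership(b, g)
  denom <- sum(pmax(ma, mb))
  if (denom <= .Machine$double.eps * n_grid)
    stop("both sets are (numerically) zero on the given universe", call. = FALSE)
  sum(pmin(ma, mb)) / denom
}
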