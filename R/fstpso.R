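# Fuzzy self-tuning particle swarm optimization of the FCM objective.
#
# Each particle encodes a full set of C cluster centers (concatenated
# coordinates); its fitness is the fuzzy c-means objective. Instead of global
# inertia/acceleration constants, every particle carries its own settings,
# re-derived each iteration by a small zero-order Sugeno rule base from two
# normalized state descriptors:
#   phi   in [-1, 1]: fitness change since the previous iteration
#                     (negative = improved),
#   delta in [0, 1] : distance from the global best, relative to the
#                     search-space diameter.
# Rule outputs are fixed singleton levels for the inertia weight, cognitive
# and social factors, and the minimum/maximum speed clamps (fractions of the
# per-dimension range).

.tri_up <- function(x) pmax(0, pmin(1, x))      # ramp 0 -> 1 on [0, 1]
.fst_levels <- list(
  inertia   = c(low = 0.3,  med = 0.5,   high = 1.0),
  cognitive = c(low = 0.1,  med = 1.5,   high = 3.0),
  social    = c(low = 1.0,  med = 2.0,   high = 3.0),
  minspeed  = c(low = 0,    med = 0.001, high = 0.01),
  maxspeed  = c(low = 0.1,  med = 0.15,  high = 0.2))

# memberships of the two state descriptors
.fst_state <- function(phi, delta) {
  c(worse = .tri_up(phi), same = 1 - pmin(1, abs(phi)),
    better = .tri_up(-phi),
    near0 = pmax(0, 1 - delta / 0.2),
    near = if (delta <= 0.2) delta / 0.2 else pmax(0, (1 - delta) / 0.8),
    far = pmax(0, (delta - 0.2) / 0.8))
}

# rule base: for each output, (firing term -> level); weighted-average defuzz
.fst_rules <- list(
  inertia   = c(worse = "low", same = "med", better = "high",
                near0 = "low", near = "med", far = "high"),
  cognitive = c(worse = "high", same = "med", better = "low"),
  social    = c(worse = "high", same = "med", better = "low",
                near0 = "low", near = "med", far = "high"),
  minspeed  = c(near0 = "low", near = "med", far = "high"),
  maxspeed  = c(near0 = "low", near = "med", far = "high"))

.fst_settings <- function(phi, delta) {
  mu <- .fst_state(phi, delta)
  vapply(names(.fst_rules), function(out) {
    rb <- .fst_rules[[out]]
    w <- mu[names(rb)]
    lv <- .fst_levels[[out]][rb]
    if (sum(w) <= 0) mean(.fst_levels[[out]]) else sum(w * lv) / sum(w)
  }, numeric(1))
}

#' Cluster with fuzzy self-tuning particle swarm optimization
#'
#' Minimizes the fuzzy c-means objective over cluster-center positions with a
#' particle swarm whose inertia, acceleration, and speed limits are adapted
#' per particle by fuzzy self-tuning rules, avoiding the premature local
#' convergence that plain alternating FCM is prone to. Data are expected
#' normalized (each dimension in \[0, 1\]); the swarm is confined to the data's
#' bounding box.
#'
#' @param data n x D numeric matrix (rows are observations).
#' @param n_clusters Number of clusters C (default 2).
#' @param m Fuzziness exponent (default 2).
#' @param max_iter Swarm iterations (default 100).
#' @param n_particles Swarm size; default `floor(10 + 2 * sqrt(C * D))`.
#' @param seed Integer seed.
#' @param polish If `TRUE`, refine the best particle with alternating FCM
#'   iterations after the swarm finishes.
#' @return Object of class `cluster_result`: `centers` (C x D), `partition`
#'   (C x n, unit column sums), `m`, `objective`, and `trace` (best objective
#'   so far per iteration, non-increasing).
#' @export
fstpso_cluster <- function(data, n_clusters = 2L, m = 2, max_iter = 100L,
                           n_particles = NULL, seed = NULL, polish = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data); D <- ncol(data); C <- as.integer(n_clusters)
  if (n < C) stop("need at least as many observations as clusters",
                  call. = FALSE)
  stopifnot(m > 1, max_iter >= 1L)
  dims <- C * D
  if (is.null(n_particles)) n_particles <- floor(10 + 2 * sqrt(dims))
  n_particles <- max(2L, as.integer(n_particles))

  lo <- rep(apply(data, 2, min), C)
  hi <- rep(apply(data, 2, max), C)
  rng <- pmax(hi - lo, .Machine$double.eps)
  diam <- sqrt(sum(rng^2))
  fitness <- function(p) fcm_objective(data, matrix(p, C, D, byrow = TRUE), m)

  run <- function() {
    X <- matrix(stats::runif(n_particles * dims, lo, hi), n_particles, dims,
                byrow = TRUE)
    V <- matrix(0, n_particles, dims)
    fit <- apply(X, 1, fitness)
    prev_fit <- fit
    P <- X; pfit <- fit
    g <- which.min(fit); G <- X[g, ]; gfit <- fit[g]
    trace <- numeric(max_iter)
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n_particles)) {
        phi <- (fit[i] - prev_fit[i]) / max(abs(prev_fit[i]), 1e-12)
        phi <- max(-1, min(1, phi))
        delta <- sqrt(sum((X[i, ] - G)^2)) / diam
        s <- .fst_settings(phi, min(1, delta))
        v <- s[["inertia"]] * V[i, ] +
          s[["cognitive"]] * stats::runif(dims) * (P[i, ] - X[i, ]) +
          s[["social"]] * stats::runif(dims) * (G - X[i, ])
        vmax <- s[["maxspeed"]] * rng
        vmin <- s[["minspeed"]] * rng
        v <- pmin(pmax(v, -vmax), vmax)
        slow <- abs(v) < vmin
        v[slow] <- sign(v[slow] + (v[slow] == 0)) * vmin[slow]
        V[i, ] <- v
        X[i, ] <- pmin(pmax(X[i, ] + v, lo), hi)
        prev_fit[i] <- fit[i]
        fit[i] <- fitness(X[i, ])
        if (fit[i] < pfit[i]) { P[i, ] <- X[i, ]; pfit[i] <- fit[i] }
        if (fit[i] < gfit) { G <- X[i, ]; gfit <- fit[i] }
      }
      trace[it] <- gfit
    }
    list(G = G, gfit = gfit, trace = trace)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  centers <- matrix(res$G, C, D, byrow = TRUE)
  objective <- res$gfit
  if (polish) {
    pol <- fcm_cluster(data, C, m, centers = centers)
    if (pol$objective < objective) {
      centers <- pol$centers; objective <- pol$objective
    }
  }
  colnames(centers) <- colnames(data)
  structure(list(centers = centers,
                 partition = fcm_partition(data, centers, m),
                 m = m, objective = objective, trace = res$trace,
                 n_particles = n_particles, max_iter = max_iter),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "FST-PSO fuzzy clustering: %d clusters, m = %g, objective = %.6g\n",
    nrow(x$centers), x$m, x$objective))
  invisible(x)
}
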