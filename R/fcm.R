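# squared Euclidean distances, n x C
.sqdist <- function(data, centers) {
  n <- nrow(data); C <- nrow(centers)
  d2 <- matrix(0, n, C)
  for (c in seq_len(C)) {
    diff <- sweep(data, 2, centers[c, ], "-")
    d2[, c] <- rowSums(diff^2)
  }
  d2
}

#' Fuzzy partition matrix induced by cluster centers
#'
#' Standard fuzzy c-means closed form:
#' `u_ic = 1 / sum_k (d_ic / d_ik)^(2/(m-1))`. Points coinciding with a
#' center receive crisp membership.
#'
#' @param data n x D numeric matrix.
#' @param centers C x D matrix of cluster centers.
#' @param m Fuzziness exponent, > 1 (default 2).
#' @return C x n membership matrix with unit column sums.
#' @export
fcm_partition <- function(data, centers, m = 2) {
  data <- as.matrix(data); centers <- as.matrix(centers)
  stopifnot(nrow(data) >= 1L, ncol(data) == ncol(centers), m > 1)
  d2 <- .sqdist(data, centers)
  C <- nrow(centers)
  U <- matrix(0, C, nrow(data))
  zero <- d2 <= .Machine$double.eps
  for (i in seq_len(nrow(data))) {
    if (any(zero[i, ])) {
      U[, i] <- zero[i, ] / sum(zero[i, ])
    } else {
      r <- d2[i, ]^(-1 / (m - 1))
      U[, i] <- r / sum(r)
    }
  }
  U
}

#' Fuzzy c-means objective
#'
#' `J_m = sum_i sum_c u_ic^m d_ic^2`, with the partition computed from the
#' centers in the standard closed form.
#'
#' @inheritParams fcm_partition
#' @return The objective value (non-negative scalar).
#' @export
fcm_objective <- function(data, centers, m = 2) {
  data <- as.matrix(data); centers <- as.matrix(centers)
  if (!nrow(data)) stop("empty data", call. = FALSE)
  U <- fcm_partition(data, centers, m)
  d2 <- .sqdist(data, centers)
  sum(t(U)^m * d2)
}

#' Plain alternating fuzzy c-means
#'
#' Classical Picard iteration (update U from V, then V from U) from random
#' initial centers. Used as the baseline optimizer that swarm-driven
#' clustering is compared against, and for optional polishing of swarm
#' results.
#'
#' @inheritParams fcm_partition
#' @param n_clusters Number of clusters.
#' @param max_iter Maximum iterations.
#' @param tol Stop when the objective improves by less than `tol`.
#' @param centers Optional starting centers; random rows of `data` otherwise.
#' @param seed Integer seed for the random start.
#' @return List with `centers`, `partition`, `objective`, `iterations`.
#' @export
fcm_cluster <- function(data, n_clusters = 2L, m = 2, max_iter = 100L,
                        tol = 1e-9, centers = NULL, seed = NULL) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= n_clusters)
  if (is.null(centers)) {
    pick <- function() data[sample.int(nrow(data), n_clusters), , drop = FALSE]
    centers <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  }
  centers <- as.matrix(centers)
  obj <- Inf
  for (it in seq_len(max_iter)) {
    U <- fcm_partition(data, centers, m)
    W <- t(U)^m
    centers <- sweep(t(W) %*% data, 1, colSums(W), "/")
    new_obj <- fcm_objective(data, centers, m)
    if (is.finite(obj) && obj - new_obj < tol) { obj <- new_obj; break }
    obj <- new_obj
  }
  list(centers = centers, partition = fcm_partition(data, centers, m),
       objective = obj, iterations = it)
}
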