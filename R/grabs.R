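#' Build the per-variable fuzzy-set similarity graph
#'
#' Nodes are the (rule, variable) antecedent sets; two sets of the same
#' variable are linked when their Jaccard similarity on the variable's
#' universe reaches the threshold. Don't-care clauses contribute no node.
#' Connected components group sets that represent the same linguistic term
#' (similarity can chain: A ~ B and B ~ C place A and C in one component even
#' if A and C themselves fall below the threshold; components therefore also
#' report their minimum pairwise similarity).
#'
#' @param model A [ts_model()].
#' @param threshold Similarity threshold in (0, 1\] (default 0.9).
#' @param n_grid Grid size for [jaccard_similarity()].
#' @return Object of class `similarity_graph`: data frames `nodes`
#'   (`variable`, `rule`), `edges` (`variable`, `rule_a`, `rule_b`,
#'   `similarity`), and `components` (`variable`, `rule`, `component`,
#'   `min_similarity`).
#' @export
build_similarity_graph <- function(model, threshold = 0.9, n_grid = 1000L) {
  stopifnot(inherits(model, "ts_model"), threshold > 0, threshold <= 1)
  nodes <- edges <- comps <- NULL
  for (v in model$variables) {
    rl <- which(vapply(model$rules, function(r) !is.null(r$sets[[v]]),
                       logical(1)))
    if (!length(rl)) next
    nodes <- rbind(nodes, data.frame(variable = v, rule = rl))
    sim <- NULL
    if (length(rl) > 1L) {
      pr <- utils::combn(rl, 2L)
      sim <- data.frame(variable = v, rule_a = pr[1, ], rule_b = pr[2, ],
                        similarity = apply(pr, 2, function(p)
                          jaccard_similarity(model$rules[[p[1]]]$sets[[v]],
                                             model$rules[[p[2]]]$sets[[v]],
                                             universe = model$universe[[v]],
                                             n_grid = n_grid)))
    }
    keep <- if (is.null(sim)) sim else sim[sim$similarity >= threshold, ,
                                           drop = FALSE]
    if (!is.null(keep) && nrow(keep)) edges <- rbind(edges, keep)
    # connected components over this variable's nodes
    g <- igraph::graph_from_data_frame(
      d = if (is.null(keep) || !nrow(keep)) data.frame(from = character(0),
                                                       to = character(0))
          else data.frame(from = as.character(keep$rule_a),
                          to = as.character(keep$rule_b)),
      directed = FALSE, vertices = data.frame(name = as.character(rl)))
    mem <- igraph::components(g)$membership
    for (k in unique(mem)) {
      rs <- as.integer(names(mem)[mem == k])
      minsim <- if (length(rs) < 2L || is.null(sim)) 1 else {
        inside <- sim$rule_a %in% rs & sim$rule_b %in% rs
        if (any(inside)) min(sim$similarity[inside]) else 1
      }
      comps <- rbind(comps, data.frame(variable = v, rule = rs, component = k,
                                       min_similarity = minsim))
    }
  }
  structure(list(nodes = nodes,
                 edges = if (is.null(edges))
                   data.frame(variable = character(0), rule_a = integer(0),
                              rule_b = integer(0), similarity = numeric(0))
                 else edges,
                 components = comps, threshold = threshold),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "Fuzzy-set similarity graph: %d node(s), %d edge(s) at threshold %.2g\n",
    nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Graph-based rule-base simplification
#'
#' Merges, per variable, all fuzzy sets in one connected component of the
#' similarity graph into a single representative set (parameter-wise mean by
#' default, or the first member's set with `representative = "keep_first"`).
#' When after merging every rule uses the same set for a variable, the clause
#' no longer discriminates between rules and is rendered don't-care
#' (`IS any value`). The rule count never changes, and consequents are not
#' refitted unless `refit_with` supplies the training data.
#'
#' @param model A [ts_model()].
#' @param threshold Jaccard similarity threshold in (0, 1\] (default 0.9).
#' @param representative `"mean"` or `"keep_first"`.
#' @param refit_with Optional list `list(inputs =, y =)` of the training data;
#'   when given, consequents are re-estimated under the simplified
#'   antecedents.
#' @param n_grid Grid size for the similarity computation.
#' @return The simplified model; the similarity graph used is attached as
#'   attribute `"similarity_graph"`, and the merged pairs (with their
#'   similarities) as attribute `"merged_pairs"`.
#' @export
simplify_rules <- function(model, threshold = 0.9,
                           representative = c("mean", "keep_first"),
                           refit_with = NULL, n_grid = 1000L) {
  representative <- match.arg(representative)
  graph <- build_similarity_graph(model, threshold, n_grid)
  comps <- graph$components
  merged <- graph$edges[0, ]
  if (!is.null(comps)) {
    for (v in unique(comps$variable)) {
      cv <- comps[comps$variable == v, , drop = FALSE]
      for (k in unique(cv$component)) {
        rs <- cv$rule[cv$component == k]
        if (length(rs) < 2L) next
        sets <- lapply(rs, function(j) model$rules[[j]]$sets[[v]])
        rep_set <- if (representative == "keep_first") sets[[1]] else {
          lab <- sets[[1]]$label
          gaussian_set(mean(vapply(sets, `[[`, numeric(1), "mu")),
                       mean(vapply(sets, `[[`, numeric(1), "sigma")), lab)
        }
        for (j in rs) model$rules[[j]]$sets[[v]] <- rep_set
        e <- graph$edges
        merged <- rbind(merged, e[e$variable == v & e$rule_a %in% rs &
                                    e$rule_b %in% rs, , drop = FALSE])
      }
    }
  }
  # a variable whose every rule carries the same (merged) set is
  # non-discriminative: render all its clauses don't-care
  for (v in model$variables) {
    sets <- lapply(model$rules, function(r) r$sets[[v]])
    if (any(vapply(sets, is.null, logical(1)))) next
    mus <- vapply(sets, `[[`, numeric(1), "mu")
    sgs <- vapply(sets, `[[`, numeric(1), "sigma")
    if (length(model$rules) > 1L &&
        all(mus == mus[1]) && all(sgs == sgs[1])) {
      for (j in seq_along(model$rules))
        model$rules[[j]]$sets[v] <- list(NULL)
    }
  }
  if (!is.null(refit_with)) {
    firing <- t(vapply(model$rules, firing_degree,
                       numeric(nrow(as.matrix(refit_with$inputs))),
                       x = refit_with$inputs))
    cons <- fit_consequents(refit_with$inputs, refit_with$y, firing)
    for (j in seq_along(model$rules)) {
      model$rules[[j]]$coefficients <- cons[[j]]$coefficients[model$variables]
      model$rules[[j]]$intercept <- cons[[j]]$intercept
    }
  }
  attr(model, "similarity_graph") <- graph
  attr(model, "merged_pairs") <- merged
  model
}
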