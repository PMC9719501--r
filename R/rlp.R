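#' Top-ranked existing edge
#'
#' Returns the existing edge with the highest score under one method --
#' the candidate the RLP strategy would remove or control next. Ties are
#' broken by the lexicographically smallest `(u, v)` internal id pair, so
#' the choice is deterministic.
#'
#' @param g A connected igraph graph with at least one edge.
#' @param method A [score_method()] or method name.
#' @return A one-row data frame with `u`, `v`, `u_label`, `v_label`,
#'   `score`.
#' @export
top_rank <- function(g, method) {
  if (igraph::ecount(g) == 0L) stop("graph has no edges to rank")
  sc <- score_existing_edges(g, method)
  sc[order(-sc$score, sc$u, sc$v)[1L], , drop = FALSE]
}

#' Greedy connectivity-preserving edge removal
#'
#' The core RLP mitigation loop: repeatedly score all existing edges on
#' the *current* graph, take the top-ranked edge, and remove it -- but
#' only while the graph stays connected. The loop stops when the removal
#' budget is exhausted (`stopped_reason = "budget_reached"`) or when the
#' top-ranked candidate is a bridge whose removal would disconnect the
#' network (`stopped_reason = "would_disconnect"`). The removed edges, in
#' order, are the priority list of relations to control.
#'
#' Scores are recomputed after every removal by default. Two variants are
#' available for sensitivity analysis: `static_ranking = TRUE` ranks the
#' original graph once and removes down that fixed list, and
#' `skip_bridges = TRUE` passes over bridge candidates to the best
#' non-bridge edge instead of stopping. Neither variant is used for the
#' standard workflow.
#'
#' @param g A connected igraph graph.
#' @param method A [score_method()] or method name.
#' @param budget Maximum number of removals (`Inf` for unlimited).
#' @param snapshot_metrics If `TRUE`, record the largest eigenvalue and
#'   log walk count after every removal.
#' @param static_ranking Rank once on the input graph instead of
#'   rescoring each step.
#' @param skip_bridges Skip bridge candidates instead of stopping.
#' @param path_cfg A [path_count_config()] used for metric snapshots.
#' @return An object of class `removal_trace`: a list with the final
#'   graph (`$graph`), the per-step data frame (`$steps`: `step`, `u`,
#'   `v`, `u_label`, `v_label`, `score`, `lambda_after`,
#'   `pathcount_after`), the method, and `$stopped_reason`.
#' @examples
#' k4 <- igraph::make_full_graph(4)
#' tr <- iterative_removal(k4, "pa")
#' tr$steps[, c("u", "v", "score")]  # 3 removals, K4 thinned to a path
#' @export
iterative_removal <- function(g, method, budget = Inf,
                              snapshot_metrics = FALSE,
                              static_ranking = FALSE,
                              skip_bridges = FALSE,
                              path_cfg = path_count_config()) {
  method <- score_method(method)
  g <- canonicalize_graph(g)
  assert_connected(g, "iterative removal")
  stopifnot(budget >= 0)

  steps <- list()
  reason <- "budget_reached"
  run <- function() {
    static_order <- NULL
    if (static_ranking) {
      sc0 <- score_existing_edges_unseeded(g, method)
      static_order <- sc0[order(-sc0$score, sc0$u, sc0$v), , drop = FALSE]
    }
    nstep <- 0L
    while (nstep < budget && igraph::ecount(g) > 0L) {
      bridge_eids <- igraph::bridges(g)
      cand <- next_candidate(g, method, static_order, nstep,
                             bridge_eids, skip_bridges)
      if (is.null(cand)) { reason <<- "would_disconnect"; break }
      eid <- igraph::get_edge_ids(g, c(cand$u, cand$v))
      g <- igraph::delete_edges(g, eid)
      nstep <- nstep + 1L
      steps[[nstep]] <<- data.frame(
        step = nstep, u = cand$u, v = cand$v,
        u_label = cand$u_label, v_label = cand$v_label, score = cand$score,
        lambda_after = if (snapshot_metrics && igraph::ecount(g) > 0L)
          largest_eigenvalue(g) else NA_real_,
        pathcount_after = if (snapshot_metrics && igraph::ecount(g) > 0L)
          path_count(g, path_cfg) else NA_real_)
    }
    g
  }
  g_final <- with_private_seed(method$seed, run)

  structure(list(
    graph = g_final,
    method = method,
    steps = if (length(steps)) do.call(rbind, steps) else empty_steps(),
    stopped_reason = reason), class = "removal_trace")
}

# Pick the edge to remove at this step, or NULL to stop.
next_candidate <- function(g, method, static_order, nstep,
                           bridge_eids, skip_bridges) {
  is_bridge <- function(u, v) {
    igraph::get_edge_ids(g, c(u, v)) %in% bridge_eids
  }
  if (!is.null(static_order)) {
    cand <- static_order[nstep + 1L, , drop = FALSE]
    if (nrow(cand) == 0L || is.na(cand$u)) return(NULL)
    if (!is_bridge(cand$u, cand$v)) return(cand)
    if (!skip_bridges) return(NULL)
    rest <- static_order[-seq_len(nstep + 1L), , drop = FALSE]
    for (i in seq_len(nrow(rest))) {   # static list: take next non-bridge
      if (!is_bridge(rest$u[i], rest$v[i])) return(rest[i, , drop = FALSE])
    }
    return(NULL)
  }
  sc <- score_existing_edges_unseeded(g, method)
  sc <- sc[order(-sc$score, sc$u, sc$v), , drop = FALSE]
  if (!skip_bridges) {
    cand <- sc[1L, , drop = FALSE]
    if (is_bridge(cand$u, cand$v)) return(NULL)
    return(cand)
  }
  eids <- igraph::get_edge_ids(g, rbind(sc$u, sc$v))
  keep <- which(!eids %in% bridge_eids)
  if (!length(keep)) return(NULL)
  sc[keep[1L], , drop = FALSE]
}

# Like score_existing_edges but drawing random scores from the ambient
# stream (the trace-level seed is set once by iterative_removal).
score_existing_edges_unseeded <- function(g, method) {
  el <- normalized_edgelist(g)
  nm <- igraph::V(g)$name
  data.frame(u = el[, 1L], v = el[, 2L],
             u_label = nm[el[, 1L]], v_label = nm[el[, 2L]],
             score = as.numeric(raw_edge_scores(g, el, method)))
}

empty_steps <- function() {
  data.frame(step = integer(), u = integer(), v = integer(),
             u_label = character(), v_label = character(),
             score = numeric(), lambda_after = numeric(),
             pathcount_after = numeric())
}

#' @export
print.removal_trace <- function(x, ...) {
  cat("<removal_trace> ", toupper(x$method$name), ": ",
      nrow(x$steps), " removal(s), stopped: ", x$stopped_reason, "\n",
      sep = "")
  if (nrow(x$steps)) {
    show <- utils::head(x$steps, 10L)
    cat(paste0("  ", show$step, ". (", show$u_label, ", ", show$v_label,
               ") score ", signif(show$score, 6)), sep = "\n")
    if (nrow(x$steps) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Disconnectivity threshold of a score method
#'
#' The maximum number of ordered top-ranked removals a method can perform
#' before its next choice would split the network -- the "durability"
#' of the method in keeping every node pair reachable. Higher is better:
#' a method with a larger threshold can control more relations without
#' cutting the network. A tree has threshold 0 (every edge is a bridge),
#' and no method can exceed `m - n + 1` removals on a connected graph
#' (the spanning-tree bound).
#'
#' @param g A connected igraph graph.
#' @param method A [score_method()] or method name.
#' @return Integer removal count.
#' @export
disconnectivity_threshold <- function(g, method) {
  nrow(iterative_removal(g, method, budget = Inf)$steps)
}
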