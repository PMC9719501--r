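#' Score methods for ranking existing edges
#'
#' Constructs a score-method descriptor for reverse link prediction. The
#' five neighborhood-similarity methods score an existing edge (x, y) from
#' the neighbor sets G(x), G(y) of its endpoints, *as the graph stands*
#' (so y is a member of G(x) and vice versa):
#'
#' * `cn` -- common neighbors, `|G(x) & G(y)|`
#' * `jc` -- Jaccard, `|G(x) & G(y)| / |G(x) | G(y)|`
#' * `pa` -- preferential attachment, `|G(x)| * |G(y)|`
#' * `ra` -- resource allocation, `sum over common neighbors s of 1/|G(s)|`
#' * `aa` -- Adamic-Adar, `sum over common neighbors s of 1/log2 |G(s)|`
#'   (log base 2; every common neighbor of an edge's endpoints has degree
#'   >= 2, so the sum is always finite)
#'
#' plus two baselines: `eb`, exact edge betweenness centrality (the
#' standard comparison method for edge-removal epidemic control), and
#' `random`, i.i.d. Uniform(0, 1) scores from a seeded stream.
#'
#' @param name One of `"cn"`, `"jc"`, `"pa"`, `"ra"`, `"aa"`, `"eb"`,
#'   `"random"` (case-insensitive).
#' @param seed Integer seed; required for (and only used by) `random`.
#' @return An object of class `score_method`.
#' @export
score_method <- function(name, seed = NULL) {
  if (inherits(name, "score_method")) return(name)
  name <- match.arg(tolower(name),
                    c("cn", "jc", "pa", "ra", "aa", "eb", "random"))
  if (name == "random" && is.null(seed)) {
    stop("the random baseline requires a seed")
  }
  if (name != "random") seed <- NULL
  structure(list(name = name, seed = if (!is.null(seed)) as.integer(seed)),
            class = "score_method")
}

#' @export
print.score_method <- function(x, ...) {
  cat("<score_method> ", toupper(x$name),
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  invisible(x)
}

#' Neighborhood-similarity score of one existing edge
#'
#' Computes the requested similarity score for a single existing edge.
#' Only the five neighborhood methods apply here; edge betweenness is a
#' whole-graph quantity (see [edge_betweenness_scores()]).
#'
#' @param g A connected igraph graph.
#' @param u,v Internal vertex ids (1-based) of an existing edge.
#' @param method A [score_method()] or its name, among cn/jc/pa/ra/aa.
#' @return The score, a nonnegative finite number, symmetric in (u, v).
#' @examples
#' k3 <- igraph::make_full_graph(3)
#' neighbor_score(k3, 1, 2, "jc")  # 1/3
#' @export
neighbor_score <- function(g, u, v, method) {
  method <- score_method(method)
  if (!method$name %in% c("cn", "jc", "pa", "ra", "aa")) {
    stop("neighbor_score applies to the neighborhood methods cn/jc/pa/ra/aa")
  }
  u <- as.integer(u); v <- as.integer(v)
  eid <- suppressWarnings(igraph::get_edge_ids(g, c(u, v)))
  if (is.na(eid) || eid == 0L) {
    stop("(", u, ",", v, ") is not an existing edge: ",
         "reverse link prediction scores existing edges only")
  }
  el <- cbind(min(u, v), max(u, v))
  as.numeric(edge_score_values(g, el, method$name))
}

# Vectorized scores for a u<v edge matrix `el` (internal ids). Neighbor
# sets include the scored edge's opposite endpoint (no temporary removal).
edge_score_values <- function(g, el, name) {
  deg <- igraph::degree(g)
  if (name == "pa") return(deg[el[, 1L]] * deg[el[, 2L]])
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  if (name %in% c("cn", "jc")) {
    M <- A %*% A
    cn <- as.numeric(M[el])
    if (name == "cn") return(cn)
    # |union| = deg(u) + deg(v) - cn; always >= 2 for an existing edge
    return(cn / (deg[el[, 1L]] + deg[el[, 2L]] - cn))
  }
  # ra / aa: weighted two-step walks through common neighbors. Degree-1
  # nodes can never be common neighbors of an edge's endpoints; zero their
  # weight so no 1/0 or 1/log2(1) enters the product.
  w <- numeric(length(deg))
  ok <- deg >= 2
  w[ok] <- if (name == "ra") 1 / deg[ok] else 1 / log2(deg[ok])
  M <- A %*% Matrix::Diagonal(x = w) %*% A
  as.numeric(M[el])
}

#' Score every existing edge of a graph
#'
#' Applies one score method to all edges, scanning each undirected edge
#' once (u < v). `eb` dispatches to exact edge betweenness; `random`
#' draws i.i.d. Uniform(0, 1) scores from the method's seeded stream.
#'
#' @param g A connected igraph graph.
#' @param method A [score_method()] or method name.
#' @return A data frame with columns `u`, `v` (internal ids, `u < v`,
#'   rows ordered by `(u, v)`), `u_label`, `v_label`, and `score`.
#' @export
score_existing_edges <- function(g, method) {
  method <- score_method(method)
  g <- canonicalize_graph(g)
  assert_connected(g, "edge scoring")
  el <- normalized_edgelist(g)
  score <- with_private_seed(method$seed,
                             function() raw_edge_scores(g, el, method))
  nm <- igraph::V(g)$name
  data.frame(u = el[, 1L], v = el[, 2L],
             u_label = nm[el[, 1L]], v_label = nm[el[, 2L]],
             score = as.numeric(score))
}

# Scores for an edge matrix under any method, drawing from the *ambient*
# RNG stream for `random` (callers manage seeding: score_existing_edges
# seeds per call, iterative_removal seeds once per trace).
raw_edge_scores <- function(g, el, method) {
  switch(
    method$name,
    eb = {
      eb <- igraph::edge_betweenness(g, directed = FALSE)
      # edge_betweenness follows E(g) order; re-sort to (u, v) order
      raw <- igraph::as_edgelist(g, names = FALSE)
      key_raw <- paste(pmin(raw[, 1L], raw[, 2L]), pmax(raw[, 1L], raw[, 2L]))
      eb[match(paste(el[, 1L], el[, 2L]), key_raw)]
    },
    random = runif(nrow(el)),
    edge_score_values(g, el, method$name))
}

#' Exact edge betweenness centrality
#'
#' For every edge e, the betweenness `c(e)` is the sum over unordered
#' distinct node pairs \{i, j\} of the fraction of shortest i-j paths
#' passing over e, computed exactly by all-pairs shortest-path counting
#' and left unnormalized (only the ranking is consumed downstream).
#'
#' @param g A connected igraph graph.
#' @return A data frame as in [score_existing_edges()] with `score`
#'   holding `c(e)`.
#' @export
edge_betweenness_scores <- function(g) {
  score_existing_edges(g, "eb")
}
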