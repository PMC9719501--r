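# Independent oracles used to cross-check the package implementation.
# They share no code path with the package internals: betweenness is
# obtained by explicitly enumerating every shortest path from BFS
# predecessor DAGs, and walk counts by expanding every walk one step at
# a time.

# BFS from source s on an adjacency list: hop distances plus, for every
# node, the list of predecessors on shortest paths.
bfs_pred <- function(adj, s, n) {
  dist <- rep(Inf, n)
  dist[s] <- 0
  pred <- vector("list", n)
  q <- s
  while (length(q)) {
    u <- q[1L]
    q <- q[-1L]
    for (w in adj[[u]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[u] + 1
        q <- c(q, w)
      }
      if (dist[w] == dist[u] + 1) pred[[w]] <- c(pred[[w]], u)
    }
  }
  list(dist = dist, pred = pred)
}

# All shortest s->t paths as vertex sequences, by backtracking the
# predecessor DAG.
enum_shortest_paths <- function(pred, s, t) {
  if (t == s) return(list(s))
  out <- list()
  for (p in pred[[t]]) {
    for (sub in enum_shortest_paths(pred, s, p)) {
      out[[length(out) + 1L]] <- c(sub, t)
    }
  }
  out
}

# Exact unnormalized edge betweenness by brute-force path enumeration,
# returned in the (u, v)-sorted edge order used by the package.
brute_edge_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  score <- stats::setNames(numeric(nrow(el)), paste(el[, 1], el[, 2]))
  for (i in seq_len(n - 1L)) {
    b <- bfs_pred(adj, i, n)
    for (j in seq(i + 1L, n)) {
      paths <- enum_shortest_paths(b$pred, i, j)
      sigma <- length(paths)
      for (p in paths) {
        for (k in seq_len(length(p) - 1L)) {
          key <- paste(min(p[k], p[k + 1L]), max(p[k], p[k + 1L]))
          score[key] <- score[key] + 1 / sigma
        }
      }
    }
  }
  unname(score)
}

# Total number of walks with length in [min_len, max_len], counted by
# materializing every walk endpoint (one list element per walk).
brute_walk_count <- function(g, min_len = 2L, max_len = 5L) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  ends <- seq_len(igraph::vcount(g))   # the length-0 walks
  total <- 0
  for (l in seq_len(max_len)) {
    ends <- unlist(lapply(ends, function(v) adj[[v]]), use.names = FALSE)
    if (l >= min_len) total <- total + length(ends)
  }
  total
}

# Small random connected G(n, p) graph for property tests (draws from
# the ambient RNG stream; callers set the seed).
random_connected_graph <- function(n, p) {
  for (i in 1:200) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= 1 && igraph::is_connected(g)) return(g)
  }
  stop("no connected draw")
}

# Graph from 0-based node-id pairs as written in worked examples;
# internally 1-based.
graph_from_pairs0 <- function(pairs) {
  el <- matrix(unlist(pairs), ncol = 2, byrow = TRUE) + 1L
  igraph::graph_from_edgelist(el, directed = FALSE)
}
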