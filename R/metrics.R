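#' Largest adjacency eigenvalue (spectral radius)
#'
#' The largest eigenvalue of the symmetric 0/1 adjacency matrix (the
#' Perron root). For epidemic processes on a network this eigenvalue
#' controls the spreading threshold: the lower it is, the slower an
#' epidemic can propagate, which is why edge-removal mitigation methods
#' aim to reduce it.
#'
#' Computed by power iteration on the shifted operator `A + I` (the shift
#' makes the Perron root strictly dominant even on bipartite graphs,
#' whose spectrum is symmetric), with a Rayleigh-quotient estimate and a
#' 2-norm residual stopping rule, which for symmetric matrices bounds the
#' absolute eigenvalue error by the residual norm.
#'
#' @param g An igraph graph with at least one edge.
#' @param tol Absolute error tolerance (> 0).
#' @param max_iter Iteration cap; exceeded only for pathological gaps.
#' @return The largest eigenvalue, a positive real.
#' @examples
#' largest_eigenvalue(igraph::make_full_graph(4))    # 3
#' largest_eigenvalue(igraph::make_star(5, "undirected"))  # sqrt(4) = 2
#' @export
largest_eigenvalue <- function(g, tol = 1e-10, max_iter = 200000L) {
  stopifnot(igraph::ecount(g) >= 1L, tol > 0)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  # positive start vector: guaranteed overlap with the Perron vector
  x <- igraph::degree(g) + 1
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x          # (A + I) x
    lam <- sum(x * y)                     # Rayleigh quotient of A + I
    if (sqrt(sum((y - lam * x)^2)) <= tol) return(lam - 1)
    x <- y / sqrt(sum(y^2))
  }
  stop("power iteration did not converge within ", max_iter, " iterations")
}

#' Configuration for the walk-count criterion
#'
#' The criterion counts routes between node pairs by powers of the
#' Boolean adjacency matrix: the entries of `A^l` count the length-`l`
#' walks between each pair. Defaults follow the standard evaluation
#' setting: lengths 2 through 5, base-10 logarithm, ordered walks (each
#' traversal counted once per direction, exactly what summing all entries
#' of `A^l` produces) and closed walks included. The two inclusion
#' toggles are exposed because reasonable variants exist; they change the
#' count, not the method rankings at these scales.
#'
#' @param min_length,max_length Walk length range, `1 <= min <= max`.
#' @param log_base Base of the final logarithm.
#' @param include_closed_walks Count walks that return to their start?
#' @param count_ordered Count both directions of each traversal?
#' @return An object of class `path_count_config`.
#' @export
path_count_config <- function(min_length = 2L, max_length = 5L,
                              log_base = 10,
                              include_closed_walks = TRUE,
                              count_ordered = TRUE) {
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  stopifnot(min_length >= 1L, min_length <= max_length, log_base > 1)
  structure(list(min_length = min_length, max_length = max_length,
                 log_base = log_base,
                 include_closed_walks = isTRUE(include_closed_walks),
                 count_ordered = isTRUE(count_ordered)),
            class = "path_count_config")
}

#' Log walk count between graph vertices
#'
#' Sums the entries of the Boolean adjacency powers `A^l` for `l` in the
#' configured range and returns the logarithm of the total. The count is
#' a *walk* count -- the quantity matrix powers deliver, and the reason
#' the criterion stays cheap (exact simple-path counting is #P-hard).
#' Fewer routes of each length mean fewer channels an infection can
#' travel, so lower values indicate better mitigation.
#'
#' Counts are accumulated exactly in integer-valued doubles; the
#' computation aborts if the total would leave the exactly-representable
#' range (2^53) rather than return a rounded count.
#'
#' @param g An igraph graph with at least one edge.
#' @param cfg A [path_count_config()].
#' @return `log(total walks, base)`, a single real.
#' @examples
#' path_count(igraph::make_full_graph(3))  # log10(12+24+48+96) = 2.2553
#' @export
path_count <- function(g, cfg = path_count_config()) {
  stopifnot(inherits(cfg, "path_count_config"), igraph::ecount(g) >= 1L)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  lim <- 2^53
  total <- 0
  if (cfg$include_closed_walks && cfg$count_ordered) {
    # fast exact path: sum(A^l) = 1' A^l 1, by repeated mat-vec
    v <- rep(1, nrow(A))
    for (l in seq_len(cfg$max_length)) {
      v <- as.numeric(A %*% v)
      if (max(v) >= lim) stop("walk count exceeds exact integer range")
      if (l >= cfg$min_length) total <- total + sum(v)
      if (total >= lim) stop("walk count exceeds exact integer range")
    }
  } else {
    M <- as(A, "generalMatrix")
    P <- M
    for (l in seq_len(cfg$max_length)) {
      if (l > 1L) P <- P %*% M
      if (max(P) >= lim) stop("walk count exceeds exact integer range")
      if (l >= cfg$min_length) {
        s_diag <- sum(Matrix::diag(P))
        s_all <- sum(P)
        s_off <- s_all - s_diag
        if (!cfg$count_ordered) { s_off <- s_off / 2 }
        total <- total + s_off +
          if (cfg$include_closed_walks) s_diag else 0
        if (total >= lim) stop("walk count exceeds exact integer range")
      }
    }
  }
  if (total <= 0) {
    stop("no walks in the configured length range; widen the range")
  }
  log(total, base = cfg$log_base)
}

#' Descriptive network statistics
#'
#' The standard summary panel for a dataset: node and edge counts,
#' average and maximum degree, density `2m / (n (n - 1))`, diameter and
#' average shortest path length in hops over all unordered distinct
#' pairs, and the average local clustering coefficient (nodes of degree
#' < 2 contribute 0).
#'
#' @param g A connected igraph graph.
#' @return An object of class `network_stats` (a named list).
#' @export
network_stats <- function(g) {
  g <- canonicalize_graph(g)
  assert_connected(g, "network_stats (diameter is undefined otherwise)")
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  structure(list(
    nodes = n,
    edges = m,
    average_degree = 2 * m / n,
    max_degree = max(deg),
    density = if (n > 1L) 2 * m / (n * (n - 1)) else 0,
    diameter = igraph::diameter(g, directed = FALSE, weights = NA),
    average_clustering = igraph::transitivity(g, type = "localaverage",
                                              isolates = "zero"),
    average_shortest_path = igraph::mean_distance(g, directed = FALSE)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("<network_stats>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
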