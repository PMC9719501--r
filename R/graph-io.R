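#' Read a graph from an edge list or MatrixMarket file
#'
#' Reads a network stored either as a plain edge list (one edge per line,
#' whitespace or comma separated, `#`/`%` comment lines allowed, extra
#' columns such as weights or timestamps ignored) or as a MatrixMarket
#' coordinate file (pattern or real, symmetric or general) -- the dialects
#' used by the networkrepository.com and konect.cc archives. The result is
#' always a canonical simple undirected graph: self-loops are dropped,
#' duplicate and reciprocal rows collapse to a single undirected edge, and
#' any weights are discarded (the adjacency is treated as Boolean).
#'
#' Original node labels are preserved in the `name` vertex attribute;
#' internal vertex ids are contiguous, assigned in sorted label order
#' (numeric order when every label parses as a number, lexicographic
#' otherwise).
#'
#' @param path Path to the file.
#' @param format `"edgelist"`, `"mtx"`, or `"auto"` (detect from the file
#'   extension and the first line).
#' @return A canonical undirected [igraph][igraph::igraph-package] graph.
#' @seealso [largest_component()] to reduce a disconnected input to its
#'   largest component, [write_graph_file()] for the inverse operation.
#' @examples
#' tf <- tempfile(fileext = ".edges")
#' writeLines(c("# toy", "a b", "b a", "b c", "c c"), tf)
#' g <- read_graph_file(tf)
#' igraph::ecount(g)  # 2: reciprocal rows collapsed, self-loop dropped
#' @export
read_graph_file <- function(path, format = c("auto", "edgelist", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read graph file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) && grepl("^%%MatrixMarket", first)) "mtx" else "edgelist"
    }
  }
  if (format == "mtx") read_graph_mtx(path) else read_graph_edgelist(path)
}

read_graph_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no edges found in ", path)
  toks <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge row at line ", idx[bad[1L]], " of ", path,
         ": ", sQuote(lines[idx[bad[1L]]]))
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  graph_from_label_pairs(from, to, path)
}

read_graph_mtx <- function(path) {
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("cannot parse MatrixMarket file ",
                                         path, ": ", conditionMessage(e)))
  tm <- as(m, "TsparseMatrix")
  n <- max(dim(m))
  # Triplet slots are 0-based; labels are the 1-based matrix indices.
  graph_from_label_pairs(as.character(tm@i + 1L), as.character(tm@j + 1L),
                         path, n_hint = n)
}

# Shared canonical construction: labels -> sorted contiguous ids, loops
# dropped, duplicates/reciprocals collapsed.
graph_from_label_pairs <- function(from, to, path, n_hint = NULL) {
  labels <- unique(c(from, to))
  if (!is.null(n_hint) && n_hint > 0L &&
      all(grepl("^[0-9]+$", labels)) &&
      (!length(labels) || max(as.numeric(labels)) <= n_hint)) {
    labels <- as.character(seq_len(n_hint))
  }
  labels <- sort_labels(labels)
  u <- match(from, labels)
  v <- match(to, labels)
  keep <- u != v
  if (!any(keep)) stop("no edges left after canonicalization of ", path)
  el <- cbind(pmin(u[keep], v[keep]), pmax(u[keep], v[keep]))
  el <- unique(el)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < length(labels)) {
    g <- igraph::add_vertices(g, length(labels) - igraph::vcount(g))
  }
  igraph::V(g)$name <- labels
  g
}

sort_labels <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) labels[order(num)] else sort(labels)
}

#' Canonicalize a graph for RLP analysis
#'
#' Coerces any igraph object to the canonical form the removal engine
#' expects: undirected, no self-loops, no duplicate edges, Boolean
#' adjacency (weights dropped), with a `name` vertex attribute (assigned
#' as `"1" ... "n"` when missing). Canonicalization is idempotent.
#'
#' @param g An igraph object.
#' @return A simple undirected igraph graph.
#' @export
canonicalize_graph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(igraph::edge_attr(g, "weight"))) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Extract the largest connected component
#'
#' Every RLP evaluation assumes a path between all node pairs, so
#' disconnected inputs are reduced to their largest component before
#' analysis. Ties in component size are broken by the smallest minimum
#' original label (numeric-aware ordering), for determinism. A warning
#' reports how many nodes were dropped.
#'
#' @param g An igraph object (canonicalized if needed).
#' @return The induced subgraph on the largest component, relabelled to
#'   contiguous internal ids; the original labels are kept.
#' @export
largest_component <- function(g) {
  g <- canonicalize_graph(g)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest minimum label wins
    key <- vapply(best, function(ci) {
      sort_labels(igraph::V(g)$name[comp$membership == ci])[1L]
    }, "")
    best <- best[order(match(key, sort_labels(key)))][1L]
  } else {
    best <- best[1L]
  }
  keep <- which(comp$membership == best)
  warning("graph is disconnected: keeping largest component (",
          length(keep), " of ", igraph::vcount(g), " nodes)")
  igraph::induced_subgraph(g, keep)
}

#' Write a graph to an edge list or MatrixMarket file
#'
#' The inverse of [read_graph_file()]: reading the written file back
#' recovers the same node count and edge set. Edge lists are written with
#' original labels; MatrixMarket files use a `coordinate pattern symmetric`
#' header with 1-based internal indices (labels are not representable in
#' the format).
#'
#' @param g An igraph graph.
#' @param path Output path.
#' @param format `"edgelist"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "mtx")) {
  format <- match.arg(format)
  g <- canonicalize_graph(g)
  el <- normalized_edgelist(g)
  if (format == "edgelist") {
    nm <- igraph::V(g)$name
    writeLines(paste(nm[el[, 1L]], nm[el[, 2L]]), path)
  } else {
    hdr <- "%%MatrixMarket matrix coordinate pattern symmetric"
    n <- igraph::vcount(g)
    # lower-triangular entries (row >= col), as the symmetric dialect expects
    writeLines(c(hdr, paste(n, n, nrow(el)),
                 paste(el[, 2L], el[, 1L])), path)
  }
  invisible(path)
}

# Edge matrix with internal ids, each row u < v, rows sorted by (u, v).
normalized_edgelist <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el[order(el[, 1L], el[, 2L]), , drop = FALSE]
}

assert_connected <- function(g, what = "this operation") {
  if (igraph::vcount(g) > 1L && !igraph::is_connected(g)) {
    stop("graph is disconnected; ", what,
         " requires a connected graph -- apply largest_component() first")
  }
  invisible(g)
}
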