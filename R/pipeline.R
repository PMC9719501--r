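#' Compare score methods on one network
#'
#' Runs the full three-step workflow. Step 1-2: each method's greedy
#' connectivity-preserving removal runs to its disconnectivity threshold.
#' Step 3: the methods are compared "in equal conditions" at a common
#' removal count `common_k` -- the minimum threshold across methods (the
#' fastest disconnector, typically edge betweenness, sets the budget) --
#' by the largest adjacency eigenvalue and the log walk count of each
#' method's graph after its own first `common_k` removals.
#'
#' If two or more methods' eigenvalues agree within `lambda_tie_tol`, the
#' removal count is extended one step at a time and the eigenvalues
#' re-evaluated until one method attains a strict unique minimum. No
#' method ever removes past its own threshold: a method whose threshold
#' is exceeded stays evaluated at its last feasible count, and if the tie
#' never resolves before every method is exhausted the report flags it
#' (`tie_resolved = FALSE`) at the last feasible count.
#'
#' @param g A connected igraph graph.
#' @param methods A list (or character vector) of [score_method()]s.
#' @param path_cfg A [path_count_config()].
#' @param lambda_tie_tol Eigenvalue gap below which two methods count as
#'   tied; the default matches the 5-6 printed decimals at which
#'   published comparisons treat values as equal.
#' @param lambda_tol Eigensolver tolerance.
#' @return An object of class `eval_report`: per-method data frame
#'   (`$methods`: `method`, `threshold`, `k_used`, `lambda`,
#'   `path_count`), `common_k`, `k_extended`, `tie_resolved`,
#'   `best_by_lambda`, `best_by_pathcount`, and the run configuration.
#' @examples
#' rep <- compare_methods(igraph::make_full_graph(4), list("pa"))
#' rep$common_k  # 3
#' @export
compare_methods <- function(g, methods,
                            path_cfg = path_count_config(),
                            lambda_tie_tol = 5e-7,
                            lambda_tol = 1e-10) {
  g <- canonicalize_graph(g)
  assert_connected(g, "method comparison")
  methods <- lapply(methods, score_method)
  nm <- vapply(methods, function(m) m$name, "")
  if (anyDuplicated(nm)) stop("duplicate methods in comparison")

  traces <- lapply(methods, function(m) iterative_removal(g, m, Inf))
  thresholds <- vapply(traces, function(tr) nrow(tr$steps), 1L)
  common_k <- min(thresholds)
  if (common_k == 0L) {
    warning("common removal budget is 0 (some method cannot remove any ",
            "edge without disconnecting -- tree-like input); ",
            "methods are indistinguishable at k = 0")
  }

  graph_after <- function(tr, k) {
    if (k == 0L) return(g)
    st <- tr$steps[seq_len(k), , drop = FALSE]
    igraph::delete_edges(g, igraph::get_edge_ids(
      g, rbind(match(st$u_label, igraph::V(g)$name),
               match(st$v_label, igraph::V(g)$name))))
  }
  lambda_at <- function(tr, k) {
    gk <- graph_after(tr, k)
    if (igraph::ecount(gk) == 0L) 0 else largest_eigenvalue(gk, lambda_tol)
  }

  # tie-extension on lambda, each method capped at its own threshold
  k <- common_k
  max_k <- max(thresholds)
  repeat {
    k_used <- pmin(k, thresholds)
    lam <- mapply(lambda_at, traces, k_used)
    ord <- order(lam)
    tie_resolved <- length(lam) == 1L ||
      (lam[ord[2L]] - lam[ord[1L]] > lambda_tie_tol)
    if (tie_resolved || k >= max_k) break
    k <- k + 1L
  }
  pc <- mapply(function(tr, kk) path_count(graph_after(tr, kk), path_cfg),
               traces, k_used)

  per_method <- data.frame(method = nm, threshold = thresholds,
                           k_used = as.integer(k_used),
                           lambda = as.numeric(lam),
                           path_count = as.numeric(pc))
  # lambda and path count "at common k" for the standard report columns
  per_method$lambda_common_k <- mapply(lambda_at, traces,
                                       pmin(common_k, thresholds))
  per_method$path_count_common_k <-
    mapply(function(tr, kk) path_count(graph_after(tr, kk), path_cfg),
           traces, pmin(common_k, thresholds))

  structure(list(
    methods = per_method,
    common_k = as.integer(common_k),
    k_extended = as.integer(k),
    tie_resolved = tie_resolved,
    best_by_lambda = nm[which.min(per_method$lambda)],
    best_by_pathcount = nm[which.min(per_method$path_count)],
    config = list(path_cfg = unclass(path_cfg),
                  lambda_tie_tol = lambda_tie_tol,
                  lambda_tol = lambda_tol,
                  methods = nm)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> common_k = ", x$common_k,
      ", extended to k = ", x$k_extended,
      if (!x$tie_resolved) " (tie unresolved at feasibility bound)",
      "\n", sep = "")
  df <- x$methods
  df$lambda <- signif(df$lambda, 7)
  df$path_count <- signif(df$path_count, 6)
  print(df[, c("method", "threshold", "k_used", "lambda", "path_count")],
        row.names = FALSE)
  cat("best by lambda: ", toupper(x$best_by_lambda),
      "; best by path count: ", toupper(x$best_by_pathcount), "\n", sep = "")
  invisible(x)
}

#' Reproduce published per-dataset tables
#'
#' Harness for re-deriving the descriptive-statistics and comparison
#' tables on locally stored copies of the public datasets (no downloading
#' is performed). For each named file it reads the graph, reduces it to
#' its largest component, computes the summary statistics, and evaluates
#' each method's eigenvalue and log walk count after `k` removals (with
#' the per-method disconnectivity thresholds optionally included --
#' they are the expensive part). Missing files are skipped with a
#' warning.
#'
#' @param dataset_paths Named character vector: dataset name -> file path.
#' @param k Removal budget per dataset: a single integer or a named
#'   vector aligned with `dataset_paths` (published comparisons fix a
#'   per-dataset `K`).
#' @param methods Methods to evaluate.
#' @param compute_thresholds Also compute each method's disconnectivity
#'   threshold (can be slow on large graphs).
#' @param path_cfg A [path_count_config()].
#' @param out Optional CSV output path.
#' @return A data frame, one row per dataset present.
#' @export
reproduce_tables <- function(dataset_paths, k = 0L,
                             methods = c("pa", "cn", "jc", "aa", "ra", "eb"),
                             compute_thresholds = FALSE,
                             path_cfg = path_count_config(),
                             out = NULL) {
  methods <- lapply(methods, score_method)
  mnames <- vapply(methods, function(m) m$name, "")
  ks <- if (length(k) == 1L) stats::setNames(rep(as.integer(k),
                                                 length(dataset_paths)),
                                             names(dataset_paths))
        else as.integer(k)[names(dataset_paths)]
  rows <- list()
  for (name in names(dataset_paths)) {
    path <- dataset_paths[[name]]
    if (!file.exists(path)) {
      warning("dataset ", name, " not found at ", path, "; skipped")
      next
    }
    g <- suppressWarnings(largest_component(read_graph_file(path)))
    st <- network_stats(g)
    row <- data.frame(dataset = name, nodes = st$nodes, edges = st$edges,
                      average_degree = st$average_degree,
                      max_degree = st$max_degree, density = st$density,
                      diameter = st$diameter,
                      average_clustering = st$average_clustering,
                      average_shortest_path = st$average_shortest_path,
                      k = ks[[name]])
    for (i in seq_along(methods)) {
      tr <- iterative_removal(g, methods[[i]],
                              budget = if (compute_thresholds) Inf
                                       else ks[[name]])
      kk <- min(ks[[name]], nrow(tr$steps))
      gk <- if (kk == 0L) g else {
        idx <- tr$steps[seq_len(kk), ]
        igraph::delete_edges(g, igraph::get_edge_ids(
          g, rbind(match(idx$u_label, igraph::V(g)$name),
                   match(idx$v_label, igraph::V(g)$name))))
      }
      row[[paste0("lambda_", mnames[i])]] <- largest_eigenvalue(gk)
      row[[paste0("pathcount_", mnames[i])]] <- path_count(gk, path_cfg)
      if (compute_thresholds) {
        row[[paste0("threshold_", mnames[i])]] <- nrow(tr$steps)
      }
    }
    rows[[name]] <- row
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    empty_reproduction_frame(mnames, compute_thresholds)
  rownames(res) <- NULL
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}

empty_reproduction_frame <- function(mnames, compute_thresholds) {
  cols <- c("dataset", "nodes", "edges", "average_degree", "max_degree",
            "density", "diameter", "average_clustering",
            "average_shortest_path", "k",
            as.vector(rbind(paste0("lambda_", mnames),
                            paste0("pathcount_", mnames),
                            if (compute_thresholds)
                              paste0("threshold_", mnames))))
  res <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                       cols))
  res$dataset <- character(0)
  res
}
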