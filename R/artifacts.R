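#' Write a removal trace as TSV
#'
#' One row per removal step with the columns `step`, `u_label`,
#' `v_label`, `method`, `score`, `lambda_after`, `pathcount_after`
#' (the last two are `NA` unless the trace was run with metric
#' snapshots). An empty trace writes the header only.
#'
#' @param trace A `removal_trace` from [iterative_removal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "removal_trace"))
  df <- trace$steps
  out <- data.frame(step = df$step, u_label = df$u_label,
                    v_label = df$v_label,
                    method = rep(trace$method$name, nrow(df)),
                    score = df$score, lambda_after = df$lambda_after,
                    pathcount_after = df$pathcount_after)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a removal trace TSV
#'
#' @param path Path written by [write_trace()].
#' @return A data frame with the trace columns.
#' @export
read_trace <- function(path) {
  read.delim(path, colClasses = c(u_label = "character",
                                  v_label = "character"))
}

#' Write / read a comparison report as JSON
#'
#' Serializes an `eval_report` with stable key order; `read_report()`
#' restores it so that a round trip is the identity on every field.
#'
#' @param report An `eval_report` from [compare_methods()].
#' @param path JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the `eval_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$methods <- as.data.frame(x$methods)
  x$common_k <- as.integer(x$common_k)
  x$k_extended <- as.integer(x$k_extended)
  structure(x, class = "eval_report")
}
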