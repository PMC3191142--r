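#' Multivariate ROI time-series container
#'
#' A `ts_matrix` holds one subject's ROI time courses: a numeric T x R matrix
#' (rows = time points, columns = regions) together with region labels and
#' the sampling interval (TR, seconds).
#'
#' @param values Numeric matrix, T rows (time) by R columns (regions).
#' @param node_labels Character vector of unique region names, length R.
#'   Defaults to `colnames(values)`.
#' @param tr_seconds Sampling interval in seconds (default 2, the EPI TR of
#'   typical resting-state protocols).
#' @return An object of class `ts_matrix`.
#' @examples
#' ts <- ts_matrix(matrix(rnorm(40), 20, 2), c("PCC", "MPFC"))
#' dim(ts$values)
#' @export
ts_matrix <- function(values, node_labels = colnames(values),
                      tr_seconds = 2) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must have at least one row and one column")
  if (anyNA(values)) stop("'values' must not contain missing values")
  if (is.null(node_labels))
    node_labels <- paste0("V", seq_len(ncol(values)))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != ncol(values))
    stop("'node_labels' must name every column")
  if (anyDuplicated(node_labels))
    stop("'node_labels' must be unique")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("'tr_seconds' must be a single positive number")
  colnames(values) <- node_labels
  structure(list(values = values, node_labels = node_labels,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("ts_matrix: %d time points x %d regions (TR = %g s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  cat("regions:", paste(x$node_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ts_matrix <- function(x) dim(x$values)

#' Read and write ROI time series as tabular text
#'
#' Plain TSV with a header row of region labels and one row per time point —
#' the on-disk interchange format used by the synthetic-cohort writer and the
#' pipeline.
#'
#' @param ts A [ts_matrix()].
#' @param path File path.
#' @param tr_seconds Sampling interval to attach on read (not stored in the
#'   table itself).
#' @return `read_timeseries` returns a [ts_matrix()]; `write_timeseries`
#'   returns `path` invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "ts_matrix"))
  utils::write.table(ts$values, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, tr_seconds = 2) {
  if (!file.exists(path)) stop("no such time-series file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  ts_matrix(as.matrix(tab), node_labels = colnames(tab),
            tr_seconds = tr_seconds)
}

# internal: validate a single column selection against a ts_matrix
.get_column <- function(ts, label) {
  i <- match(label, ts$node_labels)
  if (is.na(i)) stop("unknown region label: ", label)
  ts$values[, i]
}
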