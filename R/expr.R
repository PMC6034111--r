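#' Expression matrix with sample metadata
#'
#' Container for a log2 expression matrix (genes in rows, samples in
#' columns) together with per-sample metadata: the embryonic day the
#' sample was taken, a replicate id, and a batch id. Gene symbols are
#' the row names and may be duplicated until [collapse_probes()] is
#' applied.
#'
#' @param values numeric matrix, genes x samples; row names are gene
#'   symbols, column names sample ids.
#' @param meta data.frame with columns `sample_id`, `day`, `replicate`,
#'   `batch`; one row per sample column of `values`.
#' @return An object of class `tn_expr`: a list with elements `values`
#'   and `meta` (metadata rows ordered to match the columns).
#' @export
tn_expr <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene row names and sample column names")
  need <- c("sample_id", "day", "replicate", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(values), meta$sample_id)
  if (length(absent))
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (length(unique(meta$day[match(colnames(values), meta$sample_id)])) < 2)
    stop("at least two distinct time points are required")
  meta <- meta[match(colnames(values), meta$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "tn_expr")
}

#' @export
print.tn_expr <- function(x, ...) {
  cat(sprintf("tn_expr: %d genes x %d samples, days {%s}\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$meta$day)), collapse = ",")))
  invisible(x)
}

#' @export
dim.tn_expr <- function(x) dim(x$values)

#' Drop samples from an expression object
#'
#' Supports excluding individual outlier replicates (e.g. a single
#' aberrant E10 sample) before downstream analysis.
#'
#' @param expr a [tn_expr()] object.
#' @param sample_ids character vector of sample ids to remove.
#' @return the reduced `tn_expr`.
#' @export
drop_samples <- function(expr, sample_ids) {
  stopifnot(inherits(expr, "tn_expr"))
  absent <- setdiff(sample_ids, colnames(expr$values))
  if (length(absent))
    stop("unknown sample id(s): ", paste(absent, collapse = ", "))
  keep <- setdiff(colnames(expr$values), sample_ids)
  tn_expr(expr$values[, keep, drop = FALSE],
          expr$meta[expr$meta$sample_id %in% keep, , drop = FALSE])
}

#' Replicate-mean profiles per day
#'
#' Averages replicate columns so each gene is summarized by one value
#' per embryonic day, in increasing day order.
#'
#' @param expr a [tn_expr()] object.
#' @return numeric matrix genes x days; column names are the day values.
#' @export
replicate_means <- function(expr) {
  stopifnot(inherits(expr, "tn_expr"))
  days <- sort(unique(expr$meta$day))
  out <- vapply(days, function(d) {
    cols <- expr$meta$sample_id[expr$meta$day == d]
    rowMeans(expr$values[, cols, drop = FALSE])
  }, numeric(nrow(expr$values)))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), as.character(days)))
  out
}

# z-scale rows; zero-variance rows become all-zero (logged) rather than NaN
scale_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    message(sum(flat), " constant profile(s) scaled to zeros")
    sdv[flat] <- 1
  }
  out <- (m - mu) / sdv
  out[flat, ] <- 0
  out
}
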