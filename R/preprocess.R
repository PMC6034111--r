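#' Collapse duplicate probe rows to one row per gene
#'
#' When several probes map to the same gene symbol, the row with the
#' largest interquartile range (IQR, type-7 quantiles) across all
#' samples is kept and the rest discarded. Ties go to the first
#' occurrence in file order and are logged.
#'
#' @param expr a [tn_expr()] object, possibly with duplicated row names.
#' @return a [tn_expr()] with one row per gene symbol, in order of
#'   first occurrence.
#' @export
collapse_probes <- function(expr) {
  stopifnot(inherits(expr, "tn_expr"))
  genes <- rownames(expr$values)
  if (!anyDuplicated(genes)) return(expr)
  iqr <- apply(expr$values, 1, stats::IQR, type = 7)
  keep <- integer(0)
  for (g in unique(genes)) {
    idx <- which(genes == g)
    best <- idx[which.max(iqr[idx])]  # which.max: first max wins ties
    if (length(idx) > 1 && sum(iqr[idx] == iqr[best]) > 1)
      message("IQR tie for gene '", g, "': keeping first occurrence")
    keep <- c(keep, best)
  }
  tn_expr(expr$values[keep, , drop = FALSE], expr$meta)
}

#' Median-center batches per gene
#'
#' For each gene, each batch's values are shifted so its median equals
#' the gene's grand median. With balanced batches (each batch covering
#' every day) the time trend is preserved. A simple declared stand-in
#' for empirical-Bayes batch correction, sufficient for additive
#' per-batch offsets.
#'
#' @param expr a [tn_expr()] object with batch labels.
#' @return the centered [tn_expr()].
#' @export
center_batches <- function(expr) {
  stopifnot(inherits(expr, "tn_expr"))
  batches <- expr$meta$batch
  ub <- unique(batches)
  if (length(ub) <= 1) return(expr)
  days <- unique(expr$meta$day)
  for (b in ub) {
    if (!all(days %in% expr$meta$day[batches == b])) {
      warning("batch '", b, "' does not cover every day; ",
              "batch centering may distort the time trend")
      break
    }
  }
  vals <- expr$values
  grand <- apply(vals, 1, stats::median)
  for (b in ub) {
    cols <- which(batches == b)
    if (length(cols) < 2) {
      warning("batch '", b, "' has fewer than 2 samples; left uncentered")
      next
    }
    med_b <- apply(vals[, cols, drop = FALSE], 1, stats::median)
    vals[, cols] <- vals[, cols] - med_b + grand
  }
  tn_expr(vals, expr$meta)
}

#' Principal component analysis of the sample structure
#'
#' Samples are observations and genes features; features are centered
#' but not scaled (covariance PCA). Variance fractions come from the
#' squared singular values.
#'
#' @param expr a [tn_expr()] object.
#' @param n_components number of components to retain
#'   (<= min(genes, samples)).
#' @return list of class `tn_pca` with `variance_fraction` (length
#'   `n_components`, non-increasing) and `scores` (samples x
#'   components, annotated with the sample days).
#' @export
run_pca <- function(expr, n_components = 3) {
  stopifnot(inherits(expr, "tn_expr"))
  x <- t(expr$values)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(genes, samples)")
  if (all(apply(x, 2, stats::var) == 0))
    stop("constant expression matrix: zero variance")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  structure(list(variance_fraction = vf[seq_len(n_components)],
                 all_variance_fraction = vf,
                 scores = scores,
                 day = expr$meta$day[match(rownames(scores),
                                           expr$meta$sample_id)]),
            class = "tn_pca")
}
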