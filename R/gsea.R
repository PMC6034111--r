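#' Per-gene differential t statistics against a baseline day
#'
#' For every gene and every non-baseline day, a two-sample t test of
#' that day's replicates against the baseline day's replicates. The
#' pooled equal-variance form is the default: with few replicates it
#' is exactly t-distributed when group variances match, which keeps
#' downstream Stouffer combination calibrated; `pooled = FALSE`
#' selects Welch's unequal-variance form for robustness against
#' heteroscedastic groups.
#'
#' @param expr a [tn_expr()] object.
#' @param baseline_day day used as reference (default 6).
#' @param pooled use the pooled-variance t (default) instead of Welch.
#' @return list of class `tn_tstats` with matrices `t`, `p`, `df`
#'   (genes x non-baseline days) and the vector `days`.
#' @export
gene_t_stats <- function(expr, baseline_day = 6, pooled = TRUE) {
  stopifnot(inherits(expr, "tn_expr"))
  days <- sort(unique(expr$meta$day))
  if (!baseline_day %in% days)
    stop("baseline day ", baseline_day, " not present")
  cols_of <- function(d) expr$meta$sample_id[expr$meta$day == d]
  b_cols <- cols_of(baseline_day)
  if (length(b_cols) < 2)
    stop("fewer than 2 replicates at baseline day ", baseline_day)
  other <- setdiff(days, baseline_day)
  x0 <- expr$values[, b_cols, drop = FALSE]
  n0 <- ncol(x0)
  m0 <- rowMeans(x0)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  tmat <- pmat <- dmat <- matrix(NA_real_, nrow(expr$values), length(other),
                                 dimnames = list(rownames(expr$values),
                                                 as.character(other)))
  for (j in seq_along(other)) {
    cols <- cols_of(other[j])
    if (length(cols) < 2)
      stop("fewer than 2 replicates at day ", other[j])
    x1 <- expr$values[, cols, drop = FALSE]
    n1 <- ncol(x1)
    m1 <- rowMeans(x1)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    if (pooled) {
      sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
      se2 <- sp2 * (1 / n1 + 1 / n0)
      df <- rep(n1 + n0 - 2, length(se2))
    } else {
      se2 <- v1 / n1 + v0 / n0
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    }
    tt <- (m1 - m0) / sqrt(se2)
    zero <- se2 == 0
    tt[zero & (m1 == m0)] <- 0
    df[!is.finite(df)] <- n1 + n0 - 2
    pp <- 2 * stats::pt(-abs(tt), df)
    pp[tt == 0] <- 1
    tmat[, j] <- tt; pmat[, j] <- pp; dmat[, j] <- df
  }
  structure(list(t = tmat, p = pmat, df = dmat, days = other,
                 baseline_day = baseline_day), class = "tn_tstats")
}

# signed z from a t statistic via matching two-sided quantiles,
# computed on the log scale for numerical stability at extreme t
t_to_z <- function(t, df) {
  lp <- stats::pt(-abs(t), df, log.p = TRUE)     # log(p_two / 2)
  z <- -stats::qnorm(lp, log.p = TRUE)           # |z|
  z[!is.finite(z)] <- 0
  sign(t) * z
}

#' Stouffer combination of signed z scores
#'
#' Z = sum(z_i) / sqrt(k), with a two-sided normal p value.
#'
#' @param z_values numeric vector of finite signed z scores.
#' @return list with elements `z` and `p`.
#' @export
stouffer_combine <- function(z_values) {
  if (!length(z_values)) stop("empty z vector")
  if (!all(is.finite(z_values))) stop("non-finite z value")
  z <- sum(z_values) / sqrt(length(z_values))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q values; order-preserving and bounded by 1.
#'
#' @param p_values numeric vector of p values in \[0,1\].
#' @return q values in the input order.
#' @export
bh_correct <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Time-resolved gene-set analysis
#'
#' Per-gene two-sample t statistics against the baseline day are converted
#' to signed z scores; per set and time point the member z scores are
#' combined by Stouffer's method; per set the time-point Z values are
#' combined again into a summary p, which is BH-corrected across
#' sets. Only sets with three or more measured members are tested.
#'
#' @param expr a [tn_expr()] object (unique gene rows).
#' @param sets a `tn_genesets` collection.
#' @param baseline_day reference day (default 6).
#' @param min_set_size minimum post-intersection set size (default 3).
#' @param pooled passed to [gene_t_stats()].
#' @return list of class `tn_gsea`: `z` and `p` matrices (set x
#'   timepoint), `set_table` (set, n_genes, summary_z, summary_p, q)
#'   and `per_timepoint` long table.
#' @export
run_gsea <- function(expr, sets, baseline_day = 6, min_set_size = 3,
                     pooled = TRUE) {
  stopifnot(inherits(expr, "tn_expr"))
  genes <- rownames(expr$values)
  if (anyDuplicated(genes)) stop("collapse duplicate gene rows first")
  measured <- lapply(sets, intersect, genes)
  sizes <- lengths(measured)
  dropped_genes <- sum(lengths(sets) - sizes)
  if (dropped_genes)
    message(dropped_genes, " set member(s) absent from the matrix dropped")
  keep <- sizes >= min_set_size
  if (sum(!keep))
    message(sum(!keep), " set(s) with fewer than ", min_set_size,
            " measured members excluded")
  if (!any(keep)) stop("no gene set with >= ", min_set_size,
                       " measured members")
  measured <- measured[keep]
  ts <- gene_t_stats(expr, baseline_day, pooled = pooled)
  zgene <- t_to_z(ts$t, ts$df)
  zset <- t(vapply(measured, function(m)
    colSums(zgene[m, , drop = FALSE]) / sqrt(length(m)),
    numeric(length(ts$days))))
  dimnames(zset) <- list(names(measured), as.character(ts$days))
  pset <- 2 * stats::pnorm(-abs(zset))
  zsum <- rowSums(zset) / sqrt(ncol(zset))
  psum <- 2 * stats::pnorm(-abs(zsum))
  q <- bh_correct(psum)
  set_table <- data.frame(set = names(measured), n_genes = lengths(measured),
                          summary_z = zsum, summary_p = psum, q = q,
                          row.names = NULL, stringsAsFactors = FALSE)
  per_tp <- data.frame(set = rep(rownames(zset), times = ncol(zset)),
                       day = rep(ts$days, each = nrow(zset)),
                       z = as.vector(zset), p = as.vector(pset),
                       stringsAsFactors = FALSE)
  structure(list(z = zset, p = pset, set_table = set_table,
                 per_timepoint = per_tp, baseline_day = baseline_day),
            class = "tn_gsea")
}

#' Scaled mean set profiles with hierarchical clustering
#'
#' Per set: the mean over member genes of the replicate-mean
#' expression per time point, z-scaled across time points
#' (zero-variance profiles become zeros). Rows are clustered by
#' Euclidean distance with complete linkage.
#'
#' @param expr a [tn_expr()] object.
#' @param sets a `tn_genesets` collection.
#' @param selected_sets names of the sets to profile.
#' @return list with `profiles` (set x timepoint matrix), `order`
#'   (dendrogram leaf order) and the `hclust` object (NULL for a
#'   single set).
#' @export
set_profiles <- function(expr, sets, selected_sets) {
  stopifnot(inherits(expr, "tn_expr"))
  absent <- setdiff(selected_sets, names(sets))
  if (length(absent))
    stop("unknown set(s): ", paste(absent, collapse = ", "))
  rm_ <- replicate_means(expr)
  prof <- t(vapply(selected_sets, function(nm) {
    m <- intersect(sets[[nm]], rownames(rm_))
    if (!length(m)) stop("set '", nm, "' has no measured members")
    colMeans(rm_[m, , drop = FALSE])
  }, numeric(ncol(rm_))))
  dimnames(prof) <- list(selected_sets, colnames(rm_))
  prof <- scale_rows(prof)
  if (nrow(prof) < 2)
    return(list(profiles = prof, order = seq_len(nrow(prof)), hclust = NULL))
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "complete")
  list(profiles = prof, order = hc$order, hclust = hc)
}
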