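#' Quadratic fit to one gene time series
#'
#' Ordinary least squares of a second-order polynomial on the
#' rescaled day axis tau = (day - mid) / halfrange in \[-1, 1\].
#' Replicate values at the same day are averaged before fitting, so
#' every time point carries equal weight regardless of replicate
#' count. The quadratic coefficient `a2` is reported on the tau
#' scale; any affine change of the day axis only multiplies it by a
#' positive constant, leaving gene rankings unchanged.
#'
#' @param days numeric vector of day values (>= 3 distinct).
#' @param values numeric vector of the same length.
#' @return list with `a0`, `a1`, `a2`, `peak_day` (vertex mapped back
#'   to day units when `a2 < 0` and the vertex is interior, else NA)
#'   and `r2`.
#' @export
fit_quadratic <- function(days, values) {
  stopifnot(length(days) == length(values))
  ud <- sort(unique(days))
  if (length(ud) < 3) stop("need at least 3 distinct days")
  y <- vapply(ud, function(d) mean(values[days == d]), numeric(1))
  mid <- (min(ud) + max(ud)) / 2
  half <- (max(ud) - min(ud)) / 2
  tau <- (ud - mid) / half
  X <- cbind(1, tau, tau^2)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  a0 <- beta[1]; a1 <- beta[2]; a2 <- beta[3]
  peak <- NA_real_
  if (a2 < 0) {
    tstar <- -a1 / (2 * a2)
    if (abs(tstar) <= 1) peak <- mid + tstar * half
  }
  list(a0 = a0, a1 = a1, a2 = a2, peak_day = peak,
       r2 = if (tss > 0) 1 - rss / tss else 1)
}

#' Quadratic fits for every gene in an expression object
#'
#' Vectorized version of [fit_quadratic()] over all genes (one OLS
#' solve for the whole matrix of replicate-mean profiles).
#'
#' @param expr a [tn_expr()] object.
#' @return data.frame of class `tn_fits`: gene, a0, a1, a2, peak_day,
#'   r2.
#' @export
fit_quadratic_all <- function(expr) {
  stopifnot(inherits(expr, "tn_expr"))
  y <- replicate_means(expr)
  ud <- as.numeric(colnames(y))
  if (length(ud) < 3) stop("need at least 3 distinct days")
  mid <- (min(ud) + max(ud)) / 2
  half <- (max(ud) - min(ud)) / 2
  tau <- (ud - mid) / half
  X <- cbind(1, tau, tau^2)
  beta <- t(solve(crossprod(X), t(X) %*% t(y)))   # genes x 3
  fitted <- beta %*% t(X)
  rss <- rowSums((y - fitted)^2)
  tss <- rowSums((y - rowMeans(y))^2)
  a1 <- beta[, 2]; a2 <- beta[, 3]
  tstar <- -a1 / (2 * a2)
  peak <- ifelse(a2 < 0 & abs(tstar) <= 1, mid + tstar * half, NA_real_)
  structure(data.frame(gene = rownames(y), a0 = beta[, 1], a1 = a1, a2 = a2,
                       peak_day = peak,
                       r2 = ifelse(tss > 0, 1 - rss / tss, 1),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("tn_fits", "data.frame"))
}

#' Transience scores with apoptosis gene-set weighting
#'
#' The raw transience score of a gene is the negated quadratic
#' coefficient of its time-series fit (-a2): a mid-series peak gives a
#' concave fit (a2 < 0), hence a positive score. Each score is then
#' shifted by +weight if the gene belongs to any of the configured
#' apoptosis sets and by -weight otherwise (default weight 2), so that
#' subgraph extraction favors transient, apoptosis-annotated genes.
#'
#' @param expr a [tn_expr()] object with unique gene rows.
#' @param apoptosis_sets names of the gene sets whose union defines
#'   the apoptosis annotation.
#' @param sets a `tn_genesets` collection.
#' @param weight positive shift magnitude (default 2).
#' @return data.frame of class `tn_scores`: gene, a2, raw_score,
#'   go_flag, weighted_score.
#' @export
score_genes <- function(expr, apoptosis_sets, sets, weight = 2) {
  stopifnot(inherits(expr, "tn_expr"), weight > 0)
  if (anyDuplicated(rownames(expr$values)))
    stop("collapse duplicate gene rows first")
  fits <- fit_quadratic_all(expr)
  known <- intersect(apoptosis_sets, names(sets))
  if (length(known) < length(apoptosis_sets))
    warning("apoptosis set(s) not in collection: ",
            paste(setdiff(apoptosis_sets, names(sets)), collapse = ", "))
  union_genes <- unique(unlist(sets[known], use.names = FALSE))
  if (!length(union_genes))
    warning("empty apoptosis-set union: all go_flags are FALSE")
  raw <- -fits$a2
  flag <- fits$gene %in% union_genes
  structure(data.frame(gene = fits$gene, a2 = fits$a2, raw_score = raw,
                       go_flag = flag,
                       weighted_score = raw + ifelse(flag, weight, -weight),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("tn_scores", "data.frame"))
}
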