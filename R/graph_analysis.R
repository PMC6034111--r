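# Module structure, enrichment and centrality of an extracted subnetwork.

as_igraph <- function(x) {
  if (inherits(x, "tn_subgraph")) {
    if (is.null(x$graph)) stop("empty subgraph")
    x$graph
  } else if (igraph::is_igraph(x)) x
  else stop("expected an igraph or tn_subgraph")
}

#' Spin-glass module detection
#'
#' Partitions a connected subnetwork into modules by minimizing the
#' Reichardt-Bornholdt spin-glass Hamiltonian with a
#' configuration-model null, optimized by simulated annealing
#' (igraph's spin-glass community finder); the best of `n_restarts`
#' runs by modularity is kept. Deterministic given `seed`.
#'
#' @param subgraph connected igraph or `tn_subgraph` with >= 2 nodes.
#' @param gamma resolution parameter of the null-model term
#'   (default 1).
#' @param seed integer seed.
#' @param n_restarts independent annealing runs (default 5).
#' @return list of class `tn_modules`: `assignment` (named integer,
#'   module ids contiguous from 1), `modularity`, `sizes`, `gamma`,
#'   `seed`.
#' @export
detect_modules <- function(subgraph, gamma = 1, seed = 1L, n_restarts = 5L) {
  g <- as_igraph(subgraph)
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes")
  if (!igraph::is_connected(g)) stop("subgraph must be connected")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cm <- igraph::cluster_spinglass(g, spins = 25, gamma = gamma,
                                    weights = NA)
    q <- igraph::modularity(g, igraph::membership(cm))
    if (is.null(best) || q > best$q) best <- list(q = q, cm = cm)
  }
  if (best$q < 0) {   # never worse than the trivial single-module partition
    best$q <- 0
    memb <- rep(1L, igraph::vcount(g))
  } else {
    memb <- as.integer(igraph::membership(best$cm))
  }
  memb <- match(memb, unique(memb))          # contiguous ids from 1
  names(memb) <- igraph::V(g)$name
  structure(list(assignment = memb, modularity = best$q,
                 sizes = as.integer(table(memb)), gamma = gamma,
                 seed = seed), class = "tn_modules")
}

#' Module significance by degree-preserving rewiring
#'
#' Null model: the subgraph is rewired preserving the degree
#' sequence, and each null graph is re-partitioned by fast modularity
#' optimization. The statistic is a module's embeddedness — the
#' fraction of its edge stubs that stay internal, 2 e_in / sum(deg) —
#' and each observed module is compared against the maximum
#' embeddedness over the null partition's modules, so the test
#' conditions on the fact that modules were themselves found by
#' optimization. p = (1 + #\{null >= observed\}) / (1 + n_rewires).
#' A declared surrogate procedure: it asks whether a module is more
#' self-contained than the best module findable in a degree-matched
#' random graph.
#'
#' @param subgraph connected igraph or `tn_subgraph`.
#' @param partition a `tn_modules` partition of its nodes.
#' @param n_rewires null replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return named numeric vector of per-module p values.
#' @export
module_significance <- function(subgraph, partition, n_rewires = 1000L,
                                seed = 1L) {
  g <- as_igraph(subgraph)
  stopifnot(inherits(partition, "tn_modules"))
  if (n_rewires < 100) warning("fewer than 100 rewires: p values are coarse")
  memb <- partition$assignment[igraph::V(g)$name]
  if (anyNA(memb)) stop("partition does not cover every subgraph node")
  deg <- igraph::degree(g)
  embeddedness <- function(gr, mm) {
    el <- igraph::as_edgelist(gr, names = FALSE)
    d <- igraph::degree(gr)
    ids <- sort(unique(mm))
    vapply(ids, function(m) {
      inm <- mm == m
      e_in <- sum(inm[el[, 1]] & inm[el[, 2]])
      stubs <- sum(d[inm])
      if (stubs == 0) 0 else 2 * e_in / stubs
    }, numeric(1))
  }
  obs <- embeddedness(g, unname(memb))
  set.seed(seed)
  exceed <- numeric(length(obs))
  niter <- max(100L, 10L * igraph::ecount(g))
  for (b in seq_len(n_rewires)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    null_part <- igraph::membership(igraph::cluster_louvain(gr))
    null_max <- max(embeddedness(gr, as.integer(null_part)))
    exceed <- exceed + (null_max >= obs - 1e-12)
  }
  stats::setNames((1 + exceed) / (1 + n_rewires),
                  paste0("M", sort(unique(memb))))
}

#' Conditional hypergeometric gene-set enrichment of modules
#'
#' Upper-tail hypergeometric test of each (module, set) overlap
#' against a background gene universe (typically all interactome
#' nodes). When a parent/child set hierarchy is supplied, children
#' are tested first and a parent's test conditions on its significant
#' children by removing the child's genes from both the module and
#' the parent set (single conditioning level). BH correction across
#' all (module, set) pairs.
#'
#' @param modules a `tn_modules` partition.
#' @param sets a `tn_genesets` collection.
#' @param background character vector of background genes (must
#'   contain every module gene).
#' @param hierarchy optional data.frame with columns `parent`,
#'   `child` (set names).
#' @param child_alpha raw-p threshold for a child to condition its
#'   parent (default 0.05).
#' @return data.frame of class `tn_enrichment`: module, set, k, n, K,
#'   N, p, q.
#' @export
hypergeom_enrich <- function(modules, sets, background, hierarchy = NULL,
                             child_alpha = 0.05) {
  stopifnot(inherits(modules, "tn_modules"))
  background <- unique(background)
  miss <- setdiff(names(modules$assignment), background)
  if (length(miss))
    stop("background lacks module gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  N <- length(background)
  sets_bg <- lapply(sets, intersect, background)
  mod_ids <- sort(unique(modules$assignment))
  hyper_p <- function(k, K, n)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)

  rows <- list()
  for (m in mod_ids) {
    mod_genes <- names(modules$assignment)[modules$assignment == m]
    plain <- lapply(names(sets_bg), function(nm) {
      K <- length(sets_bg[[nm]])
      k <- length(intersect(mod_genes, sets_bg[[nm]]))
      data.frame(module = m, set = nm, k = k, n = length(mod_genes),
                 K = K, N = N, p = hyper_p(k, K, length(mod_genes)),
                 stringsAsFactors = FALSE)
    })
    plain <- do.call(rbind, plain)
    if (!is.null(hierarchy)) {
      for (pa in intersect(unique(hierarchy$parent), plain$set)) {
        kids <- intersect(hierarchy$child[hierarchy$parent == pa],
                          plain$set)
        sig_kids <- kids[plain$p[match(kids, plain$set)] < child_alpha]
        if (!length(sig_kids)) next
        strip <- unique(unlist(sets_bg[sig_kids], use.names = FALSE))
        mg <- setdiff(mod_genes, strip)
        ps <- setdiff(sets_bg[[pa]], strip)
        i <- match(pa, plain$set)
        plain$k[i] <- length(intersect(mg, ps))
        plain$n[i] <- length(mg)
        plain$K[i] <- length(ps)
        plain$p[i] <- hyper_p(plain$k[i], plain$K[i], plain$n[i])
      }
    }
    rows[[length(rows) + 1]] <- plain
  }
  out <- do.call(rbind, rows)
  out$q <- bh_correct(out$p)
  structure(out, class = c("tn_enrichment", "data.frame"))
}

#' Betweenness and eigenvector centrality with hub classification
#'
#' Unweighted shortest-path betweenness (non-normalized) and
#' eigenvector centrality (leading adjacency eigenvector scaled to
#' max 1). A node is `central` when both centralities are in the top
#' decile, `peripheral` when both lie in the bottom half, else
#' `intermediate`. Peripheral nodes are candidate upstream activators
#' or downstream effectors; central nodes are candidate regulators.
#'
#' @param subgraph connected igraph or `tn_subgraph`.
#' @return data.frame of class `tn_centrality`: node, betweenness,
#'   eigenvector, betweenness_pct, eigenvector_pct, class.
#' @export
centralities <- function(subgraph) {
  g <- as_igraph(subgraph)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  eig <- igraph::eigen_centrality(g, weights = NA)$vector  # scaled to max 1
  n <- igraph::vcount(g)
  pct <- function(x) rank(x, ties.method = "average") / n
  bp <- pct(btw); ep <- pct(eig)
  cls <- ifelse(bp >= 0.9 & ep >= 0.9, "central",
                ifelse(bp <= 0.5 & ep <= 0.5, "peripheral", "intermediate"))
  structure(data.frame(node = igraph::V(g)$name, betweenness = btw,
                       eigenvector = eig, betweenness_pct = bp,
                       eigenvector_pct = ep, class = cls,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("tn_centrality", "data.frame"))
}

#' Anchor-gene ego network with peak-time ordering
#'
#' Induced subgraph on the anchor genes plus all of their direct
#' neighbors, with nodes annotated by the peak day of their quadratic
#' time-series fit and ordered ascending by it (genes without an
#' interior peak sort last).
#'
#' @param graph igraph interactome.
#' @param anchors character vector of anchor genes (all must be
#'   present).
#' @param fits a `tn_fits` table from [fit_quadratic_all()].
#' @return list with `graph` (the ego igraph, vertex attribute
#'   `peak_day`) and `ordering` (data.frame gene, peak_day, ascending).
#' @export
ego_network <- function(graph, anchors, fits) {
  absent <- setdiff(anchors, igraph::V(graph)$name)
  if (length(absent))
    stop("anchor(s) not in graph: ", paste(absent, collapse = ", "))
  nb <- unlist(igraph::adjacent_vertices(graph, anchors), use.names = FALSE)
  members <- union(anchors, igraph::V(graph)$name[as.integer(nb)])
  sub <- igraph::induced_subgraph(graph, members)
  peak <- fits$peak_day[match(igraph::V(sub)$name, fits$gene)]
  igraph::V(sub)$peak_day <- peak
  ord <- order(is.na(peak), peak, igraph::V(sub)$name)
  list(graph = sub,
       ordering = data.frame(gene = igraph::V(sub)$name[ord],
                             peak_day = peak[ord], row.names = NULL,
                             stringsAsFactors = FALSE))
}

#' Scaled per-gene profile table with complete-linkage row order
#'
#' Per-gene replicate-mean profiles z-scaled across time points
#' (constant genes become zero rows), with rows ordered by
#' Euclidean-distance complete-linkage clustering. This is the table
#' behind a scaled-expression heatmap of a gene list.
#'
#' @param expr a [tn_expr()] object.
#' @param genes character vector of measured genes.
#' @return list with `profiles` (gene x timepoint), `order` and the
#'   `hclust` object (NULL for a single gene).
#' @export
scaled_profile_heatmap_table <- function(expr, genes) {
  stopifnot(inherits(expr, "tn_expr"))
  absent <- setdiff(genes, rownames(expr$values))
  if (length(absent))
    stop("unmeasured gene(s): ", paste(absent, collapse = ", "))
  prof <- replicate_means(expr)[genes, , drop = FALSE]
  prof <- scale_rows(prof)
  if (nrow(prof) < 2)
    return(list(profiles = prof, order = seq_len(nrow(prof)), hclust = NULL))
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "complete")
  list(profiles = prof, order = hc$order, hclust = hc)
}
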