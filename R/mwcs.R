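# Maximum-weight connected subgraph (MWCS) extraction: the objective
# is the sum of node scores over a connected vertex set; edge
# confidences annotate but do not enter the objective.

# normalize a score input (named vector or tn_scores table) to a
# named vector over the graph's nodes; nodes without a score are an error
score_vector <- function(scores, nodes) {
  if (inherits(scores, "tn_scores") || is.data.frame(scores)) {
    s <- stats::setNames(scores$weighted_score, scores$gene)
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    s <- scores
  } else stop("scores must be a tn_scores table or a named numeric vector")
  miss <- setdiff(nodes, names(s))
  if (length(miss))
    stop("unscored node(s): ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  s[nodes]
}

# strong pruning on a BFS spanning tree rooted at `root` (defaults to
# the best-scoring node): bottom-up subtree sums, branches with
# sum <= 0 are dropped
strong_prune <- function(sub, s, root_name = NULL) {
  n <- igraph::vcount(sub)
  if (n <= 1) return(sub)
  vn <- igraph::V(sub)$name
  root <- if (is.null(root_name)) which.max(s[vn]) else match(root_name, vn)
  bf <- igraph::bfs(sub, root = root, father = TRUE)
  ordv <- as.integer(bf$order)
  father <- as.integer(bf$father)
  val <- unname(s[vn])
  branch_ok <- rep(TRUE, n)
  for (v in rev(ordv)) {           # children before parents
    f <- father[v]
    if (is.na(f)) next
    if (val[v] > 0) val[f] <- val[f] + val[v] else branch_ok[v] <- FALSE
  }
  keep <- rep(FALSE, n)
  keep[root] <- TRUE
  for (v in ordv) {                # parents before children
    f <- father[v]
    if (!is.na(f) && keep[f] && branch_ok[v]) keep[v] <- TRUE
  }
  igraph::induced_subgraph(sub, vn[keep])
}

subgraph_result <- function(graph, nodes, scores, method, penalty = NA_real_,
                            seed = NA_integer_) {
  if (length(nodes)) {
    sub <- igraph::induced_subgraph(graph, nodes)
    el <- igraph::as_edgelist(sub)
    conf <- igraph::E(sub)$confidence
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        confidence = if (is.null(conf)) rep(NA_real_, nrow(el))
                                     else conf,
                        stringsAsFactors = FALSE)
    total <- sum(scores[nodes])
  } else {
    sub <- NULL
    edges <- data.frame(from = character(0), to = character(0),
                        confidence = numeric(0))
    total <- 0
  }
  structure(list(nodes = sort(nodes), edges = edges, graph = sub,
                 total_score = total, penalty_weight = penalty,
                 method = method, seed = seed), class = "tn_subgraph")
}

#' @export
print.tn_subgraph <- function(x, ...) {
  cat(sprintf("tn_subgraph (%s): %d nodes, %d edges, total score %.4g\n",
              x$method, length(x$nodes), nrow(x$edges), x$total_score))
  invisible(x)
}

#' Exact maximum-weight connected subgraph
#'
#' Enumerates every connected vertex subset (rooted at its
#' minimum-index vertex so each subset is visited once) and returns
#' the one with maximal total node score. The empty subgraph (score
#' 0) is admissible. Ties break toward fewer nodes, then the
#' lexicographically smallest sorted node set. Guarded to graphs of
#' at most `guard` nodes.
#'
#' @param graph igraph with vertex names.
#' @param scores `tn_scores` table or named numeric vector.
#' @param guard maximum graph size (default 20).
#' @return a `tn_subgraph` result with `method = "exact"`.
#' @export
solve_exact <- function(graph, scores, guard = 20L) {
  n <- igraph::vcount(graph)
  if (n > guard)
    stop("graph has ", n, " > ", guard,
         " nodes; use solve_heuristic() at this scale")
  nodes <- igraph::V(graph)$name
  s <- unname(score_vector(scores, nodes))
  adj <- igraph::as_adj_list(graph)
  nbrs <- lapply(adj, function(v) sort(as.integer(v)))

  best <- list(score = 0, set = integer(0))
  consider <- function(set) {
    sc <- sum(s[set])
    if (sc > best$score + 1e-12) {
      best <<- list(score = sc, set = set)
    } else if (abs(sc - best$score) <= 1e-12 && length(best$set)) {
      if (length(set) < length(best$set) ||
          (length(set) == length(best$set) &&
           paste(sort(nodes[set]), collapse = "\r") <
           paste(sort(nodes[best$set]), collapse = "\r")))
        best <<- list(score = sc, set = set)
    }
  }
  # enumerate connected supersets of `set`; cand: frontier vertices that
  # may still be added; banned: vertices excluded on this branch
  enum <- function(set, cand, banned) {
    consider(set)
    while (length(cand)) {
      v <- cand[1]
      cand <- cand[-1]
      grow <- setdiff(nbrs[[v]], c(set, banned, cand, v))
      grow <- grow[grow > set[1]]
      enum(c(set, v), c(cand, grow), banned)
      banned <- c(banned, v)
    }
  }
  for (root in seq_len(n)) {
    cand <- nbrs[[root]]
    enum(root, cand[cand > root], integer(0))
  }
  subgraph_result(graph, nodes[best$set], stats::setNames(s, nodes), "exact")
}

#' Heuristic maximum-weight connected subgraph
#'
#' Steiner-tree style search for genome-scale graphs: (1) nodes with
#' positive score are terminals; (2) a terminal metagraph is built
#' from shortest paths whose length accumulates
#' `max(0, -score) + eps` over interior nodes; (3) its minimum
#' spanning tree is (4) expanded back to full paths; (5) negative
#' nodes whose removal keeps the subgraph connected are pruned, worst
#' first; (6) neighbors with positive score are greedily added to
#' convergence; pruning and adding alternate until stable. The result
#' is connected, deterministic given the inputs, and never worse than
#' the best single terminal.
#'
#' @param graph igraph with vertex names; a disconnected graph is
#'   logged and searched per component, keeping the best-scoring
#'   result.
#' @param scores `tn_scores` table or named numeric vector.
#' @param seed integer recorded in the result (the search itself is
#'   deterministic).
#' @param penalty_weight optional annotation stored in the result.
#' @return a `tn_subgraph` result with `method = "heuristic"`.
#' @export
solve_heuristic <- function(graph, scores, seed = 1L,
                            penalty_weight = NA_real_) {
  set.seed(seed)
  comp <- igraph::components(graph)
  if (comp$no > 1) {
    message("graph is disconnected; searching each component")
    parts <- lapply(seq_len(comp$no), function(k) {
      sub <- igraph::induced_subgraph(graph, which(comp$membership == k))
      suppressWarnings(solve_heuristic(sub, scores, seed = seed,
                                       penalty_weight = penalty_weight))
    })
    best <- parts[[which.max(vapply(parts, `[[`, numeric(1), "total_score"))]]
    if (best$total_score <= 0)
      warning("no positive-score nodes: empty subgraph")
    return(best)
  }
  nodes <- igraph::V(graph)$name
  s <- score_vector(scores, nodes)
  terminals <- nodes[s[nodes] > 0]
  if (!length(terminals)) {
    warning("no positive-score nodes: empty subgraph")
    return(subgraph_result(graph, character(0), s, "heuristic",
                           penalty_weight, seed))
  }
  terminals <- sort(terminals)
  eps <- 1e-6
  cost <- pmax(-s, 0) + eps   # argument order keeps the names
  el <- igraph::as_edgelist(graph)
  ew <- (cost[el[, 1]] + cost[el[, 2]]) / 2

  keep <- terminals
  if (length(terminals) > 1) {
    D <- igraph::distances(graph, v = terminals, to = terminals, weights = ew)
    # subtract endpoint half-costs: interior cost only
    D <- D - outer(cost[terminals] / 2, cost[terminals] / 2, "+")
    D[D < 0] <- 0
    idx <- which(upper.tri(D), arr.ind = TRUE)
    meta <- igraph::graph_from_data_frame(
      data.frame(from = terminals[idx[, 1]], to = terminals[idx[, 2]],
                 weight = D[idx]), directed = FALSE)
    mst <- igraph::mst(meta, weights = igraph::E(meta)$weight)
    mel <- igraph::as_edgelist(mst)
    for (i in seq_len(nrow(mel))) {
      sp <- igraph::shortest_paths(graph, from = mel[i, 1], to = mel[i, 2],
                                   weights = ew)$vpath[[1]]
      keep <- union(keep, igraph::V(graph)$name[as.integer(sp)])
    }
  }

  sub0 <- igraph::induced_subgraph(graph, keep)

  refine <- function(sub, root) {
    iter <- 0L
    repeat {
      changed <- FALSE
      iter <- iter + 1L
      # strong pruning: cut branches with non-positive cumulative score
      pruned <- strong_prune(sub, s, root)
      if (igraph::vcount(pruned) < igraph::vcount(sub)) {
        sub <- pruned
        changed <- TRUE
      }
      # drop the worst negative node that is not a cut vertex
      repeat {
        vn <- igraph::V(sub)$name
        if (length(vn) <= 1) break
        arts <- igraph::V(sub)$name[
          as.integer(igraph::articulation_points(sub))]
        removable <- setdiff(vn[s[vn] < 0], arts)
        if (!length(removable)) break
        worst <- removable[order(s[removable], removable)][1]
        sub <- igraph::delete_vertices(sub, worst)
        changed <- TRUE
      }
      # absorb positive-score neighbors
      repeat {
        cur <- igraph::V(sub)$name
        nb <- unique(unlist(igraph::adjacent_vertices(graph, cur),
                            use.names = FALSE))
        nb <- setdiff(igraph::V(graph)$name[nb], cur)
        nb <- nb[s[nb] > 0]
        if (!length(nb)) break
        sub <- igraph::induced_subgraph(graph, c(cur, nb))
        changed <- TRUE
      }
      if (!changed || iter > 50L) break
    }
    sub
  }

  # the pruning outcome depends on the tree root; try the top-scoring
  # terminals and keep the best refined subgraph
  roots <- intersect(igraph::V(sub0)$name, terminals)
  roots <- roots[order(-s[roots], roots)]
  roots <- utils::head(roots, 10L)
  found <- character(0); found_score <- -Inf
  for (root in roots) {
    cand <- igraph::V(refine(sub0, root))$name
    cand_score <- sum(s[cand])
    better <- cand_score > found_score + 1e-12 ||
      (abs(cand_score - found_score) <= 1e-12 &&
         length(cand) < length(found))
    if (better) { found <- cand; found_score <- cand_score }
  }
  best_single <- terminals[which.max(s[terminals])]
  if (found_score < s[best_single])
    found <- best_single
  subgraph_result(graph, found, s, "heuristic", penalty_weight, seed)
}

#' Subgraph size as a function of the gene-set weight
#'
#' Re-solves the heuristic MWCS for each weight in `weights`, shifting
#' raw transience scores by +/- the weight according to the apoptosis
#' flag. Larger weights penalize unannotated genes more, so the
#' subgraph shrinks toward the annotated core.
#'
#' @param graph igraph interactome.
#' @param raw_scores named numeric vector of raw transience scores
#'   (or a `tn_scores` table, whose `raw_score`/`go_flag` columns are
#'   used).
#' @param go_flags named logical vector (ignored when `raw_scores` is
#'   a table).
#' @param weights positive, sorted weight values.
#' @param seed passed to [solve_heuristic()].
#' @return data.frame: weight, n_nodes, n_edges, total_score.
#' @export
penalty_sweep <- function(graph, raw_scores, go_flags = NULL,
                          weights = c(0.5, 1, 2, 4), seed = 1L) {
  if (inherits(raw_scores, "tn_scores") || is.data.frame(raw_scores)) {
    go_flags <- stats::setNames(raw_scores$go_flag, raw_scores$gene)
    raw_scores <- stats::setNames(raw_scores$raw_score, raw_scores$gene)
  }
  stopifnot(all(weights > 0), !is.unsorted(weights), !is.null(go_flags))
  rows <- lapply(weights, function(w) {
    s <- raw_scores + ifelse(go_flags[names(raw_scores)], w, -w)
    r <- solve_heuristic(graph, s, seed = seed, penalty_weight = w)
    data.frame(weight = w, n_nodes = length(r$nodes),
               n_edges = nrow(r$edges), total_score = r$total_score)
  })
  do.call(rbind, rows)
}

#' Degree distribution of an extracted subgraph
#'
#' @param result a non-empty `tn_subgraph`.
#' @return list with `histogram` (table of node degrees),
#'   `max_degree`, `mean_degree` and `frac_degree_one`.
#' @export
degree_distribution <- function(result) {
  stopifnot(inherits(result, "tn_subgraph"))
  if (!length(result$nodes)) stop("empty subgraph has no degrees")
  deg <- table(factor(c(result$edges$from, result$edges$to),
                      levels = result$nodes))
  deg <- as.integer(deg)
  list(histogram = table(deg), max_degree = max(deg),
       mean_degree = mean(deg), frac_degree_one = mean(deg == 1))
}
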