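# Independent oracles and tiny fixtures used across the suite.

# small expression object built directly in code
toy_expr <- function(values, days, reps = ncol(values) / length(days)) {
  ids <- paste0("S", seq_len(ncol(values)))
  colnames(values) <- ids
  meta <- data.frame(sample_id = ids,
                     day = rep(days, each = reps),
                     replicate = rep(seq_len(reps), times = length(days)),
                     batch = 1L)
  tn_expr(values, meta)
}

# expression object from per-gene day profiles plus i.i.d. noise
profile_expr <- function(profiles, days, reps = 4, noise_sd = 0, seed = 1) {
  set.seed(seed)
  v <- profiles[, rep(seq_along(days), each = reps), drop = FALSE]
  v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow = nrow(v))
  ids <- sprintf("D%g_R%d", rep(days, each = reps),
                 rep(seq_len(reps), times = length(days)))
  colnames(v) <- ids
  meta <- data.frame(sample_id = ids, day = rep(days, each = reps),
                     replicate = rep(seq_len(reps), times = length(days)),
                     batch = 1L)
  tn_expr(v, meta)
}

# named random graph (possibly disconnected)
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# igraph from an explicit edge list over named nodes
named_graph <- function(edges, nodes = sort(unique(c(edges)))) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes)
  if (length(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

# exhaustive MWCS: every vertex subset, connectivity by bitmask BFS
mwcs_oracle <- function(graph, s) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 16)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  nbmask <- vapply(seq_len(n),
                   function(i) sum(2^(which(A[i, ] > 0) - 1)), numeric(1))
  best <- 0; best_set <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    bits <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    reach <- 2^(bits[1] - 1)
    repeat {
      inreach <- bits[bitwAnd(reach, 2^(bits - 1)) > 0]
      nxt <- bitwAnd(Reduce(bitwOr, c(reach, nbmask[inreach])), mask)
      if (nxt == reach) break
      reach <- nxt
    }
    if (reach == mask) {
      sc <- sum(s[bits])
      if (sc > best) { best <- sc; best_set <- bits }
    }
  }
  list(score = best, set = igraph::V(graph)$name[best_set])
}

# betweenness by shortest-path counting from adjacency powers:
# sigma_st = (A^d(s,t))[s,t]; contribution sigma_sv sigma_vt / sigma_st
betweenness_oracle <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  pow <- vector("list", n)
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- Ak %*% A
    pow[[k]] <- Ak
    D[D == Inf & Ak > 0] <- k
  }
  diag(D) <- 0
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    d <- D[s, t]
    if (!is.finite(d) || d < 2) next
    sigma <- pow[[d]][s, t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      d1 <- D[s, v]; d2 <- D[v, t]
      if (is.finite(d1) && is.finite(d2) && d1 + d2 == d)
        btw[v] <- btw[v] + pow[[d1]][s, v] * pow[[d2]][v, t] / sigma
    }
  }
  stats::setNames(btw, igraph::V(graph)$name)
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# modularity of a partition from its definition
modularity_oracle <- function(graph, memb) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  k <- rowSums(A)
  m2 <- sum(k)
  sum((A - outer(k, k) / m2) * outer(memb, memb, "==")) / m2
}
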