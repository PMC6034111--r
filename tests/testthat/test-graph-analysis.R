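two_cliques <- function() {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("v", 1:12)
  igraph::add_edges(g, c("v1", "v7"))
}

clique_ring <- function(k = 4, size = 5) {
  g <- igraph::make_empty_graph(directed = FALSE)
  for (i in seq_len(k)) g <- g + igraph::make_full_graph(size)
  igraph::V(g)$name <- paste0("v", seq_len(k * size))
  for (i in seq_len(k)) {
    a <- (i - 1) * size + 1
    b <- (i %% k) * size + 2
    g <- igraph::add_edges(g, c(paste0("v", a), paste0("v", b)))
  }
  g
}

test_that("spin-glass splits two joined cliques along the bridge", {
  g <- two_cliques()
  part <- detect_modules(g, seed = 11)
  expect_equal(max(part$assignment), 2)
  expect_length(unique(part$assignment[paste0("v", 1:6)]), 1)
  expect_length(unique(part$assignment[paste0("v", 7:12)]), 1)
  # oracle: the clique split is the best bipartition over all 2^11
  memb_best <- NULL; q_best <- -Inf
  for (mask in 0:(2^11 - 1)) {
    memb <- c(1L, 1L + as.integer(intToBits(mask))[1:11])
    q <- modularity_oracle(g, memb)
    if (q > q_best) { q_best <- q; memb_best <- memb }
  }
  expect_equal(part$modularity, q_best, tolerance = 1e-9)
})

test_that("a complete graph stays a single module", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  part <- detect_modules(g, seed = 2)
  expect_equal(max(part$assignment), 1)
  expect_gte(part$modularity, 0)
})

test_that("a ring of four cliques yields four modules", {
  g <- clique_ring()
  part <- detect_modules(g, gamma = 1, seed = 5)
  expect_equal(max(part$assignment), 4)
  for (i in 1:4) {
    block <- paste0("v", ((i - 1) * 5 + 1):(i * 5))
    expect_length(unique(part$assignment[block]), 1)
  }
})

test_that("module detection is deterministic and contiguously labeled", {
  g <- two_cliques()
  p1 <- detect_modules(g, seed = 9)
  p2 <- detect_modules(g, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(sort(unique(p1$assignment)), seq_len(max(p1$assignment)))
  expect_error(detect_modules(igraph::make_full_graph(1)), "2 nodes")
})

test_that("rewiring significance flags dense modules, not sparse ones", {
  g <- two_cliques()
  part <- detect_modules(g, seed = 3)
  p <- module_significance(g, part, n_rewires = 200, seed = 3)
  expect_true(all(p <= 1) && all(p > 0))
  expect_equal(unname(p["M1"]), 1 / 201, tolerance = 1e-12)
  expect_equal(unname(p["M2"]), 1 / 201, tolerance = 1e-12)

  # a single-node module has no internal edges: p = 1
  star <- named_graph(cbind(rep("h", 4), paste0("L", 1:4)))
  fake <- structure(list(assignment = setNames(c(1L, 2L, 2L, 2L, 2L),
                                               c("h", paste0("L", 1:4))),
                         modularity = 0, sizes = c(1L, 4L), gamma = 1,
                         seed = 1L), class = "tn_modules")
  ps <- module_significance(star, fake, n_rewires = 100, seed = 1)
  expect_equal(unname(ps["M1"]), 1)

  # Erdos-Renyi graphs carry no real module structure
  med <- sapply(1:10, function(sd) {
    gg <- rand_graph(24, 0.35, seed = 400 + sd)
    gg <- igraph::induced_subgraph(
      gg, which(igraph::components(gg)$membership == 1))
    if (igraph::vcount(gg) < 4) return(NA_real_)
    pp <- detect_modules(gg, seed = sd)
    median(module_significance(gg, pp, n_rewires = 150, seed = sd))
  })
  expect_gt(median(med, na.rm = TRUE), 0.05)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  bg <- paste0("g", 1:20)
  part <- structure(list(assignment = setNames(rep(1L, 5), bg[1:5]),
                         modularity = 0, sizes = 5L, gamma = 1, seed = 1L),
                    class = "tn_modules")
  sets <- structure(list(S = bg[1:5], none = bg[16:20]),
                    class = "tn_genesets")
  enr <- hypergeom_enrich(part, sets, bg)
  expect_equal(enr$p[enr$set == "S"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(enr$p[enr$set == "none"], 1)   # k = 0 keeps all upper mass

  # oracle: explicit sum of the hypergeometric pmf across a parameter grid
  for (N in c(15, 40, 80)) for (K in c(4, 9)) for (n in c(5, 12)) {
    k_obs <- 3
    p_or <- sum(sapply(k_obs:min(K, n), function(k)
      choose(K, k) * choose(N - K, n - k) / choose(N, n)))
    expect_equal(phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE), p_or,
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich(part, sets, bg[1:3]), "background lacks")
})

test_that("conditioning on a significant child weakens the parent", {
  bg <- paste0("g", 1:60)
  mod_genes <- bg[1:10]
  part <- structure(list(assignment = setNames(rep(1L, 10), mod_genes),
                         modularity = 0, sizes = 10L, gamma = 1, seed = 1L),
                    class = "tn_modules")
  child <- bg[1:8]
  parent <- bg[1:16]            # overlap fully explained by the child
  sets <- structure(list(parent = parent, child = child),
                    class = "tn_genesets")
  plain <- hypergeom_enrich(part, sets, bg)
  cond <- hypergeom_enrich(part, sets, bg,
                           hierarchy = data.frame(parent = "parent",
                                                  child = "child"))
  expect_gt(cond$p[cond$set == "parent"], plain$p[plain$set == "parent"])
  expect_equal(cond$p[cond$set == "child"], plain$p[plain$set == "child"])
})

test_that("centralities match closed-form values on canonical graphs", {
  star <- named_graph(cbind(rep("h", 5), paste0("L", 1:5)))
  ct <- centralities(star)
  expect_equal(ct$betweenness[ct$node == "h"], choose(5, 2))
  expect_true(all(ct$betweenness[ct$node != "h"] == 0))
  expect_equal(max(ct$eigenvector), 1)

  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- paste0("r", 1:5)
  cr <- centralities(ring)
  expect_equal(length(unique(round(cr$betweenness, 9))), 1)
  expect_equal(length(unique(round(cr$eigenvector, 6))), 1)

  p3 <- named_graph(cbind(c("a", "b"), c("b", "c")))
  cp <- centralities(p3)
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  expect_equal(cp$betweenness[cp$node == "a"], 0)
})

test_that("betweenness matches shortest-path counting on random graphs", {
  for (i in 1:20) {
    g <- rand_graph(sample(5:12, 1), 0.35, seed = 600 + i)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == 1))
    if (igraph::vcount(g) < 3) next
    ct <- centralities(g)
    oracle <- betweenness_oracle(g)
    expect_equal(setNames(ct$betweenness, ct$node), oracle[ct$node],
                 tolerance = 1e-9)
  }
})

test_that("ego networks take anchors plus direct neighbors, time-ordered", {
  g <- named_graph(cbind(c("TP53", "TP53", "MDM2", "X"),
                         c("BID", "MDM2", "GATA3", "Y")))
  fits <- data.frame(gene = c("TP53", "MDM2", "BID", "GATA3", "X", "Y"),
                     peak_day = c(8, NA, 9, 7, 6, 6))
  ego <- ego_network(g, c("TP53", "MDM2"), fits)
  expect_setequal(igraph::V(ego$graph)$name, c("TP53", "MDM2", "BID", "GATA3"))
  expect_equal(ego$ordering$gene, c("GATA3", "TP53", "BID", "MDM2"))
  expect_error(ego_network(g, "NOPE", fits), "NOPE")

  lone <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("Z")
  solo <- ego_network(lone, "Z", data.frame(gene = "Z", peak_day = NA))
  expect_equal(igraph::vcount(solo$graph), 1)
})

test_that("scaled heatmap tables cluster correlated profiles together", {
  days <- c(6, 7, 8, 9, 10, 14)
  up <- seq(0, 5)
  prof <- rbind(a = up, b = up + 2, c = rev(up), d = up * 1.5) + 7
  e <- profile_expr(prof, days, reps = 2)
  tab <- scaled_profile_heatmap_table(e, c("a", "b", "c", "d"))
  expect_equal(min(tab$hclust$height), 0, tolerance = 1e-9)  # a and b identical after scaling
  grp <- cutree(tab$hclust, 2)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_equal(grp[["a"]], grp[["d"]])
  expect_false(grp[["a"]] == grp[["c"]])
  expect_error(scaled_profile_heatmap_table(e, "zz"), "unmeasured")
})
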