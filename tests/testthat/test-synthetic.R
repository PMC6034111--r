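test_that("interactome generation is deterministic and plants a connected module", {
  d <- synthetic_design(n_genes = 10, planted_module_size = 3,
                        mean_degree = 4, rng_seed = 1)
  a <- generate_interactome(d)
  b <- generate_interactome(d)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(a$truth$planted_module_genes, b$truth$planted_module_genes)
  expect_equal(igraph::vcount(a$graph), 10)
  sub <- igraph::induced_subgraph(a$graph, a$truth$planted_module_genes)
  expect_true(igraph::is_connected(sub))
  expect_true(all(a$truth$planted_module_genes %in% a$truth$transient_genes))
})

test_that("graph invariants hold across 100 seeds at default parameters", {
  ok <- vapply(1:100, function(sd) {
    d <- synthetic_design(rng_seed = sd)
    net <- generate_interactome(d)
    g <- net$graph
    igraph::is_connected(g) &&
      !igraph::any_loop(g) && !igraph::any_multiple(g) &&
      all(igraph::E(g)$confidence > 0.4) &&
      all(igraph::E(g)$confidence <= 1) &&
      igraph::is_connected(igraph::induced_subgraph(
        g, net$truth$planted_module_genes))
  }, logical(1))
  expect_true(all(ok))
})

test_that("scale-free graphs have a heavier degree tail than Erdos-Renyi", {
  q99 <- sapply(1:20, function(sd) {
    dsf <- synthetic_design(graph_model = "scale-free", rng_seed = sd)
    der <- synthetic_design(graph_model = "Erdos-Renyi", rng_seed = sd)
    c(sf = quantile(igraph::degree(generate_interactome(dsf)$graph), 0.99),
      er = quantile(igraph::degree(generate_interactome(der)$graph), 0.99))
  })
  expect_gt(mean(q99["sf.99%", ]), mean(q99["er.99%", ]))
})

test_that("impossible designs are rejected", {
  expect_error(synthetic_design(planted_module_size = 50, n_genes = 10),
               "exceeds")
  expect_error(synthetic_design(noise_sd = -1))
  expect_error(synthetic_design(transient_peak_day = 20), "day-label")
  expect_error(
    generate_interactome(synthetic_design(n_genes = 100, mean_degree = 0.5,
                                          graph_model = "Erdos-Renyi")),
    "mean_degree")
})

test_that("noiseless expression peaks at the time point nearest the peak day", {
  d <- synthetic_design(n_genes = 60, planted_module_size = 5,
                        noise_sd = 0, peak_amplitude = 2,
                        transient_peak_day = 8.5, rng_seed = 4)
  net <- generate_interactome(d)
  expr <- generate_expression(d, net$truth)
  expect_equal(ncol(expr$values), 24)   # 6 days x 4 replicates
  rm_ <- replicate_means(expr)
  days <- as.numeric(colnames(rm_))
  nearest <- which.min(abs(days - 8.5))
  for (g in net$truth$transient_genes)
    expect_equal(which.max(rm_[g, ]), nearest, ignore_attr = TRUE)
})

test_that("zero amplitude makes transient and background genes indistinguishable", {
  a2_tr <- a2_bg <- c()
  for (sd in 1:10) {
    d <- synthetic_design(n_genes = 200, planted_module_size = 6,
                          peak_amplitude = 0, rng_seed = sd)
    net <- generate_interactome(d)
    expr <- generate_expression(d, net$truth)
    fits <- fit_quadratic_all(expr)
    tr <- fits$gene %in% net$truth$transient_genes
    a2_tr <- c(a2_tr, fits$a2[tr])
    a2_bg <- c(a2_bg, fits$a2[!tr])
  }
  expect_gt(t.test(a2_tr, a2_bg)$p.value, 0.01)
})

test_that("per-gene sample variance is unbiased for the noise variance", {
  d <- synthetic_design(n_genes = 6000, planted_module_size = 5,
                        noise_sd = 0.4, rng_seed = 11)
  net <- generate_interactome(d)
  expr <- generate_expression(d, net$truth)
  flat <- setdiff(rownames(expr$values), net$truth$transient_genes)
  v <- apply(expr$values[flat, ], 1, var)
  expect_lt(abs(mean(v) / 0.4^2 - 1), 0.05)
})

test_that("gene sets cover the planted module and respect size bounds", {
  d <- synthetic_design(n_genes = 400, planted_module_size = 12, rng_seed = 7)
  net <- generate_interactome(d)
  sets <- generate_gene_sets(net$truth, n_sets = 50, set_size_range = c(5, 40))
  expect_length(sets, 50)
  expect_true(all(lengths(sets) >= 3))
  apo <- attr(sets, "apoptosis")
  expect_true(all(net$truth$planted_module_genes %in% sets[[apo[1]]]))
  expect_true(all(unlist(sets[apo]) %in% net$truth$transient_genes))
  expect_error(generate_gene_sets(net$truth, set_size_range = c(2, 10)),
               ">= 3")
})

test_that("a fixed seed reproduces byte-identical GMT output", {
  d <- synthetic_design(n_genes = 120, planted_module_size = 6, rng_seed = 5)
  net <- generate_interactome(d)
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(generate_gene_sets(net$truth, n_sets = 12), f1)
  write_gmt(generate_gene_sets(net$truth, n_sets = 12), f2)
  expect_identical(readLines(f1), readLines(f2))
})
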