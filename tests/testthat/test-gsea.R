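test_that("t statistics match the Welch closed form and its limits", {
  x0 <- c(2.1, 2.3, 1.9, 2.2)
  x1 <- c(3.0, 3.2, 2.8, 3.1)
  vals <- rbind(c(x0, x1), c(x0, x0))
  rownames(vals) <- c("g1", "g2")
  e <- toy_expr(vals, days = c(6, 9), reps = 4)
  ts <- gene_t_stats(e, baseline_day = 6, pooled = FALSE)
  or <- t.test(x1, x0)             # Welch oracle
  expect_equal(unname(ts$t["g1", "9"]), unname(or$statistic), tolerance = 1e-6)
  expect_equal(unname(ts$p["g1", "9"]), or$p.value, tolerance = 1e-6)
  expect_equal(unname(ts$t["g2", "9"]), 0)
  expect_equal(unname(ts$p["g2", "9"]), 1)
})

test_that("near-separated groups give enormous t values", {
  set.seed(1)
  x0 <- rep(0, 4)
  x1 <- 1 + rnorm(4, 0, 1e-6)
  e <- toy_expr(rbind(g = c(x0, x1)), days = c(6, 9), reps = 4)
  ts <- gene_t_stats(e, 6)
  expect_gt(abs(ts$t["g", "9"]), 1e4)
})

test_that("too few replicates in a group is an error naming the day", {
  vals <- matrix(rnorm(5), 1, 5, dimnames = list("g", NULL))
  ids <- paste0("s", 1:5)
  colnames(vals) <- ids
  meta <- data.frame(sample_id = ids, day = c(6, 6, 7, 7, 9),
                     replicate = c(1, 2, 1, 2, 1), batch = 1)
  e <- tn_expr(vals, meta)
  expect_error(gene_t_stats(e, 6), "day 9")
})

test_that("Stouffer combination matches its closed form", {
  expect_equal(stouffer_combine(1.6449)$z, 1.6449)
  r <- stouffer_combine(c(1.96, 1.96))
  expect_equal(r$z, 2 * 1.96 / sqrt(2), tolerance = 1e-9)
  expect_equal(r$p, 2 * pnorm(-2 * 1.96 / sqrt(2)), tolerance = 1e-9)
  r0 <- stouffer_combine(c(2.5, -2.5))
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  expect_error(stouffer_combine(numeric(0)), "empty")
  # k identical copies combine to sqrt(k) * z exactly
  for (k in c(2, 5, 9))
    expect_equal(stouffer_combine(rep(0.7, k))$z, sqrt(k) * 0.7,
                 tolerance = 1e-12)
})

test_that("BH q-values match a hand step-up implementation", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(c(1, 1, 1)), c(1, 1, 1))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_correct(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("the planted apoptosis set dominates the GSEA ranking", {
  d <- synthetic_design(n_genes = 600, planted_module_size = 10, rng_seed = 33)
  net <- generate_interactome(d)
  expr <- generate_expression(d, net$truth)
  sets <- generate_gene_sets(net$truth, n_sets = 40)
  gs <- run_gsea(expr, sets, baseline_day = 6)
  top <- gs$set_table$set[which.min(gs$set_table$q)]
  expect_true(top %in% attr(sets, "apoptosis"))
})

test_that("sets below three measured members are excluded with a message", {
  d <- synthetic_design(n_genes = 100, planted_module_size = 5, rng_seed = 3)
  net <- generate_interactome(d)
  expr <- generate_expression(d, net$truth)
  sets <- generate_gene_sets(net$truth, n_sets = 10)
  sets$tiny <- net$truth$gene_universe[1:2]
  expect_message(gs <- run_gsea(expr, sets, 6), "fewer than 3")
  expect_false("tiny" %in% gs$set_table$set)
})

test_that("GSEA results are invariant to gene and set order", {
  d <- synthetic_design(n_genes = 150, planted_module_size = 6, rng_seed = 12)
  net <- generate_interactome(d)
  expr <- generate_expression(d, net$truth)
  sets <- generate_gene_sets(net$truth, n_sets = 12)
  g1 <- run_gsea(expr, sets, 6)
  set.seed(5)
  perm <- sample(nrow(expr$values))
  expr2 <- tn_expr(expr$values[perm, ], expr$meta)
  sets2 <- sets[sample(length(sets))]
  class(sets2) <- "tn_genesets"
  g2 <- run_gsea(expr2, sets2, 6)
  m <- match(g1$set_table$set, g2$set_table$set)
  expect_equal(g1$set_table$summary_p, g2$set_table$summary_p[m],
               tolerance = 1e-12)
  expect_equal(g1$set_table$q, g2$set_table$q[m], tolerance = 1e-12)
})

test_that("set profiles are z-scaled and cluster by shape", {
  days <- c(6, 7, 8, 9, 10, 14)
  up <- matrix(rep(seq(0, 5), each = 4), 4, 6, byrow = FALSE)
  peak <- matrix(rep(exp(-(days - 8.5)^2 / 2), each = 4), 4, 6, byrow = FALSE)
  prof <- rbind(up, up + 0.01, peak, peak * 1.5)
  prof <- prof + 7
  rownames(prof) <- paste0("g", 1:16)
  e <- profile_expr(prof[rep(1:16, each = 1), , drop = FALSE], days, reps = 2)
  sets <- structure(list(U1 = paste0("g", 1:4), U2 = paste0("g", 5:8),
                         P1 = paste0("g", 9:12), P2 = paste0("g", 13:16)),
                    class = "tn_genesets")
  sp <- set_profiles(e, sets, names(sets))
  expect_equal(rowMeans(sp$profiles), rep(0, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  grp <- cutree(sp$hclust, k = 2)
  expect_equal(grp[["U1"]], grp[["U2"]])
  expect_equal(grp[["P1"]], grp[["P2"]])
  expect_false(grp[["U1"]] == grp[["P1"]])
  # identical sets sit at distance zero and merge first
  sets2 <- structure(list(A = paste0("g", 1:4), B = paste0("g", 1:4),
                          C = paste0("g", 9:12)), class = "tn_genesets")
  sp2 <- set_profiles(e, sets2, names(sets2))
  expect_equal(min(sp2$hclust$height), 0, tolerance = 1e-12)
})

test_that("constant profiles scale to zeros rather than NaN", {
  vals <- matrix(5, 3, 8, dimnames = list(c("a", "b", "c"), NULL))
  e <- toy_expr(vals, days = c(6, 7, 8, 9), reps = 2)
  sets <- structure(list(S = c("a", "b", "c")), class = "tn_genesets")
  expect_message(sp <- set_profiles(e, sets, "S"), "constant")
  expect_true(all(is.finite(sp$profiles)))
})
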