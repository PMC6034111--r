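#' Design of a synthetic developmental time-course study
#'
#' Describes the simulated study: a replicated expression time course
#' over embryonic days with a scale-free (or Erdos-Renyi) interactome
#' in which a connected module of transiently expressed,
#' apoptosis-annotated genes is planted. Defaults emulate a 4x44K
#' chicken array study across embryonic days E6-E14: 6 time points
#' labeled {6,7,8,9,10,14}, 4 replicates, a minority of genes with a
#' transient mid-series peak, and a planted connected module of 12
#' such genes.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_timepoints number of time points; 6 gives the canonical
#'   day labels {6,7,8,9,10,14}, other values give consecutive days
#'   starting at 6.
#' @param n_replicates replicates per time point (default 4).
#' @param n_batches number of batches; replicates are assigned to
#'   batches in round-robin so batches stay balanced across time.
#' @param planted_module_size size of the planted connected module.
#' @param module_density probability of each additional within-module
#'   edge beyond the spanning tree (default 0.8), emulating the near-clique
#'   interconnection of pathway genes in curated interactomes.
#' @param n_transient total number of transiently expressed genes
#'   (includes the planted module; default 4x the module size).
#' @param transient_peak_day day at which transient genes peak.
#' @param peak_amplitude height of the transient bump, log2 units.
#' @param peak_sd width (sd, in days) of the Gaussian bump.
#' @param noise_sd i.i.d. Gaussian noise sd per observation, log2 units.
#' @param batch_sd sd of the additive per-batch offset, log2 units.
#' @param drift_sd sd of per-gene linear drift slopes (log2 per day)
#'   for background genes; 0 keeps background genes flat so that
#'   `peak_amplitude = 0` is an exact global null.
#' @param graph_model `"scale-free"` (preferential attachment) or
#'   `"Erdos-Renyi"`.
#' @param mean_degree target mean degree of the interactome.
#' @param rng_seed integer seed controlling all three generators.
#' @return a validated list of class `tn_design`, with `days` holding
#'   the actual day labels.
#' @export
synthetic_design <- function(n_genes = 2000,
                             n_timepoints = 6,
                             n_replicates = 4,
                             n_batches = 1,
                             planted_module_size = 12,
                             module_density = 0.8,
                             n_transient = min(4 * planted_module_size,
                                               n_genes),
                             transient_peak_day = 8.5,
                             peak_amplitude = 2,
                             peak_sd = 1,
                             noise_sd = 0.25,
                             batch_sd = 0,
                             drift_sd = 0,
                             graph_model = c("scale-free", "Erdos-Renyi"),
                             mean_degree = 10,
                             rng_seed = 1L) {
  graph_model <- match.arg(graph_model)
  days <- if (n_timepoints == 6) c(6, 7, 8, 9, 10, 14) else
    seq(6, length.out = n_timepoints)
  d <- structure(list(
    n_genes = as.integer(n_genes), n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates), n_batches = as.integer(n_batches),
    planted_module_size = as.integer(planted_module_size),
    module_density = module_density,
    n_transient = as.integer(n_transient),
    transient_peak_day = transient_peak_day,
    peak_amplitude = peak_amplitude, peak_sd = peak_sd,
    noise_sd = noise_sd, batch_sd = batch_sd, drift_sd = drift_sd,
    graph_model = graph_model, mean_degree = mean_degree,
    rng_seed = as.integer(rng_seed), days = days), class = "tn_design")
  validate_design(d)
  d
}

validate_design <- function(d) {
  counts <- c(d$n_genes, d$n_timepoints, d$n_replicates, d$n_batches,
              d$planted_module_size)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (d$planted_module_size > d$n_genes)
    stop("planted_module_size exceeds n_genes")
  if (d$n_transient < d$planted_module_size || d$n_transient > d$n_genes)
    stop("n_transient must lie in [planted_module_size, n_genes]")
  if (d$noise_sd < 0 || d$batch_sd < 0 || d$peak_sd <= 0)
    stop("noise_sd/batch_sd must be >= 0 and peak_sd > 0")
  if (d$module_density < 0 || d$module_density > 1)
    stop("module_density must lie in [0, 1]")
  if (d$transient_peak_day < min(d$days) || d$transient_peak_day > max(d$days))
    stop("transient_peak_day outside the day-label range")
  invisible(d)
}

#' Generate a synthetic interactome with a planted connected module
#'
#' Draws an undirected simple graph over gene symbols (scale-free via
#' preferential attachment, or Erdos-Renyi) with edge confidences in
#' (0.4, 1], plants a connected module of `planted_module_size` genes
#' by adding a random spanning tree among them, and guarantees a
#' single connected component.
#'
#' @param design a [synthetic_design()] object.
#' @return list with elements `graph` (igraph; vertex `name`, edge
#'   `confidence`) and `truth` (class `tn_truth`: the planted module
#'   genes and edges, the full transient gene set, and the gene
#'   universe).
#' @export
generate_interactome <- function(design) {
  validate_design(design)
  set.seed(design$rng_seed)
  n <- design$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  if (design$graph_model == "scale-free") {
    m <- max(1L, as.integer(round(design$mean_degree / 2)))
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
  } else {
    n_edges <- round(design$mean_degree * n / 2)
    if (n_edges < n - 1)
      stop("mean_degree too small for a connected Erdos-Renyi graph")
    g <- igraph::sample_gnm(n, n_edges)
  }
  igraph::V(g)$name <- sample(genes)  # decouple hub status from symbol order
  g <- igraph::simplify(g)

  # stitch minor components onto the largest one
  comp <- igraph::components(g)
  if (comp$no > 1) {
    giant <- which.max(comp$csize)
    anchor_pool <- igraph::V(g)$name[comp$membership == giant]
    for (k in setdiff(seq_len(comp$no), giant)) {
      v <- sample(igraph::V(g)$name[comp$membership == k], 1)
      g <- igraph::add_edges(g, c(v, sample(anchor_pool, 1)))
    }
  }

  module <- sort(sample(genes, design$planted_module_size))
  tree <- plant_spanning_tree(module)
  dense <- plant_dense_edges(module, tree, design$module_density)
  planted <- rbind(tree, dense)
  have <- igraph::get_edge_ids(g, t(planted), error = FALSE)
  if (any(have == 0))
    g <- igraph::add_edges(g, t(planted[have == 0, , drop = FALSE]))
  g <- igraph::simplify(g)
  igraph::E(g)$confidence <- stats::runif(igraph::ecount(g), 0.4, 1.0)

  extra <- design$n_transient - design$planted_module_size
  transient <- sort(c(module, sample(setdiff(genes, module), extra)))
  truth <- structure(list(
    planted_module_genes = module,
    planted_edges = planted,
    transient_genes = transient,
    apoptosis_set_names = character(0),
    gene_universe = genes,
    rng_seed = design$rng_seed), class = "tn_truth")
  list(graph = g, truth = truth)
}

# random spanning tree over the given symbols: each node joins an
# earlier one, in shuffled order
plant_spanning_tree <- function(nodes) {
  ord <- sample(nodes)
  if (length(ord) < 2) return(matrix(character(0), ncol = 2))
  to <- vapply(2:length(ord),
               function(i) ord[sample.int(i - 1, 1)], character(1))
  cbind(from = ord[-1], to = to)
}

# extra within-module edges beyond the tree, each pair kept with
# probability `density`
plant_dense_edges <- function(nodes, tree, density) {
  if (length(nodes) < 3 || density <= 0)
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  pairs <- t(utils::combn(sort(nodes), 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  rest <- pairs[!key(pairs) %in% key(tree), , drop = FALSE]
  picked <- rest[stats::runif(nrow(rest)) < density, , drop = FALSE]
  colnames(picked) <- c("from", "to")
  picked
}

#' Generate a replicated expression time course
#'
#' Transient genes follow baseline + `peak_amplitude` *
#' exp(-(day - peak)^2 / (2 peak_sd^2)); background genes are flat
#' (plus an optional small linear drift). Gaussian noise is added per
#' observation and an additive scalar offset per batch.
#'
#' @param design a [synthetic_design()] object.
#' @param truth the `tn_truth` from [generate_interactome()].
#' @return a [tn_expr()] expression object with sample metadata.
#' @export
generate_expression <- function(design, truth) {
  validate_design(design)
  if (!identical(truth$gene_universe, sprintf("G%05d", seq_len(design$n_genes))))
    stop("gene universes of design and truth do not match")
  set.seed(design$rng_seed + 1L)
  genes <- truth$gene_universe
  days <- design$days
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      day = days, KEEP.OUT.ATTRS = FALSE)
  grid$sample_id <- sprintf("D%g_R%d", grid$day, grid$replicate)
  grid$batch <- ((grid$replicate - 1L) %% design$n_batches) + 1L
  n_s <- nrow(grid)

  baseline <- stats::rnorm(length(genes), mean = 7, sd = 1)
  is_tr <- genes %in% truth$transient_genes
  bump <- design$peak_amplitude *
    exp(-(grid$day - design$transient_peak_day)^2 / (2 * design$peak_sd^2))
  slope <- ifelse(is_tr, 0, stats::rnorm(length(genes), 0, design$drift_sd))

  vals <- matrix(baseline, nrow = length(genes), ncol = n_s)
  vals <- vals + outer(as.numeric(is_tr), bump)
  vals <- vals + outer(slope, grid$day - mean(days))
  if (design$batch_sd > 0) {
    off <- stats::rnorm(design$n_batches, 0, design$batch_sd)
    vals <- vals + matrix(off[grid$batch], nrow = length(genes),
                          ncol = n_s, byrow = TRUE)
  }
  vals <- vals + matrix(stats::rnorm(length(genes) * n_s, 0, design$noise_sd),
                        nrow = length(genes))
  dimnames(vals) <- list(genes, grid$sample_id)
  tn_expr(vals, data.frame(sample_id = grid$sample_id, day = grid$day,
                           replicate = grid$replicate, batch = grid$batch,
                           stringsAsFactors = FALSE))
}

#' Generate a gene-set collection covering the planted module
#'
#' Produces random gene sets plus four "apoptosis" sets named after
#' the GO apoptosis categories used for node weighting. The apoptosis
#' annotation covers the planted module together with a handful of
#' transient genes outside it (`n_peripheral`), emulating annotated
#' apoptosis effectors peripheral to the core pathway module; the
#' first apoptosis set contains the entire planted module, the others
#' random subsets of the annotated genes. Every set has at least
#' three members.
#'
#' @param truth the `tn_truth` from [generate_interactome()].
#' @param n_sets total number of sets (>= number of apoptosis sets).
#' @param set_size_range length-2 integer vector; lower bound >= 3.
#' @param n_peripheral number of annotated transient genes outside the
#   planted module (default 4, capped by availability).
#' @param rng_seed seed (defaults to the truth's seed + 2).
#' @return named list of character vectors of class `tn_genesets`,
#'   with attributes `description` (named character) and `apoptosis`
#'   (the apoptosis set names, also copied into
#'   `attr(,"truth_apoptosis")` for convenience).
#' @export
generate_gene_sets <- function(truth, n_sets = 50, set_size_range = c(5, 40),
                               n_peripheral = 4,
                               rng_seed = truth$rng_seed + 2L) {
  if (set_size_range[1] < 3)
    stop("set_size_range lower bound must be >= 3")
  set.seed(rng_seed)
  genes <- truth$gene_universe
  module <- truth$planted_module_genes
  apo_names <- c("GO:1900119", "GO:0042771", "GO:0097191", "GO:0043065")
  apo_desc <- c("positive regulation of execution phase of apoptosis",
                "intrinsic apoptotic signaling pathway by p53 class mediator",
                "extrinsic apoptotic signaling pathway",
                "positive regulation of apoptotic process")
  n_apo <- min(length(apo_names), n_sets)
  apo_names <- apo_names[seq_len(n_apo)]
  apo_desc <- apo_desc[seq_len(n_apo)]

  sets <- vector("list", n_sets)
  desc <- character(n_sets)
  nm <- character(n_sets)
  outside <- setdiff(truth$transient_genes, module)
  peri <- sort(sample(outside, min(n_peripheral, length(outside))))
  annotated <- sort(c(module, peri))
  sub_size <- min(length(annotated),
                  max(3, set_size_range[1], ceiling(length(annotated) / 2)))
  for (i in seq_len(n_apo)) {
    sets[[i]] <- if (i == 1) sort(c(module, sample(peri, min(2, length(peri)))))
                 else sort(sample(annotated, sub_size))
    nm[i] <- apo_names[i]
    desc[i] <- apo_desc[i]
  }
  for (i in seq_len(n_sets - n_apo) + n_apo) {
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    sets[[i]] <- sort(sample(genes, sz))
    nm[i] <- sprintf("RS%04d", i - n_apo)
    desc[i] <- "random background gene set"
  }
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc, apoptosis = apo_names,
            class = "tn_genesets")
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the three generators and writes expression/metadata TSVs, the
#' GMT collection, the interactome edge list, and a truth TSV marking
#' the planted module and transient genes.
#'
#' @param design a [synthetic_design()].
#' @param out_dir output directory (created if needed).
#' @param header_lines optional `#` metadata lines for the TSVs.
#' @return invisibly, a list with `paths` (named file paths) and the
#'   in-memory objects `graph`, `truth`, `expr`, `sets`.
#' @export
write_synthetic_dataset <- function(design, out_dir, header_lines = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_interactome(design)
  expr <- generate_expression(design, net$truth)
  sets <- generate_gene_sets(net$truth)
  net$truth$apoptosis_set_names <- attr(sets, "apoptosis")
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    metadata = file.path(out_dir, "sample_metadata.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    network = file.path(out_dir, "interactome.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_expression(expr, paths$expression, paths$metadata, header_lines)
  write_gmt(sets, paths$gmt)
  write_edges(net$graph, paths$network, header_lines)
  truth_df <- data.frame(
    gene = net$truth$gene_universe,
    planted_module = net$truth$gene_universe %in% net$truth$planted_module_genes,
    transient = net$truth$gene_universe %in% net$truth$transient_genes)
  write_tsv_with_header(truth_df, paths$truth, header_lines)
  invisible(list(paths = paths, graph = net$graph, truth = net$truth,
                 expr = expr, sets = sets))
}
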