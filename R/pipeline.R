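# End-to-end orchestration: simulate -> preprocess -> gsea -> score ->
# subnet -> modules -> ego, with deterministic per-stage seeds and
# metadata-stamped outputs.

# FNV-1a 32-bit hash of a string, kept below 2^31 for use as a seed;
# xor on 16-bit halves since bitwXor() only takes values below 2^31
fnv1a <- function(x) {
  xor32 <- function(a, b)
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

#' Assemble (or read) a pipeline configuration
#'
#' @param path optional YAML file; entries override the defaults.
#' @param ... named overrides applied after the file.
#' @return list of class `tn_config` with design parameters, analysis
#'   settings (`baseline_day`, `min_confidence`, `go_weight`,
#'   `apoptosis_set_ids`), a `master_seed` from which per-stage seeds
#'   are derived by hashing the stage name, `drop_samples`, `anchors`
#'   and the `stages` toggle vector.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    design = list(),                      # overrides for synthetic_design()
    baseline_day = 6,
    min_confidence = 0.4,
    go_weight = 2,
    apoptosis_set_ids = c("GO:1900119", "GO:0042771", "GO:0097191",
                          "GO:0043065"),
    drop_samples = character(0),
    anchors = NULL,                       # default: top-2 betweenness nodes
    n_restarts = 5L,
    n_rewires = 200L,
    master_seed = 1L,
    stages = c("simulate", "preprocess", "gsea", "score", "subnet",
               "modules", "ego"))
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = "tn_config")
}

stage_seed <- function(cfg, stage) {
  # double arithmetic to dodge 32-bit overflow before the modulus
  as.integer((fnv1a(stage) + cfg$master_seed * 1009) %% 2147483647)
}

config_hash <- function(cfg) {
  sprintf("%08x", fnv1a(paste(deparse(unclass(cfg)), collapse = "")))
}

#' Run the full transient-subnetwork pipeline on synthetic data
#'
#' Executes the enabled stages in order, writing TSV/GraphML
#' artifacts stamped with the configuration hash and per-stage seeds.
#' Reruns with an identical configuration reproduce identical files.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir output directory.
#' @return invisibly, a manifest list: per-stage output paths plus the
#'   key in-memory results (`truth`, `scores`, `subnet`, `modules`,
#'   `enrichment`, `centrality`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hh <- config_hash(cfg)
  stamp <- function(stage)
    c(sprintf("transientnet stage=%s config=%s seed=%d", stage, hh,
              stage_seed(cfg, stage)))
  manifest <- list(config_hash = hh)
  on <- function(stage) stage %in% cfg$stages

  if (!on("simulate")) stop("stage 'simulate' is required to provide inputs")
  design <- do.call(synthetic_design,
                    utils::modifyList(list(rng_seed = stage_seed(cfg, "simulate")),
                                      cfg$design))
  sim_dir <- file.path(out_dir, "simulate")
  sim <- write_synthetic_dataset(design, sim_dir, stamp("simulate"))
  manifest$simulate <- sim$paths
  expr <- sim$expr; sets <- sim$sets; graph <- sim$graph
  manifest$truth <- sim$truth

  if (on("preprocess")) {
    expr <- collapse_probes(expr)
    if (length(cfg$drop_samples)) expr <- drop_samples(expr, cfg$drop_samples)
    expr <- center_batches(expr)
    pca <- run_pca(expr, n_components = min(3, ncol(expr$values) - 1))
    pre_dir <- file.path(out_dir, "preprocess")
    dir.create(pre_dir, showWarnings = FALSE)
    p1 <- file.path(pre_dir, "expression_centered.tsv")
    p2 <- file.path(pre_dir, "sample_metadata.tsv")
    write_expression(expr, p1, p2, stamp("preprocess"))
    p3 <- file.path(pre_dir, "pca_variance.tsv")
    write_tsv_with_header(
      data.frame(component = seq_along(pca$variance_fraction),
                 variance_fraction = pca$variance_fraction),
      p3, stamp("preprocess"))
    manifest$preprocess <- list(expression = p1, metadata = p2, pca = p3)
    manifest$pca <- pca
  }

  if (on("gsea")) {
    gs <- run_gsea(expr, sets, baseline_day = cfg$baseline_day)
    gd <- file.path(out_dir, "gsea")
    dir.create(gd, showWarnings = FALSE)
    g1 <- file.path(gd, "set_timepoint.tsv")
    g2 <- file.path(gd, "set_summary.tsv")
    write_tsv_with_header(gs$per_timepoint, g1, stamp("gsea"))
    write_tsv_with_header(gs$set_table, g2, stamp("gsea"))
    manifest$gsea <- list(per_timepoint = g1, summary = g2)
    manifest$gsea_result <- gs
  }

  scores <- score_genes(expr, cfg$apoptosis_set_ids, sets,
                        weight = cfg$go_weight)
  if (on("score")) {
    sd_ <- file.path(out_dir, "score")
    dir.create(sd_, showWarnings = FALSE)
    s1 <- file.path(sd_, "scores.tsv")
    write_tsv_with_header(scores, s1, stamp("score"))
    manifest$score <- list(scores = s1)
  }
  manifest$scores <- scores

  if (on("subnet")) {
    subnet <- solve_heuristic(graph, scores,
                              seed = stage_seed(cfg, "subnet"),
                              penalty_weight = cfg$go_weight)
    nd <- file.path(out_dir, "subnet")
    dir.create(nd, showWarnings = FALSE)
    ann <- subnet$graph
    igraph::V(ann)$raw_score <-
      scores$raw_score[match(igraph::V(ann)$name, scores$gene)]
    igraph::V(ann)$weighted_score <-
      scores$weighted_score[match(igraph::V(ann)$name, scores$gene)]
    igraph::V(ann)$go_flag <-
      scores$go_flag[match(igraph::V(ann)$name, scores$gene)]
    n1 <- file.path(nd, "subnet.graphml")
    n2 <- file.path(nd, "subnet_edges.tsv")
    write_graphml(ann, n1)
    write_edges(subnet$graph, n2, stamp("subnet"))
    manifest$subnet_files <- list(graphml = n1, edges = n2)
    manifest$subnet <- subnet
  }

  if (on("modules")) {
    if (!on("subnet")) stop("stage 'modules' needs the 'subnet' stage")
    part <- detect_modules(manifest$subnet, seed = stage_seed(cfg, "modules"),
                           n_restarts = cfg$n_restarts)
    sig <- module_significance(manifest$subnet, part,
                               n_rewires = cfg$n_rewires,
                               seed = stage_seed(cfg, "modules"))
    enr <- hypergeom_enrich(part, sets,
                            background = igraph::V(graph)$name)
    cent <- centralities(manifest$subnet)
    md <- file.path(out_dir, "modules")
    dir.create(md, showWarnings = FALSE)
    m1 <- file.path(md, "module_assignment.tsv")
    m2 <- file.path(md, "module_enrichment.tsv")
    m3 <- file.path(md, "centrality.tsv")
    write_tsv_with_header(
      data.frame(gene = names(part$assignment), module = part$assignment,
                 module_p = unname(sig[paste0("M", part$assignment)])),
      m1, stamp("modules"))
    write_tsv_with_header(as.data.frame(enr), m2, stamp("modules"))
    write_tsv_with_header(as.data.frame(cent), m3, stamp("modules"))
    manifest$modules_files <- list(assignment = m1, enrichment = m2,
                                   centrality = m3)
    manifest$modules <- part
    manifest$module_significance <- sig
    manifest$enrichment <- enr
    manifest$centrality <- cent
  }

  if (on("ego")) {
    if (!on("subnet")) stop("stage 'ego' needs the 'subnet' stage")
    anchors <- cfg$anchors
    if (is.null(anchors)) {
      cent <- if (!is.null(manifest$centrality)) manifest$centrality
              else centralities(manifest$subnet)
      anchors <- cent$node[order(-cent$betweenness)][1:2]
    }
    fits <- fit_quadratic_all(expr)
    ego <- ego_network(graph, anchors, fits)
    ed <- file.path(out_dir, "ego")
    dir.create(ed, showWarnings = FALSE)
    e1 <- file.path(ed, "ego.graphml")
    e2 <- file.path(ed, "ego_ordering.tsv")
    write_graphml(ego$graph, e1)
    write_tsv_with_header(ego$ordering, e2, stamp("ego"))
    manifest$ego_files <- list(graphml = e1, ordering = e2)
    manifest$ego <- ego
  }
  invisible(manifest)
}

#' Comparative qPCR fold change (2^-ddCt)
#'
#' ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,baseline - Ct_ref,baseline); the fold change is
#' 2^(-ddCt), i.e. expression normalized to a reference gene (such as
#' GAPDH) and a baseline condition.
#'
#' @param ct_target_sample,ct_ref_gene_sample Ct values in the sample.
#' @param ct_target_baseline,ct_ref_gene_baseline Ct values in the
#'   baseline condition.
#' @return fold change (positive real).
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_gene_sample,
                             ct_target_baseline, ct_ref_gene_baseline) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_gene_sample),
            is.finite(ct_target_baseline), is.finite(ct_ref_gene_baseline))
  ddct <- (ct_target_sample - ct_ref_gene_sample) -
    (ct_target_baseline - ct_ref_gene_baseline)
  2^(-ddct)
}

#' Percent change of a group mean against a reference mean
#'
#' @param group_mean mean of the treated/observed group.
#' @param reference_mean reference (control) mean; must be positive.
#' @return list with `percent` (full precision) and `rounded`
#'   (nearest integer percent).
#' @export
percent_change <- function(group_mean, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference_mean must be positive")
  pct <- 100 * (group_mean - reference_mean) / reference_mean
  list(percent = pct, rounded = round(pct))
}
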