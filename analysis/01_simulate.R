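#!/usr/bin/env Rscript
# Stage 1 — simulate the study: a replicated expression time course
# (4 replicates x days {6,7,8,9,10,14}, 2000 genes) with a planted
# 12-gene transient apoptosis module inside a scale-free interactome,
# plus GO-style gene sets covering the module.
#
# Writes results/data/{expression,sample_metadata,interactome,truth}.tsv
# and gene_sets.gmt.

library(transientnet)

design <- synthetic_design(rng_seed = 1L)
out <- write_synthetic_dataset(design, "results/data",
                               header_lines = "stage=simulate seed=1")

cat(sprintf("genes: %d  samples: %d  interactome edges: %d\n",
            design$n_genes,
            ncol(out$expr$values),
            igraph::ecount(out$graph)))
cat(sprintf("planted module: %d genes (%s ...)\n",
            length(out$truth$planted_module_genes),
            paste(head(out$truth$planted_module_genes, 4), collapse = ", ")))
cat(sprintf("transient genes: %d  apoptosis sets: %s\n",
            length(out$truth$transient_genes),
            paste(attr(out$sets, "apoptosis"), collapse = ", ")))
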