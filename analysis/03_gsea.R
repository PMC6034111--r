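#!/usr/bin/env Rscript
# Stage 3 — time-resolved gene-set analysis: per-gene two-sample t
# against the E6 baseline, Stouffer combination per set and time
# point, BH correction across sets, and scaled set profiles with
# complete-linkage clustering.
#
# Reads results/data/, writes results/gsea_set_summary.tsv,
# results/gsea_set_timepoint.tsv and results/gsea_profiles.tsv.

library(transientnet)

expr <- collapse_probes(read_expression("results/data/expression.tsv",
                                        "results/data/sample_metadata.tsv"))
sets <- read_gmt("results/data/gene_sets.gmt")
gsea <- run_gsea(expr, sets, baseline_day = 6)

tab <- gsea$set_table[order(gsea$set_table$q), ]
cat("top 5 sets by FDR q:\n")
print(head(tab[, c("set", "n_genes", "summary_z", "q")], 5), row.names = FALSE)

sig <- tab$set[tab$q < 0.001]
cat(sprintf("%d set(s) at q < 0.001\n", length(sig)))
sel <- head(tab$set, max(4, length(sig)))
prof <- set_profiles(expr, sets, sel)

w <- transientnet:::write_tsv_with_header
w(tab, "results/gsea_set_summary.tsv", "stage=gsea baseline_day=6")
w(gsea$per_timepoint, "results/gsea_set_timepoint.tsv",
  "stage=gsea baseline_day=6")
w(data.frame(set = rownames(prof$profiles)[prof$order],
             round(prof$profiles[prof$order, , drop = FALSE], 4)),
  "results/gsea_profiles.tsv", "stage=gsea scaled mean set profiles")
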