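# transientnet

Inference of transiently regulated subnetworks from replicated
developmental gene-expression time series.

During development of the avian ciliary ganglion, programmed cell
death transiently removes neurons around embryonic days E8–E9. Genes
driving such an event rise and fall within the series, so no single
differential contrast captures them. `transientnet` is for
computational biologists who have (i) a replicated expression time
course, (ii) a gene-set collection (GMT), and (iii) a STRING-style
protein-interaction network, and who want the connected piece of the
interactome that carries a transient, pathway-annotated program —
plus its module structure, enrichments, and hub/effector
classification. A synthetic-data generator with a planted transient
module makes the whole pipeline testable offline.

## Method

For each gene $g$, replicate-mean expression over embryonic days is
fitted with a second-order polynomial on the rescaled day axis
$\tau \in [-1, 1]$:

$$x_g(\tau) = a_0 + a_1 \tau + a_2 \tau^2 .$$

A transient (peaked) profile is concave, so the **transience score**
is $s_g = -a_2$. Scores are shifted by $\pm w$ (default $w = 2$)
according to membership in configured apoptosis GO categories, and a
**maximum-weight connected subgraph**

$$\max_{S \subseteq V,\ S\ \text{connected}} \sum_{g \in S} \left(s_g \pm w\right)$$

is extracted from the confidence-filtered interactome (score > 0.4)
— exactly for small graphs, and at genome scale by a Steiner-tree
heuristic (terminal metagraph over shortest paths with interior cost
$\max(0, -s) + \varepsilon$, MST expansion, strong pruning from
multiple roots, greedy absorption of positive neighbors). The
subnetwork is decomposed by Reichardt–Bornholdt spin-glass community
detection, modules are tested by a detection-aware degree-preserving
rewiring null, enriched by a conditional hypergeometric test against
the interactome background, and nodes classed central/peripheral by
betweenness and eigenvector centrality. Time-resolved gene-set
analysis uses per-gene two-sample $t$ statistics versus the E6
baseline, converted to signed $z$ and combined per set with
Stouffer's method $Z = \sum z_i / \sqrt{k}$, with BH correction
across sets. See the methods vignette
(`vignettes/transient-subnetwork-methods.Rmd`) for assumptions,
parameter defaults, and design rationale.

## Worked example

The numbered drivers under `analysis/` run the full study on the
default synthetic design (2000 genes, 4 replicates × days
{6,7,8,9,10,14}, planted 12-gene module, amplitude 2, noise sd 0.25):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_subnetwork.R
```

prints

```
genes: 2000  samples: 24  interactome edges: 10040
planted module: 12 genes (G00640, G00641, G00681, G00759 ...)
transient genes: 48  apoptosis sets: GO:1900119, GO:0042771, GO:0097191, GO:0043065

tn_subgraph (heuristic): 18 nodes, 62 edges, total score 44.93
planted-module recovery: 12/12 genes, node F1 = 0.80
degree: max 13, mean 6.89, fraction of leaves 0.17
penalty sweep (nodes shrink as the weight grows):
 weight n_nodes n_edges total_score
    0.5      71     128    43.65026
    1.0      27      75    34.67870
    2.0      18      62    44.93381
    4.0      18      62    68.93381
```

All 12 planted genes are recovered inside an 18-node subgraph (the
extras are annotated peripheral genes and their connectors), and the
subgraph shrinks as the annotation weight grows — the
specificity/size trade-off behind the default weight of 2. Stage 3
ranks the planted apoptosis sets first in the time-resolved gene-set
analysis (q < 1e-50 versus q ≈ 4e-7 for the best random set), and
stage 5 labels the recovered modules with those same sets. The
in-package equivalent of the whole chain is `run_pipeline()`, driven
by a config list or YAML file.

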