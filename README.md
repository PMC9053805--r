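# polypnet

Cascaded co-expression and network clustering analysis for normal-colon
versus adenomatous-polyp expression cohorts.

Most colorectal carcinomas arise from adenomatous polyps, and expression
changes in the normal-to-polyp transition are candidate early biomarkers.
polypnet implements, as a tested and reusable R pipeline, the cascade that
takes multi-batch probe-level log2 microarray cohorts to ranked biomarker
gene submodules:

1. probe-to-gene median aggregation and empirical-Bayes batch correction
   (location/scale model, via `sva::ComBat`);
2. weighted gene co-expression module detection — soft power β by the
   scale-free criterion, unsigned adjacency `|cor|^β`, topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
   average-linkage clustering of `1 − TOM`, eigengene merge at height 0.25
   (correlation 0.75), module–trait selection at `|r| > 0.3`;
3. mapping of the selected module genes onto a tissue-specific weighted
   functional interaction network (edge weights > 0.1, tissue-expressed
   genes, largest component, order-0 induced subgraph);
4. graph clustering by Markov clustering (inflation 1.2, expansion 2),
   greedy modularity ("FN"), and spectral clustering on the precomputed
   affinity;
5. partition scoring with modularity
   `Q = (1/2m) Σ_ij (A_ij − k_i k_j/2m) δ(c_i,c_j)`, a connectivity-based
   silhouette, the Biological Homogeneity Index, and Wang semantic
   similarity (BP/MF, relation weights 0.8/0.6, best-match average);
6. differential expression (Student's t, Benjamini–Hochberg,
   `|log2FC| > 1` and `FDR < 0.05`), hypergeometric over-representation
   (`FDR ≤ 0.05`), independent-cohort validation by direction concordance,
   and an action-type compound filter (inhibitors for up-regulated targets,
   activators for down-regulated ones).

A seeded synthetic-data generator (`sim_config()`, `simulate_all()`) plants
co-expressed phenotype-linked modules, batch effects, differential
expression, network communities and an annotation DAG with full ground
truth, so every stage is testable end to end without downloads. It is
first-class, documented code, not a fixture.

## Worked example

The numbered scripts under `analysis/` run the whole cascade on the
reference synthetic conditions (2000 genes, two planted 50-gene modules
down-regulated in polyp, three batches × 40 samples, two independent
validation cohorts of 67 and 106 samples):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_coexpression.R
Rscript analysis/04_network_clustering.R
Rscript analysis/05_dge_enrichment.R
Rscript analysis/06_validation_report.R
```

which prints, stage by stage:

```
genes with batch-mean differences at p<0.05: 88.0% before, 0.0% after correction
soft power 5 chosen (scale-free fit 0.84 )
1 modules of sizes: 99 (plus 1901 unassigned genes)
ME1: r = -0.88, p = 4.5e-39  [selected]
mapped submodule network: 99 genes, 794 links
 algorithm clusters modularity silhouette mean_bhi mean_wang_bp mean_wang_mf
       mcl        1      0.000         NA    0.350        0.487        0.576
        fn        2      0.453      0.345    0.653        0.708        0.682
  spectral        2      0.453      0.345    0.653        0.708        0.682
DEGs at |log2FC| > 1 and FDR < 0.05: 88 down, 0 up
88 training DEGs checked against 2 validation cohorts; 79 concordant
```

Reading this: the batch correction removes essentially all batch-mean
structure; the co-expression stage finds one phenotype-linked module — the
two planted modules share their phenotype factor (r = 0.6 each), so the
unsigned analysis legitimately coalesces them, and the selection union
covers 99 of the 100 planted genes with no background; on the mapped
network, greedy-modularity and spectral clustering split that union back
into the two planted communities (modularity 0.45) while MCL at the
pipeline's inflation 1.2 stays coarse; the DEG filter recovers the planted
down-regulated genes; and most training DEGs validate with the same
direction on both independent cohorts. Tables land under `results/`.

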