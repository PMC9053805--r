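#!/usr/bin/env Rscript
# Assemble the gene-level training cohort: drop unannotated probes, collapse
# probes to genes by median, and remove the batch effect with the parametric
# empirical-Bayes location/scale adjustment. Validation cohorts are only
# aggregated - never batch-corrected, never merged.

suppressMessages(library(polypnet))

pm <- read_probe_matrix("scratch/sim/probe_matrix.tsv",
                        "scratch/sim/probe_annotation.tsv")
md <- read_metadata("scratch/sim/metadata.tsv")
agg <- drop_unannotated_and_aggregate(pm, md)
cat("dropped", nrow(pm$values) - sum(!is.na(pm$annotation$gene_id)),
    "unannotated probes;", nrow(agg$values), "genes x", ncol(agg$values),
    "samples after median aggregation\n")

em <- combat_adjust(agg)
dir.create("scratch/preprocess", showWarnings = FALSE, recursive = TRUE)
write_expression_matrix(em, "scratch/preprocess/expression.tsv",
                        "scratch/preprocess/metadata.tsv")

# how much batch structure the adjustment removed
batch_f_p <- function(e) {
  b <- factor(e$metadata$batch)
  apply(e$values, 1, function(row) anova(lm(row ~ b))[["Pr(>F)"]][1])
}
cat("genes with batch-mean differences at p<0.05:",
    sprintf("%.1f%% before, %.1f%% after correction\n",
            100 * mean(batch_f_p(agg) < 0.05),
            100 * mean(batch_f_p(em) < 0.05)))

for (nm in list.dirs("scratch/sim_validation", recursive = FALSE)) {
  vpm <- read_probe_matrix(file.path(nm, "probe_matrix.tsv"),
                           file.path(nm, "probe_annotation.tsv"))
  vmd <- read_metadata(file.path(nm, "metadata.tsv"))
  vem <- drop_unannotated_and_aggregate(vpm, vmd)
  write_expression_matrix(vem, file.path(nm, "expression.tsv"),
                          file.path(nm, "metadata_clean.tsv"))
  cat("validation", basename(nm), ":", nrow(vem$values), "genes x",
      ncol(vem$values), "samples (no batch correction)\n")
}
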