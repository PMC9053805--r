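#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a three-batch training cohort with two
# planted phenotype-linked co-expression modules (down-regulated in polyp), a
# planted-partition functional interaction network whose communities contain
# the module genes, a two-namespace annotation DAG, and two independent
# validation cohorts sized like the real validation series (67 = 38 normal +
# 29 polyp; 106 = 55 normal + 51 polyp).

suppressMessages(library(polypnet))

seed <- 7L
outdir <- "scratch/sim"  # bulky raw inputs; regenerated on demand

cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg)
paths <- write_simulation(sim, outdir)

v_cfgs <- list(
  cohortA = sim_config(n_samples_per_batch = 67L,
                       phenotype_balance = 29 / 67, seed = seed + 1000L),
  cohortB = sim_config(n_samples_per_batch = 106L,
                       phenotype_balance = 51 / 106, seed = seed + 2000L))
for (nm in names(v_cfgs)) {
  v <- simulate_cohort(v_cfgs[[nm]])
  vdir <- file.path("scratch/sim_validation", nm)
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  vals <- v$probes$values
  pm <- data.frame(probe_id = rownames(vals),
                   matrix(sprintf("%.17g", vals), nrow(vals),
                          dimnames = dimnames(vals)), check.names = FALSE)
  write.table(pm, file.path(vdir, "probe_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(v$probes$annotation, file.path(vdir, "probe_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(v$metadata, file.path(vdir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

cat("training cohort:", nrow(sim$probes$values), "probes x",
    ncol(sim$probes$values), "samples in",
    length(unique(sim$metadata$batch)), "batches\n")
cat("network:", igraph::vcount(sim$network), "genes,",
    igraph::ecount(sim$network), "weighted interactions\n")
cat("planted DE genes:", sum(sim$truth$planted_lfc != 0), "\n")
cat("wrote", length(paths), "training files under", outdir,
    "and two validation cohorts under scratch/sim_validation\n")
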