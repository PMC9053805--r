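#!/usr/bin/env Rscript
# Weighted co-expression module detection on the corrected cohort: choose the
# soft power by the scale-free criterion, build the topological overlap
# matrix, cut the average-linkage dendrogram, merge modules whose eigengenes
# correlate above 0.75 (height cut 0.25), and keep modules with
# |module-trait correlation| > 0.3.

suppressMessages(library(polypnet))

em <- read_expression_matrix("scratch/preprocess/expression.tsv",
                             "scratch/preprocess/metadata.tsv")
ps <- suppressWarnings(pick_soft_threshold(em))
cat("soft power", ps$power, "chosen (scale-free fit",
    sprintf("%.2f", ps$table$sft_r2[ps$table$power == ps$power]), ")\n")

tom <- tom_from_expression(em, ps$power)
labels <- detect_modules(tom)
merged <- merge_close_modules(em, labels)
mt <- module_trait_select(merged$eigengenes, em$metadata, r_threshold = 0.3)

dir.create("results/coexpression", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(gene_id = names(merged$labels),
                       module = unclass(merged$labels)),
            "results/coexpression/module_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ps$table, "results/coexpression/soft_threshold.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mt$table, "results/coexpression/module_trait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sel_ids <- as.integer(sub("^ME", "", mt$selected))
sel_genes <- sort(names(merged$labels)[merged$labels %in% sel_ids])
writeLines(sel_genes, "results/coexpression/selected_module_genes.txt")

sizes <- table(merged$labels[merged$labels > 0])
cat(length(sizes), "modules of sizes:",
    paste(as.integer(sizes), collapse = ", "), "(plus",
    sum(merged$labels == 0), "unassigned genes)\n")
for (i in seq_len(nrow(mt$table))) {
  cat(sprintf("%s: r = %+.2f, p = %.2g%s\n", mt$table$module[i],
              mt$table$r[i], mt$table$p[i],
              if (mt$table$selected[i]) "  [selected]" else ""))
}
cat("selected modules carry", length(sel_genes), "genes;",
    "negative r means up in normal colon, down in polyp\n")
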