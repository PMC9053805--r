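#!/usr/bin/env Rscript
# Differential expression on the corrected cohort (|log2FC| > 1, FDR < 0.05,
# Student's t with Benjamini-Hochberg), ranking of submodules by the
# biological criteria (min-max-normalized BHI / Wang-BP / Wang-MF among
# submodules with >= 10 genes and >= 1 DEG), and over-representation
# analysis of the top submodule genes with the term-gene graph export.

suppressMessages(library(polypnet))

em <- read_expression_matrix("scratch/preprocess/expression.tsv",
                             "scratch/preprocess/metadata.tsv")
ont <- read_ontology("scratch/sim/ontology.tsv",
                     "scratch/sim/annotations.tsv")
degs <- differential_expression(em)
dir.create("results/dge", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch/dge", showWarnings = FALSE, recursive = TRUE)
write.table(degs, "scratch/dge/deg_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)  # full per-gene table is bulky
sel <- select_degs(degs)
cat("DEGs at |log2FC| > 1 and FDR < 0.05:", length(sel$down), "down,",
    length(sel$up), "up\n")

reports <- list()
parts <- list()
for (nm in c("mcl", "fn", "spectral")) {
  tab <- read.delim(file.path("results/clustering",
                              paste0("submodules_", nm, ".tsv")))
  ptab <- read.delim(file.path("results/clustering",
                               paste0("partition_", nm, ".tsv")))
  parts[[nm]] <- partition(setNames(ptab$cluster, ptab$gene_id), nm)
  reports[[nm]] <- structure(list(algorithm = nm, q = NA, s_u = NA,
                                  submodules = tab[, -1]),
                             class = "metric_report")
}
ranked <- select_submodules(reports, min_size = 10, top_n = 3)
write.table(ranked, "results/dge/ranked_submodules.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top-ranked submodules:\n")
print(ranked[, c("algorithm", "cluster", "size", "bhi", "wang_bp",
                 "wang_mf", "n_down", "n_up", "score")],
      row.names = FALSE, digits = 3)

top_genes <- unique(unlist(lapply(seq_len(nrow(ranked)), function(i) {
  p <- parts[[ranked$algorithm[i]]]
  names(p)[unclass(p) == ranked$cluster[i]]
})))
writeLines(sort(top_genes), "results/dge/top_submodule_genes.txt")

collections <- list(BP = annotation_gene_sets(ont$annotations, "BP"),
                    MF = annotation_gene_sets(ont$annotations, "MF"))
enr <- ora(intersect(top_genes, rownames(em$values)), collections,
           rownames(em$values))
write.table(enr, "results/dge/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sum(enr$significant), "terms significant at FDR <= 0.05\n")
if (any(enr$significant & enr$overlap_size > 0)) {
  gr <- term_gene_graph(enr, degs)
  write_term_gene_graph(gr, "results/dge/term_gene_graph.json",
                        "results/dge/term_gene_graph.dot")
  dirs <- table(gr$nodes$direction[gr$nodes$type == "gene"])
  cat("term-gene graph:", sum(gr$nodes$type == "term"), "terms,",
      sum(gr$nodes$type == "gene"), "genes (",
      paste(names(dirs), as.integer(dirs), collapse = ", "), ")\n")
}
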