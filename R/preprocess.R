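#' Drop unannotated probes and aggregate probes to genes by median
#'
#' Probes without a gene annotation (`NA`) are removed; for every remaining
#' gene, the per-sample expression value is the median over that gene's
#' probes. Genes are returned sorted by id.
#'
#' @param pm A [probe_matrix()].
#' @param metadata Sample metadata data frame (`sample_id`, `phenotype`,
#'   `batch`) matching the probe matrix columns.
#' @return An [expression_matrix()], one row per gene.
#' @export
drop_unannotated_and_aggregate <- function(pm, metadata) {
  stopifnot(inherits(pm, "probe_matrix"))
  ann <- pm$annotation
  gene_of <- stats::setNames(ann$gene_id, ann$probe_id)[rownames(pm$values)]
  keep <- !is.na(gene_of)
  if (!any(keep)) stop("all probes are unannotated; nothing to aggregate")
  vals <- pm$values[keep, , drop = FALSE]
  genes <- gene_of[keep]
  gene_ids <- sort(unique(genes))
  out <- matrix(NA_real_, length(gene_ids), ncol(vals),
                dimnames = list(gene_ids, colnames(vals)))
  idx <- split(seq_len(nrow(vals)), genes)
  single <- lengths(idx) == 1L
  out[names(idx)[single], ] <- vals[unlist(idx[single]), , drop = FALSE]
  for (g in names(idx)[!single]) {
    out[g, ] <- apply(vals[idx[[g]], , drop = FALSE], 2, stats::median)
  }
  expression_matrix(out, metadata)
}

#' Assemble a multi-dataset cohort on the gene intersection
#'
#' Column-binds several gene-level matrices on the intersection of their gene
#' ids; each input contributes its samples under its own batch label, so the
#' merged cohort carries the source dataset as batch.
#'
#' @param matrices Named list of [expression_matrix()] objects; names become
#'   batch labels (unnamed inputs keep their own metadata batch column).
#' @return An [expression_matrix()] with `sum(sample counts)` columns.
#' @export
assemble_cohort <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  if (length(matrices) == 1L) {
    m <- matrices[[1]]
    if (!is.null(names(matrices))) m$metadata$batch <- names(matrices)[1]
    return(expression_matrix(m$values, m$metadata))
  }
  genes <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(genes) == 0) stop("empty gene intersection across inputs")
  ids <- unlist(lapply(matrices, function(m) m$metadata$sample_id))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sample ids across inputs: ",
                        paste(utils::head(dup, 5), collapse = ", "))
  genes <- sort(genes)
  vals <- do.call(cbind, lapply(matrices, function(m)
    m$values[genes, , drop = FALSE]))
  meta <- do.call(rbind, lapply(seq_along(matrices), function(i) {
    md <- matrices[[i]]$metadata
    if (!is.null(names(matrices)) && nzchar(names(matrices)[i])) {
      md$batch <- names(matrices)[i]
    }
    md
  }))
  rownames(meta) <- NULL
  expression_matrix(vals, meta)
}

#' Empirical-Bayes batch-effect adjustment
#'
#' Removes additive and multiplicative per-batch effects with the parametric
#' empirical-Bayes location/scale model (genes are standardized; per-batch,
#' per-gene location and scale parameters are shrunk toward batch-level
#' normal / inverse-gamma priors and divided out; the grand mean and pooled
#' variance are restored). The adjustment is computed by
#' [sva::ComBat()] with parametric priors and, by default, no phenotype
#' covariate. Validation cohorts must never pass through this function; the
#' pipeline runner enforces that.
#'
#' @param em An [expression_matrix()] with at least two batches, each with at
#'   least two samples.
#' @param use_phenotype_covariate If `TRUE`, protect the phenotype contrast
#'   with a model matrix during adjustment (off by default; see the methods
#'   vignette).
#' @return An [expression_matrix()] of identical dimensions and sample order.
#' @export
combat_adjust <- function(em, use_phenotype_covariate = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  batch <- em$metadata$batch
  tab <- table(batch)
  if (length(tab) < 2) stop("batch correction requires >= 2 batches")
  small <- names(tab)[tab < 2]
  if (length(small)) stop("batches with a single sample: ",
                          paste(small, collapse = ", "))
  v <- apply(em$values, 1, stats::var)
  zero <- rownames(em$values)[v <= 0]
  if (length(zero)) stop("zero-variance genes: ",
                         paste(utils::head(zero, 5), collapse = ", "))
  mod <- NULL
  if (use_phenotype_covariate) {
    mod <- stats::model.matrix(~phenotype, data = em$metadata)
  }
  adj <- suppressMessages(
    sva::ComBat(dat = em$values, batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  expression_matrix(adj, em$metadata)
}
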