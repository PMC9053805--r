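#' Per-gene differential expression between normal and polyp
#'
#' Vectorized two-sample t-test per gene (equal-variance Student's test by
#' default, Welch optionally), two-sided p-values, log2 fold change as the
#' difference of group means (polyp minus normal; the matrix is already on
#' the log2 scale), and Benjamini-Hochberg adjustment across all genes. The
#' `direction` column applies the DEG thresholds: `up` if
#' `log2FC > fc_threshold` and `FDR < fdr_threshold`, `down` if
#' `log2FC < -fc_threshold` and `FDR < fdr_threshold`, otherwise `ns`
#' (strict inequalities).
#'
#' @param em An [expression_matrix()] with >= 2 samples per phenotype.
#' @param welch Use Welch's unequal-variance t-test (default `FALSE`).
#' @param fc_threshold Absolute log2 fold-change threshold for the direction
#'   call (default 1.0).
#' @param fdr_threshold FDR threshold for the direction call (default 0.05).
#' @return Data frame of class `deg_table`: `gene_id`, `log2fc`, `t`, `p`,
#'   `fdr`, `direction`; zero-variance genes get `p = 1` and are flagged in
#'   the `flagged` column (with a warning).
#' @export
differential_expression <- function(em, welch = FALSE, fc_threshold = 1,
                                    fdr_threshold = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  z <- em$metadata$phenotype == "polyp"
  n1 <- sum(z); n0 <- sum(!z)
  if (n1 < 2 || n0 < 2) stop("each phenotype group needs >= 2 samples")
  x1 <- em$values[, z, drop = FALSE]
  x0 <- em$values[, !z, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  lfc <- m1 - m0
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    tt <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tt <- lfc / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df = df)
  flagged <- v1 + v0 <= 0
  if (any(flagged)) {
    warning(sum(flagged), " zero-variance genes: p set to 1")
    p[flagged] <- 1
    tt[flagged] <- 0
  }
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", length(lfc))
  direction[lfc > fc_threshold & fdr < fdr_threshold] <- "up"
  direction[lfc < -fc_threshold & fdr < fdr_threshold] <- "down"
  out <- data.frame(gene_id = rownames(em$values), log2fc = lfc, t = tt,
                    p = p, fdr = fdr, direction = direction,
                    flagged = flagged, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", class(out))
  out
}

#' Select differentially expressed genes and intersect with modules
#'
#' Applies the strict thresholds `|log2FC| > fc_threshold` and
#' `FDR < fdr_threshold` to split genes into up- and down-regulated lists,
#' and reports the intersection with one or more module gene sets.
#'
#' @param table A `deg_table` from [differential_expression()].
#' @param fc_threshold Absolute log2 fold-change threshold (default 1.0).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param module_genes Character vector or named list of character vectors of
#'   module gene sets (optional).
#' @return A list: `up`, `down` (character vectors), and if module sets were
#'   given, `per_module` (data frame `module`, `n_genes`, `n_up`, `n_down`)
#'   and `module_degs` (named list of the DEG ids per module).
#' @export
select_degs <- function(table, fc_threshold = 1, fdr_threshold = 0.05,
                        module_genes = NULL) {
  stopifnot(fc_threshold > 0, fdr_threshold > 0)
  up <- table$gene_id[table$log2fc > fc_threshold &
                        table$fdr < fdr_threshold]
  down <- table$gene_id[table$log2fc < -fc_threshold &
                          table$fdr < fdr_threshold]
  out <- list(up = up, down = down)
  if (!is.null(module_genes)) {
    if (!is.list(module_genes)) module_genes <- list(module = module_genes)
    out$per_module <- do.call(rbind, lapply(names(module_genes), function(m) {
      g <- module_genes[[m]]
      data.frame(module = m, n_genes = length(g),
                 n_up = length(intersect(g, up)),
                 n_down = length(intersect(g, down)),
                 stringsAsFactors = FALSE)
    }))
    out$module_degs <- lapply(module_genes, function(g)
      intersect(g, c(up, down)))
  }
  out
}
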