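#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power `beta` the unsigned co-expression connectivity
#' `k_i = sum_j |cor(x_i, x_j)|^beta` is computed; the degree distribution is
#' binned on log10(k) and log10 frequency is regressed on log10 mean
#' connectivity per bin. The signed scale-free fit index is `R^2` multiplied
#' by the sign convention that a decreasing relationship (negative slope)
#' counts as positive fit. The chosen power is the smallest candidate whose
#' signed fit reaches `r2_cut`; if none does, the best-fitting candidate is
#' returned with a warning.
#'
#' @param em An [expression_matrix()] with at least 3 samples and 10 genes.
#' @param candidates Integer vector of candidate powers.
#' @param r2_cut Signed scale-free fit threshold (default 0.8).
#' @param n_bins Number of connectivity bins for the fit (default 10).
#' @return A list of class `power_selection`: `table` (data frame `power`,
#'   `sft_r2`, `mean_k`), `power` (chosen), `reached_cut` (logical).
#' @export
pick_soft_threshold <- function(em, candidates = c(1:10, seq(12, 20, 2)),
                                r2_cut = 0.8, n_bins = 10) {
  stopifnot(inherits(em, "expression_matrix"),
            ncol(em$values) >= 3, nrow(em$values) >= 10)
  ac <- abs_cor_checked(em$values)
  tab <- do.call(rbind, lapply(candidates, function(beta) {
    a <- ac^beta
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(power = beta, sft_r2 = scale_free_fit(k, n_bins),
               mean_k = mean(k))
  }))
  rownames(tab) <- NULL
  ok <- which(tab$sft_r2 >= r2_cut)
  if (length(ok)) {
    power <- tab$power[ok[1]]
    reached <- TRUE
  } else {
    power <- tab$power[which.max(tab$sft_r2)]
    reached <- FALSE
    warning("no candidate power reached the scale-free fit cut of ", r2_cut,
            "; using the best-fitting power ", power)
  }
  structure(list(table = tab, power = power, reached_cut = reached),
            class = "power_selection")
}

# |cor| matrix over gene rows, with a hard error for constant genes.
abs_cor_checked <- function(values) {
  v <- apply(values, 1, stats::var)
  bad <- rownames(values)[v <= 0 | !is.finite(v)]
  if (length(bad)) stop("constant gene rows (correlation undefined): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  ac <- abs(stats::cor(t(values)))
  if (any(!is.finite(ac))) stop("non-finite correlations encountered")
  ac
}

# Signed scale-free fit R^2 from a connectivity vector.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Topological overlap matrix from expression
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (with `a_ii = 0` inside
#' the overlap sums) is turned into the topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `TOM_ii = 1` and `k_i = sum_u a_iu`.
#'
#' @param em An [expression_matrix()].
#' @param beta Soft-threshold power (>= 1).
#' @return Symmetric gene x gene matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @export
tom_from_expression <- function(em, beta) {
  stopifnot(inherits(em, "expression_matrix"), beta >= 1)
  a <- abs_cor_checked(em$values)^beta
  diag(a) <- 0
  tom_from_adjacency(a)
}

#' @rdname tom_from_expression
#' @param a Symmetric adjacency matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
tom_from_adjacency <- function(a) {
  stopifnot(is.matrix(a), isSymmetric(unname(a)), all(diag(a) == 0))
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a fixed height; branches smaller than `min_module_size` are
#' relabelled unassigned (label 0). Modules are numbered 1, 2, ... by
#' decreasing size (ties broken by smallest member gene id).
#'
#' @param tom Topological overlap matrix (symmetric, unit diagonal).
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Dendrogram cut height on the `1 - TOM` scale
#'   (default 0.99).
#' @return Named integer vector gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  if (cut_height >= max(tree$height)) {
    raw <- stats::setNames(rep(1L, nrow(tom)), rownames(tom))
  } else {
    raw <- stats::cutree(tree, h = cut_height)
  }
  relabel_by_size(raw, min_module_size)
}

# Renumber cluster labels by decreasing size (ties by smallest member id);
# clusters below min_size become 0.
relabel_by_size <- function(raw, min_size = 1L) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  first_id <- vapply(keep, function(cl) min(names(raw)[raw == cl]),
                     character(1))
  ord <- keep[order(-sizes[keep], first_id)]
  new <- stats::setNames(rep(0L, length(raw)), names(raw))
  for (i in seq_along(ord)) new[raw == ord[i]] <- i
  new
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized gene x sample submatrix, sign-oriented so the mean
#' correlation with the member genes is positive. Unassigned genes
#' (label 0) are excluded.
#'
#' @param em An [expression_matrix()].
#' @param labels Named integer vector gene -> module label.
#' @return Matrix module x sample (rownames `ME1`, `ME2`, ...), each row
#'   unit-norm over samples, with attribute `var_explained` (per-module
#'   proportion of variance captured by the first component).
#' @export
module_eigengenes <- function(em, labels) {
  stopifnot(inherits(em, "expression_matrix"))
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned modules")
  n <- ncol(em$values)
  me <- matrix(NA_real_, length(mods), n,
               dimnames = list(paste0("ME", mods), colnames(em$values)))
  ve <- stats::setNames(numeric(length(mods)), rownames(me))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    if (length(genes) < 2) stop("module ", mods[i], " has fewer than 2 genes")
    x <- t(scale(t(em$values[genes, , drop = FALSE])))
    sv <- svd(x, nu = 0, nv = 1)
    eg <- sv$v[, 1]
    if (mean(stats::cor(eg, t(x))) < 0) eg <- -eg
    me[i, ] <- eg
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- ve
  me
}

#' Merge modules with similar eigengenes
#'
#' Modules are clustered by average linkage on the eigengene dissimilarity
#' `1 - cor`; branches below `merge_height` are merged, eigengenes are
#' recomputed, and the step is iterated until no further merge occurs. The
#' default height 0.25 corresponds to an eigengene correlation of 0.75.
#'
#' @param em An [expression_matrix()].
#' @param labels Named integer vector gene -> module label.
#' @param merge_height Dissimilarity cut (default 0.25).
#' @return A list: `labels` (renumbered by size), `eigengenes`,
#'   `cor_threshold` (`1 - merge_height`), `n_merges`.
#' @export
merge_close_modules <- function(em, labels, merge_height = 0.25) {
  stopifnot(merge_height >= 0, merge_height < 1)
  n_merges <- 0L
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2 || merge_height == 0) break
    me <- module_eigengenes(em, labels)
    d <- stats::as.dist(1 - stats::cor(t(me)))
    tree <- stats::hclust(d, method = "average")
    grp <- stats::cutree(tree, h = merge_height)
    if (max(table(grp)) == 1) break
    remap <- stats::setNames(mods[match(grp, grp)], mods)  # first of group
    for (m in mods) labels[labels == m] <- remap[as.character(m)]
    n_merges <- n_merges + 1L
  }
  labels <- relabel_by_size_keep_zero(labels)
  list(labels = labels,
       eigengenes = if (any(labels > 0)) module_eigengenes(em, labels)
       else NULL,
       cor_threshold = 1 - merge_height,
       n_merges = n_merges)
}

relabel_by_size_keep_zero <- function(labels) {
  assigned <- labels[labels > 0]
  if (!length(assigned)) return(labels)
  new <- relabel_by_size(assigned, min_size = 1L)
  labels[names(new)] <- new
  labels
}

#' Correlate module eigengenes with the phenotype and select modules
#'
#' Pearson correlation between each eigengene and the phenotype indicator
#' (normal = 0, polyp = 1), with a two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Modules
#' with `|r|` strictly above `r_threshold` are selected. A selected module
#' with negative `r` is up in normal colon and down in polyp.
#'
#' @param eigengenes Module x sample eigengene matrix.
#' @param metadata Sample metadata with `phenotype` in `{normal, polyp}`.
#' @param r_threshold Absolute-correlation selection threshold (default 0.3).
#' @return A list: `table` (data frame `module`, `r`, `p`, `selected`),
#'   `selected` (character module ids).
#' @export
module_trait_select <- function(eigengenes, metadata, r_threshold = 0.3) {
  n <- ncol(eigengenes)
  if (n < 3) stop("module-trait correlation requires >= 3 samples")
  stopifnot(identical(colnames(eigengenes), metadata$sample_id))
  z <- as.integer(metadata$phenotype == "polyp")
  r <- as.numeric(stats::cor(t(eigengenes), z))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  tab <- data.frame(module = rownames(eigengenes), r = r, p = p,
                    selected = abs(r) > r_threshold,
                    stringsAsFactors = FALSE)
  list(table = tab, selected = tab$module[tab$selected])
}
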