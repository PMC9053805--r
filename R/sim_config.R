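#' Planted co-expression module description
#'
#' Describes one planted module for the cohort simulator: the member genes, the
#' strength of the association between the module's latent factor and the
#' binary phenotype, the range of per-gene factor loadings, and the subset of
#' members carrying an additional planted differential-expression shift.
#'
#' @param member_genes Character vector of gene ids belonging to the module.
#' @param eigen_effect Correlation strength in `[0, 1]` between the module's
#'   latent factor and the phenotype indicator.
#' @param loading_range Length-2 numeric interval from which per-gene loadings
#'   are drawn uniformly.
#' @param de_genes Character vector (subset of `member_genes`) carrying a
#'   planted expression shift in polyp samples.
#' @param de_lfc Numeric scalar or vector (recycled over `de_genes`): planted
#'   log2 fold change (polyp minus normal) for each DE gene.
#' @param direction `+1` if the module factor is higher in polyp samples,
#'   `-1` if higher in normal samples.
#'
#' @return A list of class `planted_module`.
#' @export
planted_module <- function(member_genes, eigen_effect = 0.6,
                           loading_range = c(0.6, 0.95),
                           de_genes = character(), de_lfc = -2,
                           direction = -1L) {
  stopifnot(length(member_genes) >= 1, !anyDuplicated(member_genes))
  if (eigen_effect < 0 || eigen_effect > 1) {
    stop("eigen_effect must lie in [0, 1]")
  }
  if (length(loading_range) != 2 || loading_range[1] > loading_range[2]) {
    stop("loading_range must be an increasing length-2 interval")
  }
  if (!all(de_genes %in% member_genes)) {
    stop("de_genes must be a subset of member_genes")
  }
  if (!direction %in% c(-1L, 1L)) stop("direction must be +1 or -1")
  de_lfc <- rep_len(de_lfc, length(de_genes))
  structure(list(member_genes = as.character(member_genes),
                 eigen_effect = eigen_effect,
                 loading_range = loading_range,
                 de_genes = as.character(de_genes),
                 de_lfc = de_lfc,
                 direction = as.integer(direction)),
            class = "planted_module")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort / network / ontology
#' generator. The defaults define the package's reference study conditions:
#' 2000 genes, two planted phenotype-linked modules of 50 genes with
#' module-trait correlation 0.6, three batches of 40 samples each with a
#' balanced normal/polyp split, moderate additive and multiplicative batch
#' effects on the log2 scale, a planted-partition functional network whose
#' communities contain the module genes, and a two-namespace annotation DAG
#' whose leaf branches concentrate within network communities.
#'
#' @param n_genes Number of genes in the universe.
#' @param probe_count_probs Probabilities of a gene being measured by
#'   1, 2, ... probes (vector summing to 1).
#' @param unannotated_frac Fraction of additional probes emitted with a
#'   missing (`NA`) gene annotation, exercising the drop rule.
#' @param probe_noise_sd Standard deviation (log2 units) of independent
#'   probe-level noise around the gene value.
#' @param n_samples_per_batch Integer vector: samples in each batch (its
#'   length is the number of batches).
#' @param phenotype_balance Fraction of polyp samples per batch.
#' @param modules List of [planted_module()] objects with disjoint members.
#' @param baseline_range Interval for per-gene baseline log2 intensities.
#' @param batch_shift_sd SD (log2 units) of the per-gene, per-batch additive
#'   batch shift.
#' @param batch_scale_sd SD (log scale) of the per-gene, per-batch
#'   multiplicative noise-scale factor `exp(N(0, batch_scale_sd^2))`.
#' @param noise_sd SD (log2 units) of the per-sample residual noise.
#' @param network List of planted-partition network settings:
#'   `p_within`, `p_between` (edge probabilities, `p_within > p_between`),
#'   `w_within`, `w_between` (uniform weight intervals within `(0, 1]`),
#'   `bg_community_size` (approximate size of background communities),
#'   `tissue_coverage` (fraction of background genes present on the
#'   tissue-expressed list; planted module genes are always tissue-expressed).
#' @param ontology List of annotation-DAG settings: `n_terms` (terms per
#'   namespace, incl. the root), `depth` (number of layers below the root),
#'   `p_is_a` (fraction of is_a vs part_of parent relations),
#'   `p_home` (probability a gene is annotated to its community's home leaf),
#'   `p_second` (probability of an extra random leaf annotation).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `sim_config`, validated.
#' @export
sim_config <- function(n_genes = 2000,
                       probe_count_probs = c(0.5, 0.3, 0.2),
                       unannotated_frac = 0.05,
                       probe_noise_sd = 0.25,
                       n_samples_per_batch = c(40L, 40L, 40L),
                       phenotype_balance = 0.5,
                       modules = NULL,
                       baseline_range = c(4, 12),
                       batch_shift_sd = 0.8,
                       batch_scale_sd = 0.2,
                       noise_sd = 1,
                       network = list(),
                       ontology = list(),
                       seed = 7L) {
  if (is.null(modules)) {
    gene_ids <- default_gene_ids(n_genes)
    modules <- list(
      planted_module(gene_ids[1:50], eigen_effect = 0.6,
                     de_genes = gene_ids[1:30], de_lfc = -1.2, direction = -1L),
      planted_module(gene_ids[51:100], eigen_effect = 0.6,
                     de_genes = gene_ids[51:80], de_lfc = -1.2, direction = -1L)
    )
  }
  network <- utils::modifyList(list(
    p_within = 0.3, p_between = 0.02,
    w_within = c(0.5, 1), w_between = c(0.02, 0.4),
    bg_community_size = 250, tissue_coverage = 0.9
  ), network)
  ontology <- utils::modifyList(list(
    n_terms = 40L, depth = 4L, p_is_a = 0.8,
    p_home = 0.8, p_second = 0.3
  ), ontology)

  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    probe_count_probs = probe_count_probs,
    unannotated_frac = unannotated_frac,
    probe_noise_sd = probe_noise_sd,
    n_samples_per_batch = as.integer(n_samples_per_batch),
    phenotype_balance = phenotype_balance,
    modules = modules,
    baseline_range = baseline_range,
    batch_shift_sd = batch_shift_sd,
    batch_scale_sd = batch_scale_sd,
    noise_sd = noise_sd,
    network = network,
    ontology = ontology,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

default_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, all(cfg$n_samples_per_batch >= 1),
            length(cfg$n_samples_per_batch) >= 1)
  probs <- c(cfg$phenotype_balance, cfg$probe_count_probs,
             cfg$unannotated_frac, cfg$network$p_within,
             cfg$network$p_between, cfg$network$tissue_coverage,
             cfg$ontology$p_is_a, cfg$ontology$p_home, cfg$ontology$p_second)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$network$p_within <= cfg$network$p_between) {
    stop("within-community edge probability must exceed between-community ",
         "probability")
  }
  gene_ids <- default_gene_ids(cfg$n_genes)
  members <- unlist(lapply(cfg$modules, `[[`, "member_genes"))
  if (anyDuplicated(members)) {
    stop("planted module member sets must be disjoint")
  }
  bad <- setdiff(members, gene_ids)
  if (length(bad)) {
    stop("module member ids outside the gene universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (cfg$ontology$n_terms < 1 || cfg$ontology$depth < 1) {
    stop("ontology must have at least one term and one layer")
  }
  invisible(cfg)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
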