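#' Simulate a multi-batch probe-level expression cohort
#'
#' Draws a latent-factor cohort: each planted module has one latent factor per
#' sample, correlated with the binary phenotype at the configured
#' `eigen_effect`; each member gene is `baseline + loading * factor + DE shift
#' + batch shift + batch scale * noise`. Probes replicate their gene's value
#' plus independent probe noise, and a configurable fraction of probes is
#' emitted without a gene annotation to exercise the drop rule.
#'
#' @param config A [sim_config()].
#' @return A list with elements `probes` (a `probe_matrix`: probe x sample
#'   log2 values plus a probe annotation table), `metadata` (a data frame of
#'   `sample_id`, `phenotype`, `batch`) and `truth` (a `planted_truth` list
#'   recording module membership, planted and expected log2 fold changes, and
#'   the drawn batch parameters).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n_genes <- config$n_genes
  gene_ids <- default_gene_ids(n_genes)
  n_batches <- length(config$n_samples_per_batch)

  batch <- rep(seq_len(n_batches), config$n_samples_per_batch)
  n_samples <- length(batch)
  sample_ids <- sprintf("b%d_s%03d", batch,
                        unlist(lapply(config$n_samples_per_batch, seq_len)))
  # fixed number of polyp samples per batch, positions randomized
  phenotype <- unlist(lapply(config$n_samples_per_batch, function(nb) {
    n_polyp <- round(config$phenotype_balance * nb)
    sample(rep(c("polyp", "normal"), c(n_polyp, nb - n_polyp)))
  }))
  z <- as.integer(phenotype == "polyp")
  if (stats::sd(z) == 0) {
    z_std <- rep(0, n_samples)
  } else {
    z_std <- as.numeric(scale(z))
  }

  baseline <- stats::runif(n_genes, config$baseline_range[1],
                           config$baseline_range[2])
  values <- matrix(rep(baseline, n_samples), nrow = n_genes,
                   dimnames = list(gene_ids, sample_ids))

  gene_module <- stats::setNames(rep(0L, n_genes), gene_ids)
  planted_lfc <- stats::setNames(rep(0, n_genes), gene_ids)
  loadings <- stats::setNames(rep(0, n_genes), gene_ids)
  d_z <- if (any(z == 1) && any(z == 0)) {
    mean(z_std[z == 1]) - mean(z_std[z == 0])
  } else 0

  for (mi in seq_along(config$modules)) {
    mod <- config$modules[[mi]]
    ee <- mod$eigen_effect
    f <- mod$direction * ee * z_std +
      sqrt(max(0, 1 - ee^2)) * stats::rnorm(n_samples)
    load <- stats::runif(length(mod$member_genes),
                         mod$loading_range[1], mod$loading_range[2])
    values[mod$member_genes, ] <- values[mod$member_genes, ] +
      outer(load, f)
    gene_module[mod$member_genes] <- mi
    loadings[mod$member_genes] <- load
    if (length(mod$de_genes)) {
      planted_lfc[mod$de_genes] <- mod$de_lfc
      values[mod$de_genes, z == 1] <- values[mod$de_genes, z == 1] +
        mod$de_lfc
    }
  }

  # ComBat-style location/scale batch model: per-gene additive shift plus a
  # multiplicative factor on the residual noise.
  gamma <- matrix(stats::rnorm(n_genes * n_batches, 0, config$batch_shift_sd),
                  n_genes, n_batches)
  delta <- matrix(exp(stats::rnorm(n_genes * n_batches, 0,
                                   config$batch_scale_sd)),
                  n_genes, n_batches)
  noise <- matrix(stats::rnorm(n_genes * n_samples, 0, config$noise_sd),
                  n_genes, n_samples)
  values <- values + gamma[, batch] + delta[, batch] * noise

  # expected realized log2FC = planted shift + module-factor contribution
  expected_lfc <- planted_lfc
  for (mi in seq_along(config$modules)) {
    mod <- config$modules[[mi]]
    expected_lfc[mod$member_genes] <- expected_lfc[mod$member_genes] +
      loadings[mod$member_genes] * mod$direction * mod$eigen_effect * d_z
  }

  # probe replication: 1..k probes per gene, plus unannotated filler probes
  n_probes_gene <- sample(seq_along(config$probe_count_probs), n_genes,
                          replace = TRUE, prob = config$probe_count_probs)
  probe_gene <- rep(gene_ids, n_probes_gene)
  n_real <- length(probe_gene)
  n_na <- round(config$unannotated_frac * n_real)
  probe_ids <- sprintf("p%06d", seq_len(n_real + n_na))
  probe_values <- values[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(n_real * n_samples, 0, config$probe_noise_sd),
           n_real, n_samples)
  if (n_na > 0) {
    filler <- matrix(stats::rnorm(n_na * n_samples, mean(baseline), 2),
                     n_na, n_samples)
    probe_values <- rbind(probe_values, filler)
    probe_gene <- c(probe_gene, rep(NA_character_, n_na))
  }
  ord <- sample(nrow(probe_values))  # shuffle so gene order is not positional
  probe_values <- probe_values[ord, , drop = FALSE]
  probe_gene <- probe_gene[ord]
  rownames(probe_values) <- probe_ids

  probes <- probe_matrix(
    values = probe_values,
    annotation = data.frame(probe_id = probe_ids, gene_id = probe_gene,
                            stringsAsFactors = FALSE)
  )
  metadata <- data.frame(sample_id = sample_ids, phenotype = phenotype,
                         batch = paste0("batch", batch),
                         stringsAsFactors = FALSE)
  truth <- structure(list(
    gene_module = gene_module,
    planted_lfc = planted_lfc,
    expected_lfc = expected_lfc,
    de_direction = ifelse(planted_lfc > 0, "up",
                          ifelse(planted_lfc < 0, "down", "ns")),
    loadings = loadings,
    batch_shift = gamma, batch_scale = delta,
    gene_values = values,
    communities = NULL, home_terms = NULL,
    seed = config$seed
  ), class = "planted_truth")
  list(probes = probes, metadata = metadata, truth = truth)
}

#' Simulate a weighted planted-partition functional interaction network
#'
#' Nodes are the gene universe; planted co-expression modules each form one
#' community and the remaining genes are split into background communities.
#' Within-community edges are drawn with higher probability and higher
#' uniform weights than between-community edges; weights lie in `(0, 1]`.
#' The true community labels and a tissue-expressed gene list (all module
#' genes plus a configurable fraction of the background) are recorded on the
#' returned truth.
#'
#' @param config A [sim_config()].
#' @param truth The `planted_truth` from [simulate_cohort()] (updated in the
#'   return value); may be `NULL` for standalone use.
#' @return A list with `network` (an igraph `functional_network`),
#'   `tissue_genes` (character vector) and the updated `truth` (gains
#'   `communities`, a named integer vector).
#' @export
simulate_network <- function(config, truth = NULL) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, simulate_network_impl(config, truth))
}

simulate_network_impl <- function(config, truth) {
  net_cfg <- config$network
  gene_ids <- default_gene_ids(config$n_genes)
  comm <- stats::setNames(rep(NA_integer_, config$n_genes), gene_ids)
  ci <- 0L
  for (mod in config$modules) {
    ci <- ci + 1L
    comm[mod$member_genes] <- ci
  }
  bg <- names(comm)[is.na(comm)]
  if (length(bg)) {
    n_bg_comm <- max(1L, round(length(bg) / net_cfg$bg_community_size))
    comm[bg] <- ci + rep_len(seq_len(n_bg_comm), length(bg))
  }

  edges <- draw_planted_edges(comm, net_cfg)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = gene_ids)
  g <- as_functional_network(g)

  n_module <- sum(comm <= length(config$modules) & !is.na(comm)) *
    (length(config$modules) > 0)
  module_genes <- unlist(lapply(config$modules, `[[`, "member_genes"))
  keep_bg <- sample(bg, round(net_cfg$tissue_coverage * length(bg)))
  tissue_genes <- sort(c(module_genes, keep_bg))

  if (is.null(truth)) {
    truth <- structure(list(), class = "planted_truth")
  }
  truth$communities <- comm
  truth$tissue_genes <- tissue_genes
  list(network = g, tissue_genes = tissue_genes, truth = truth)
}

# Sample edges block-wise over community pairs; returns a data.frame
# (from, to, weight) with no duplicates or self-loops.
draw_planted_edges <- function(comm, net_cfg) {
  ids <- names(comm)
  k <- sort(unique(comm))
  out <- vector("list", length(k) * (length(k) + 1) / 2)
  idx <- 0L
  for (a in seq_along(k)) {
    for (b in a:length(k)) {
      na_ <- ids[comm == k[a]]
      nb_ <- ids[comm == k[b]]
      within <- a == b
      p <- if (within) net_cfg$p_within else net_cfg$p_between
      wr <- if (within) net_cfg$w_within else net_cfg$w_between
      if (within) {
        n_pairs <- length(na_) * (length(na_) - 1) / 2
      } else {
        n_pairs <- length(na_) * length(nb_)
      }
      if (n_pairs == 0 || p == 0) next
      n_edges <- stats::rbinom(1, n_pairs, p)
      if (n_edges == 0) next
      pick <- sample.int(n_pairs, n_edges)
      if (within) {
        pr <- linear_to_pair(pick, length(na_))
        from <- na_[pr[, 1]]; to <- na_[pr[, 2]]
      } else {
        from <- na_[((pick - 1) %% length(na_)) + 1]
        to <- nb_[((pick - 1) %/% length(na_)) + 1]
      }
      w <- stats::runif(n_edges, wr[1], wr[2])
      w[w <= 0] <- .Machine$double.eps
      w[w > 1] <- 1
      idx <- idx + 1L
      out[[idx]] <- data.frame(from = from, to = to, weight = w,
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(idx)])
}

# Map linear indices of the strict upper triangle of an n x n matrix
# (column-major over pairs i < j) back to (i, j).
linear_to_pair <- function(lin, n) {
  j <- ceiling((1 + sqrt(1 + 8 * lin)) / 2)
  i <- lin - (j - 1) * (j - 2) / 2
  cbind(i, j)
}

#' Simulate a layered annotation DAG and gene annotations
#'
#' Builds one rooted, acyclic, layered DAG per namespace (`BP`, `MF`); every
#' non-root term has one or two parents in the previous layer with relation
#' `is_a` or `part_of` (configurable mix). Each planted network community is
#' assigned a "home" leaf term, and its genes are annotated predominantly to
#' that leaf, so functional classes concentrate within communities.
#'
#' @param config A [sim_config()].
#' @param truth A `planted_truth` carrying `communities` (from
#'   [simulate_network()]); if absent, every gene forms one community.
#' @return A list with `dag` (an `ontology_dag`), `annotations` (an
#'   `annotation_map`) and the updated `truth` (gains `home_terms`).
#' @export
simulate_ontology <- function(config, truth = NULL) {
  validate_sim_config(config)
  with_seed(config$seed + 2L, simulate_ontology_impl(config, truth))
}

simulate_ontology_impl <- function(config, truth) {
  ont <- config$ontology
  gene_ids <- default_gene_ids(config$n_genes)
  comm <- if (!is.null(truth$communities)) truth$communities else
    stats::setNames(rep(1L, config$n_genes), gene_ids)

  all_edges <- list(); all_terms <- list(); ann <- list()
  home <- list()
  for (ns in c("BP", "MF")) {
    n_terms <- ont$n_terms
    root <- sprintf("%s:0000", ns)
    if (n_terms == 1) {
      terms <- data.frame(term = root, namespace = ns, layer = 0L,
                          stringsAsFactors = FALSE)
      edges <- data.frame(child = character(), parent = character(),
                          relation = character(), stringsAsFactors = FALSE)
      leaves <- root
    } else {
      n_rest <- n_terms - 1L
      depth <- min(ont$depth, n_rest)
      # layer sizes grow roughly geometrically toward the leaves
      w <- 2^(seq_len(depth) - 1)
      sizes <- pmax(1L, round(n_rest * w / sum(w)))
      while (sum(sizes) > n_rest) sizes[which.max(sizes)] <-
          sizes[which.max(sizes)] - 1L
      while (sum(sizes) < n_rest) sizes[depth] <- sizes[depth] + 1L
      term_id <- sprintf("%s:%04d", ns, seq_len(n_rest))
      layer <- rep(seq_len(depth), sizes)
      terms <- data.frame(term = c(root, term_id), namespace = ns,
                          layer = c(0L, layer), stringsAsFactors = FALSE)
      edges <- list()
      for (li in seq_len(depth)) {
        children <- term_id[layer == li]
        parents <- terms$term[terms$layer == li - 1L]
        for (ch in children) {
          n_par <- if (length(parents) > 1 && stats::runif(1) < 0.3) 2L else 1L
          par <- sample(parents, n_par)
          rel <- ifelse(stats::runif(n_par) < ont$p_is_a, "is_a", "part_of")
          edges[[length(edges) + 1L]] <-
            data.frame(child = ch, parent = par, relation = rel,
                       stringsAsFactors = FALSE)
        }
      }
      edges <- do.call(rbind, edges)
      leaves <- setdiff(terms$term, edges$parent)
    }
    all_terms[[ns]] <- terms
    all_edges[[ns]] <- edges

    # home-leaf annotation per community
    communities <- sort(unique(comm))
    home_leaf <- stats::setNames(
      leaves[((seq_along(communities) - 1) %% length(leaves)) + 1],
      communities)
    # shuffle the assignment so BP and MF branches differ
    home_leaf[] <- sample(home_leaf)
    home[[ns]] <- home_leaf
    gene_home <- home_leaf[as.character(comm[gene_ids])]
    use_home <- stats::runif(length(gene_ids)) < ont$p_home
    primary <- ifelse(use_home, gene_home,
                      sample(leaves, length(gene_ids), replace = TRUE))
    extra <- stats::runif(length(gene_ids)) < ont$p_second
    ann[[ns]] <- data.frame(
      gene_id = c(gene_ids, gene_ids[extra]),
      term_id = c(primary, sample(leaves, sum(extra), replace = TRUE)),
      namespace = ns, stringsAsFactors = FALSE)
  }

  dag <- ontology_dag(edges = do.call(rbind, all_edges),
                      terms = do.call(rbind, all_terms))
  annotations <- annotation_map(do.call(rbind, ann), dag)
  if (is.null(truth)) truth <- structure(list(), class = "planted_truth")
  truth$home_terms <- home
  list(dag = dag, annotations = annotations, truth = truth)
}

#' Simulate every pipeline input at once
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_network()] and
#' [simulate_ontology()] under the configured seed and returning the combined
#' artifact list with a single consistent truth object.
#'
#' @param config A [sim_config()].
#' @return A list: `probes`, `metadata`, `network`, `tissue_genes`, `dag`,
#'   `annotations`, `truth`.
#' @export
simulate_all <- function(config) {
  co <- simulate_cohort(config)
  ne <- simulate_network(config, co$truth)
  on <- simulate_ontology(config, ne$truth)
  list(probes = co$probes, metadata = co$metadata,
       network = ne$network, tissue_genes = ne$tissue_genes,
       dag = on$dag, annotations = on$annotations, truth = on$truth)
}

#' Write simulated inputs to a directory of plain-text files
#'
#' Emits the TSV/GMT/JSON formats consumed by the pipeline stages: probe
#' matrix, probe annotation, sample metadata, network edge list, tissue gene
#' list, ontology edges, gene-term annotations, a GMT of leaf-term gene sets,
#' and the planted truth as JSON.
#'
#' @param sim Result of [simulate_all()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    probe_matrix = file.path(outdir, "probe_matrix.tsv"),
    probe_annotation = file.path(outdir, "probe_annotation.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    network = file.path(outdir, "network_edges.tsv"),
    tissue = file.path(outdir, "tissue_genes.txt"),
    ontology = file.path(outdir, "ontology.tsv"),
    annotations = file.path(outdir, "annotations.tsv"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    truth = file.path(outdir, "truth.json")
  )
  # %.17g so that doubles round-trip exactly through the text format
  vals <- sim$probes$values
  pm <- data.frame(probe_id = rownames(vals),
                   matrix(sprintf("%.17g", vals), nrow(vals),
                          dimnames = dimnames(vals)),
                   check.names = FALSE)
  utils::write.table(pm, paths["probe_matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$probes$annotation, paths["probe_annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  el <- network_edges(sim$network)
  el$weight <- sprintf("%.17g", el$weight)
  utils::write.table(el, paths["network"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$tissue_genes, paths["tissue"])
  utils::write.table(sim$dag$edges, paths["ontology"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotations$table, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(annotation_gene_sets(sim$annotations, "BP"), paths["gmt"])
  truth_json <- sim$truth
  truth_json$batch_shift <- NULL; truth_json$batch_scale <- NULL
  truth_json$gene_values <- NULL
  jsonlite::write_json(unclass(truth_json), paths["truth"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
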