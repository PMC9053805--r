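#' Pipeline configuration
#'
#' Collects every input and stage parameter of the end-to-end run. Defaults
#' equal the published analysis settings: weight cut 0.1, scale-free fit cut
#' 0.8, module-merge height 0.25, module-trait threshold 0.3, MCL inflation
#' 1.2 / expansion 2, DEG thresholds |log2FC| > 1.0 and FDR < 0.05,
#' enrichment FDR <= 0.05.
#'
#' @param inputs Either a list from [simulate_all()] (in-memory run) or a
#'   named list of file paths: `probe_matrix`, `probe_annotation`,
#'   `metadata`, `network`, `tissue`, `ontology`, `annotations`.
#' @param validation Named list of validation cohorts, each a list with
#'   `probes` (a `probe_matrix`) and `metadata`; validation cohorts are
#'   analyzed independently and are never batch-corrected or merged.
#' @param compounds Optional compound table (`compound`, `target`, `action`,
#'   `description`) for the action-type filter.
#' @param outdir Output directory for artifacts and the manifest (`NULL` for
#'   an in-memory run).
#' @param power Soft-threshold power, or `NULL` to choose it by the
#'   scale-free criterion.
#' @param r2_cut,cut_height,min_module_size,merge_height,trait_r
#'   Co-expression stage parameters.
#' @param min_weight,mcl_inflation,mcl_expansion,spectral_k Network and
#'   clustering parameters (`spectral_k = NULL`: use the MCL cluster count).
#' @param fc_threshold,fdr_threshold,enrich_fdr,min_submodule_size,top_n
#'   DEG, enrichment and submodule-selection parameters.
#' @param seed Integer seed fanned out to the seeded stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, validation = list(), compounds = NULL,
                            outdir = NULL, power = NULL, r2_cut = 0.8,
                            cut_height = 0.99, min_module_size = 30,
                            merge_height = 0.25, trait_r = 0.3,
                            min_weight = 0.1, mcl_inflation = 1.2,
                            mcl_expansion = 2L, spectral_k = NULL,
                            fc_threshold = 1, fdr_threshold = 0.05,
                            enrich_fdr = 0.05, min_submodule_size = 10,
                            top_n = 3, seed = 0L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_inputs <- function(paths) {
  required <- c("probe_matrix", "probe_annotation", "metadata", "network",
                "tissue", "ontology", "annotations")
  missing_keys <- setdiff(required, names(paths))
  if (length(missing_keys)) stop("missing input paths: ",
                                 paste(missing_keys, collapse = ", "))
  for (key in required) {
    if (!file.exists(paths[[key]])) {
      stop("input file for '", key, "' not found: ", paths[[key]])
    }
  }
  ont <- read_ontology(paths$ontology, paths$annotations)
  list(probes = read_probe_matrix(paths$probe_matrix,
                                  paths$probe_annotation),
       metadata = read_metadata(paths$metadata),
       network = read_network(paths$network),
       tissue_genes = readLines(paths$tissue),
       dag = ont$dag, annotations = ont$annotations)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the cascaded pipeline end to end
#'
#' Executes the stages in order: preprocess (probe aggregation +
#' empirical-Bayes batch correction), co-expression module detection and
#' module-trait selection, mapping of the selected module genes onto the
#' tissue-filtered functional network, graph clustering with MCL / greedy
#' modularity / spectral, partition scoring, differential expression,
#' over-representation analysis of the top-ranked submodules, independent
#' validation, and the final biomarker report. Artifacts and a manifest
#' (parameter set, seed, file hashes) are written when `outdir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the per-stage artifacts:
#'   `expression` (corrected cohort), `power_selection`, `modules`,
#'   `module_trait`, `mapped_network`, `partitions`, `reports`, `degs`,
#'   `ranked_submodules`, `enrichment`, `term_graph`, `validation`,
#'   `biomarkers`, `candidates`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- if (!is.null(config$inputs$probes)) config$inputs
  else run_stage("read-inputs", read_pipeline_inputs(config$inputs))

  em <- run_stage("preprocess", {
    agg <- drop_unannotated_and_aggregate(inputs$probes, inputs$metadata)
    if (length(unique(agg$metadata$batch)) >= 2) combat_adjust(agg) else agg
  })

  coexp <- run_stage("wgcna", {
    if (is.null(config$power)) {
      ps <- pick_soft_threshold(em, r2_cut = config$r2_cut)
    } else {
      ps <- list(table = NULL, power = config$power, reached_cut = NA)
    }
    tom <- tom_from_expression(em, ps$power)
    labels0 <- detect_modules(tom, config$min_module_size,
                              config$cut_height)
    merged <- merge_close_modules(em, labels0, config$merge_height)
    mt <- module_trait_select(merged$eigengenes, em$metadata,
                              config$trait_r)
    list(power_selection = ps, labels = merged$labels,
         eigengenes = merged$eigengenes, module_trait = mt)
  })
  selected_mods <- as.integer(sub("^ME", "", coexp$module_trait$selected))
  if (!length(selected_mods)) {
    stop("pipeline stage 'wgcna' failed: no module passed the ",
         "module-trait threshold |r| > ", config$trait_r, call. = FALSE)
  }
  selected_genes <- names(coexp$labels)[coexp$labels %in% selected_mods]

  mapped <- run_stage("map-network", {
    fin <- filter_network(inputs$network, config$min_weight,
                          inputs$tissue_genes)
    lc <- largest_component(fin)
    sub <- induced_submodule(lc$network, selected_genes)
    list(fin = lc, submodule = sub)
  })

  degs <- run_stage("dge", {
    differential_expression(em, fc_threshold = config$fc_threshold,
                            fdr_threshold = config$fdr_threshold)
  })

  partitions <- run_stage("cluster", {
    p_mcl <- mcl(mapped$submodule, inflation = config$mcl_inflation,
                 expansion = config$mcl_expansion)
    k <- if (is.null(config$spectral_k)) max(2L, n_clusters(p_mcl))
    else config$spectral_k
    list(mcl = p_mcl,
         fn = fn_cluster(mapped$submodule),
         spectral = spectral_cluster(mapped$submodule,
                                     k = min(k, igraph::vcount(
                                       mapped$submodule)),
                                     seed = config$seed))
  })

  reports <- run_stage("evaluate", {
    lapply(partitions, function(p)
      evaluate_partition(mapped$submodule, p, inputs$annotations,
                         inputs$dag, degs))
  })

  ranked <- run_stage("rank-submodules", {
    select_submodules(reports, min_size = config$min_submodule_size,
                      top_n = config$top_n)
  })

  # genes and training directions of the top-ranked submodules
  biomarker_rows <- do.call(rbind, lapply(seq_len(nrow(ranked)), function(i) {
    p <- partitions[[ranked$algorithm[i]]]
    genes <- names(p)[unclass(p) == ranked$cluster[i]]
    dd <- degs[match(genes, degs$gene_id), ]
    keep <- dd$direction != "ns"
    if (!any(keep)) return(NULL)
    data.frame(gene_id = genes[keep],
               submodule = paste0(ranked$algorithm[i], "_",
                                  ranked$cluster[i]),
               direction = dd$direction[keep], stringsAsFactors = FALSE)
  }))

  enrich <- run_stage("enrich", {
    if (is.null(biomarker_rows) || !nrow(biomarker_rows)) {
      list(table = NULL, graph = NULL)
    } else {
      top_genes <- unique(unlist(lapply(seq_len(nrow(ranked)), function(i) {
        p <- partitions[[ranked$algorithm[i]]]
        names(p)[unclass(p) == ranked$cluster[i]]
      })))
      collections <- list(BP = annotation_gene_sets(inputs$annotations, "BP"),
                          MF = annotation_gene_sets(inputs$annotations, "MF"))
      tab <- ora(intersect(top_genes, rownames(em$values)), collections,
                 rownames(em$values), config$enrich_fdr)
      gr <- if (any(tab$significant & tab$overlap_size > 0)) {
        term_gene_graph(tab, degs)
      } else NULL
      list(table = tab, graph = gr)
    }
  })

  validation <- run_stage("validate", {
    if (!length(config$validation) || is.null(biomarker_rows)) NULL
    else {
      vdegs <- lapply(config$validation, function(vc) {
        vem <- drop_unannotated_and_aggregate(vc$probes, vc$metadata)
        differential_expression(vem, fc_threshold = config$fc_threshold,
                                fdr_threshold = config$fdr_threshold)
      })
      validate_overlap(biomarker_rows, vdegs)
    }
  })

  candidates <- run_stage("report", {
    if (is.null(config$compounds) || is.null(validation)) NULL
    else {
      conc <- validation$records[validation$records$concordant, ]
      drug_action_filter(conc, config$compounds)
    }
  })

  result <- structure(list(
    expression = em, power_selection = coexp$power_selection,
    modules = coexp$labels, eigengenes = coexp$eigengenes,
    module_trait = coexp$module_trait, selected_genes = selected_genes,
    mapped_network = mapped, partitions = partitions, reports = reports,
    degs = degs, ranked_submodules = ranked, enrichment = enrich,
    validation = validation, biomarkers = biomarker_rows,
    candidates = candidates, config = config
  ), class = "pipeline_result")
  result$manifest <- run_stage("manifest", write_pipeline_artifacts(result))
  result
}

# Write the main artifacts as TSV/JSON and return a manifest with their
# md5 hashes, the parameters and the seed. In-memory runs (outdir NULL)
# get a manifest hashing serialized artifacts instead of files.
write_pipeline_artifacts <- function(result) {
  config <- result$config
  params <- config[setdiff(names(config),
                           c("inputs", "validation", "compounds", "outdir"))]
  if (is.null(config$outdir)) {
    hashes <- vapply(list(modules = result$modules, degs = result$degs,
                          ranked = result$ranked_submodules),
                     function(x) digest_obj(x), character(1))
    return(list(params = params, seed = config$seed, hashes = as.list(hashes)))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(modules = file.path(outdir, "module_labels.tsv"),
             module_trait = file.path(outdir, "module_trait.tsv"),
             degs = file.path(outdir, "deg_table.tsv"),
             ranked = file.path(outdir, "ranked_submodules.tsv"))
  utils::write.table(data.frame(gene_id = names(result$modules),
                                module = unclass(result$modules)),
                     paths["modules"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$module_trait$table, paths["module_trait"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$degs, paths["degs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$ranked_submodules, paths["ranked"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$enrichment$table)) {
    utils::write.table(result$enrichment$table,
                       file.path(outdir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$enrichment$graph)) {
    write_term_gene_graph(result$enrichment$graph,
                          json_path = file.path(outdir,
                                                "term_gene_graph.json"),
                          dot_path = file.path(outdir,
                                               "term_gene_graph.dot"))
  }
  if (!is.null(result$validation)) {
    utils::write.table(result$validation$records,
                       file.path(outdir, "validation_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$candidates)) {
    utils::write.table(result$candidates,
                       file.path(outdir, "drug_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(params = params, seed = config$seed,
                   hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  manifest
}

digest_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, compress = FALSE, version = 2)
  unname(tools::md5sum(tmp))
}
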