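#' Rank submodules by biological evaluation criteria
#'
#' Operationalizes the selection of the biologically strongest submodules:
#' among submodules with at least `min_size` genes and at least one
#' differentially expressed member, each of BHI, Wang-BP and Wang-MF is
#' min-max normalized across the qualifying submodules and the three are
#' averaged; submodules are ranked by that score.
#'
#' @param reports List of `metric_report` objects (one per clustering
#'   algorithm), as returned by [evaluate_partition()].
#' @param min_size Minimum submodule size (default 10).
#' @param top_n Number of submodules to return (default 3).
#' @return Data frame `algorithm`, `cluster`, `size`, `bhi`, `wang_bp`,
#'   `wang_mf`, `n_down`, `n_up`, `score`, `rank`, at most `top_n` rows
#'   (empty, with a warning, if nothing qualifies).
#' @export
select_submodules <- function(reports, min_size = 10, top_n = 3) {
  stopifnot(length(reports) >= 1)
  tab <- do.call(rbind, lapply(reports, function(rep) {
    cbind(algorithm = rep$algorithm, rep$submodules,
          stringsAsFactors = FALSE)
  }))
  tab <- tab[tab$size >= min_size & (tab$n_down + tab$n_up) >= 1 &
               !is.na(tab$bhi) & !is.na(tab$wang_bp) & !is.na(tab$wang_mf), ]
  if (!nrow(tab)) {
    warning("no submodule qualifies (size and DEG filters)")
    return(tab)
  }
  minmax <- function(x) {
    if (max(x) == min(x)) return(rep(1, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  tab$score <- (minmax(tab$bhi) + minmax(tab$wang_bp) +
                  minmax(tab$wang_mf)) / 3
  tab <- tab[order(-tab$score, tab$algorithm, tab$cluster), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  utils::head(tab, top_n)
}

#' Validate training submodule genes on independent cohorts
#'
#' Each validation cohort is analyzed independently (no merging, no batch
#' correction); its DEG lists are intersected with the training submodule
#' genes and direction agreement is recorded. A biomarker is concordant if
#' at least one cohort reproduces its training direction.
#'
#' @param training Data frame with columns `gene_id`, `submodule`,
#'   `direction` (training up/down).
#' @param validation_degs Named list of `deg_table`s, one per validation
#'   cohort, each already thresholded via its own `direction` column.
#' @return A list: `records` (data frame with one row per gene: training
#'   direction, per-cohort direction, `concordant`), `summary` (data frame of
#'   concordant up/down counts per submodule and cohort).
#' @export
validate_overlap <- function(training, validation_degs) {
  stopifnot(all(c("gene_id", "submodule", "direction") %in% names(training)))
  if (!length(validation_degs)) stop("at least one validation cohort needed")
  records <- training
  for (cn in names(validation_degs)) {
    dt <- validation_degs[[cn]]
    if (!sum(dt$direction != "ns")) {
      warning("validation cohort ", cn, " has an empty DEG list")
    }
    dir <- rep("absent", nrow(records))
    hit <- records$gene_id %in% dt$gene_id
    dir[hit] <- dt$direction[match(records$gene_id[hit], dt$gene_id)]
    records[[paste0("dir_", cn)]] <- dir
  }
  dir_cols <- paste0("dir_", names(validation_degs))
  records$concordant <- apply(records[, dir_cols, drop = FALSE] ==
                                records$direction, 1, any)
  summary <- do.call(rbind, lapply(names(validation_degs), function(cn) {
    do.call(rbind, lapply(unique(records$submodule), function(sm) {
      r <- records[records$submodule == sm, ]
      agree <- r[[paste0("dir_", cn)]] == r$direction
      data.frame(submodule = sm, cohort = cn,
                 n_genes = nrow(r),
                 concordant_down = sum(agree & r$direction == "down"),
                 concordant_up = sum(agree & r$direction == "up"),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(records = records, summary = summary)
}

#' Filter candidate compounds by action type
#'
#' Keeps compounds whose action class matches the biomarker's expression
#' change: inhibitory actions (antagonist, inhibitor, blocker) for
#' up-regulated targets, activating actions (agonist, activator) for
#' down-regulated targets. Rows with an action outside the vocabulary are
#' skipped with a warning.
#'
#' @param biomarkers Data frame with columns `gene_id`, `direction`
#'   (`up`/`down`), typically concordant records from [validate_overlap()].
#' @param compounds Data frame with columns `compound`, `target`, `action`,
#'   optional `description`.
#' @param action_classes Named list mapping class -> action synonyms;
#'   editable vocabulary.
#' @return Data frame `target`, `expression`, `compound`, `action`,
#'   `description` of the retained candidates.
#' @export
drug_action_filter <- function(biomarkers, compounds,
                               action_classes = list(
                                 inhibitory = c("antagonist", "inhibitor",
                                                "blocker"),
                                 activating = c("agonist", "activator"))) {
  stopifnot(all(c("gene_id", "direction") %in% names(biomarkers)),
            all(c("compound", "target", "action") %in% names(compounds)))
  if (is.null(compounds$description)) compounds$description <- ""
  action <- tolower(compounds$action)
  known <- unlist(action_classes)
  unknown <- !(action %in% known)
  if (any(unknown)) {
    warning("skipping rows with unknown action types: ",
            paste(unique(compounds$action[unknown]), collapse = ", "))
  }
  dir <- stats::setNames(biomarkers$direction, biomarkers$gene_id)
  keep <- !unknown & compounds$target %in% names(dir) & (
    (dir[compounds$target] == "up" & action %in% action_classes$inhibitory) |
      (dir[compounds$target] == "down" &
         action %in% action_classes$activating))
  out <- data.frame(target = compounds$target[keep],
                    expression = unname(dir[compounds$target[keep]]),
                    compound = compounds$compound[keep],
                    action = compounds$action[keep],
                    description = compounds$description[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
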