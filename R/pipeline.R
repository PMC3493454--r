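# Pipeline orchestration: FDR filter -> parsimony grouping ->
# two-unique-peptide rule -> razor counting -> enrichment cascade, with all
# result tables and a run log.

#' Default pipeline configuration
#'
#' The defaults are the reference ranking strategy: PSM FDR 0.5%, stage-1
#' fold 10 (bait vs control), stage-2 fold 2 (bait vs comparator),
#' detection in at least 2 bait runs, two unique peptides per group,
#' decoy prefix `DECOY_`, lower-is-better scores.
#'
#' @param ... overrides of the default fields (`nominal_fdr`, `fold1`,
#'   `fold2`, `min_runs`, `min_unique`, `decoy_prefix`,
#'   `lower_is_better`, `fdr_method`, `psm_paths`, `design_path`,
#'   `out_dir`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(nominal_fdr = 0.005, fold1 = 10, fold2 = 2, min_runs = 2L,
              min_unique = 2L, decoy_prefix = "DECOY_",
              lower_is_better = TRUE, fdr_method = "ratio",
              psm_paths = NULL, design_path = NULL, out_dir = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    abort_nucenrich(sprintf("unknown config field(s): %s",
                            paste(unknown, collapse = ", ")),
                    "nucenrich_validation_error")
  }
  cfg <- modifyList(cfg, override)
  stopifnot(cfg$nominal_fdr > 0, cfg$nominal_fdr <= 1,
            cfg$fold1 > 0, cfg$fold2 > 0,
            is_count(cfg$min_runs), is_count(cfg$min_unique))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys are rejected. `psm_paths` may be a
#' list of files or a directory (all `psm_*.tsv` inside, sorted).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_nucenrich(sprintf("config file not found: '%s'", path),
                    "nucenrich_io_error")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

resolve_psm_paths <- function(psm_paths) {
  if (length(psm_paths) == 1L && dir.exists(psm_paths)) {
    psm_paths <- sort_c(list.files(psm_paths, pattern = "^psm_.*\\.tsv$",
                                   full.names = TRUE))
  }
  if (!length(psm_paths)) {
    abort_nucenrich("no PSM tables to read", "nucenrich_io_error")
  }
  missing <- psm_paths[!file.exists(psm_paths)]
  if (length(missing)) {
    abort_nucenrich(sprintf("PSM table not found: '%s'", missing[1]),
                    "nucenrich_io_error")
  }
  psm_paths
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, nucenrich_error = function(e) {
    abort_nucenrich(sprintf("pipeline stage '%s' failed: %s",
                            name, conditionMessage(e)),
                    "nucenrich_pipeline_error")
  })
}

#' Run the full candidate-discovery pipeline
#'
#' Executes FDR threshold selection, confident-PSM filtering, parsimony
#' grouping, the two-unique-peptide rule, razor spectral counting and the
#' two-stage enrichment cascade, either on in-memory inputs (`psms` +
#' `design`) or on the files named in the config. When `config$out_dir` is
#' set, writes `groups.tsv`, `counts.tsv`, `candidates.tsv`,
#' `heatmap_matrix.tsv`, `funnel.tsv`, `overlap.tsv` and `run_log.txt`
#' there; re-running on the same inputs reproduces the files byte for
#' byte.
#'
#' @param config a [pipeline_config()] (or the result of [read_config()]).
#' @param psms optional in-memory [psm_table()] (overrides
#'   `config$psm_paths`).
#' @param design optional in-memory [experiment_design()] (overrides
#'   `config$design_path`).
#' @return List with `selection`, `groups` (post two-peptide rule),
#'   `matrix`, `result` (the `cascade_result`), `config`, and `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), psms = NULL,
                         design = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (is.null(psms)) {
    paths <- pipeline_stage("read_psms", resolve_psm_paths(config$psm_paths))
    tabs <- lapply(paths, read_psm_table, decoy_prefix = config$decoy_prefix)
    psms <- do.call(rbind, tabs)
    psms <- validate_psm_table(psms, config$decoy_prefix)
  }
  if (is.null(design)) {
    if (is.null(config$design_path)) {
      abort_nucenrich("no design given (config$design_path is empty)",
                      "nucenrich_io_error")
    }
    design <- pipeline_stage("read_design", read_design(config$design_path))
  }
  say("input: %d PSMs (%d decoy) across %d runs", nrow(psms),
      sum(psms$is_decoy), length(unique(psms$run_id)))

  selection <- pipeline_stage("fdr_filter", select_threshold(
    psms, config$nominal_fdr, lower_is_better = config$lower_is_better,
    method = config$fdr_method))
  conf <- confident_psms(psms, selection)
  say("fdr: threshold %.3g keeps %d target PSMs (est. FDR %.4g, nominal %g)",
      selection$score_threshold, nrow(conf), selection$estimated_fdr,
      selection$nominal_fdr)

  groups_all <- pipeline_stage("grouping", group_proteins(map_peptides(conf)))
  groups <- apply_two_peptide_rule(groups_all, config$min_unique)
  say("grouping: %d group(s), %d with >= %d unique peptides",
      nrow(groups_all), nrow(groups), config$min_unique)

  assignment <- pipeline_stage("counting", assign_razor(groups, conf))
  m <- count_matrix(groups, assignment, conf, design)
  say("counts: %d of %d confident PSMs razor-assigned", sum(m$counts),
      nrow(conf))

  result <- pipeline_stage("cascade", run_cascade(
    m, fold1 = config$fold1, fold2 = config$fold2,
    min_runs = config$min_runs))
  say("cascade: funnel %d -> %d -> %d (fold1 >= %g, fold2 >= %g, min_runs %d)",
      result$funnel["n_input"], result$funnel["n_stage1"],
      result$funnel["n_stage2"], config$fold1, config$fold2,
      config$min_runs)

  files <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_group_table(groups, p("groups.tsv"))
    write_count_table(m, p("counts.tsv"))
    write_candidate_table(result, p("candidates.tsv"))
    heatmap_export(result, p("heatmap_matrix.tsv"))
    funnel_df <- data.frame(stage = names(result$funnel),
                            n = as.integer(result$funnel))
    write.table(funnel_df, p("funnel.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    ov <- data.frame(region = names(result$overlap_counts),
                     n = as.integer(result$overlap_counts))
    write.table(ov, p("overlap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    writeLines(log_lines, p("run_log.txt"))
    files <- vapply(c("groups.tsv", "counts.tsv", "candidates.tsv",
                      "heatmap_matrix.tsv", "funnel.tsv", "overlap.tsv",
                      "run_log.txt"), p, "")
  }
  list(selection = selection, groups = groups, matrix = m, result = result,
       config = config, files = files)
}

#' Export the candidate heat-map matrix
#'
#' Writes the stage-2 survivors by runs spectral-count matrix, rows ordered
#' by descending summed bait counts — the data behind a top-candidates
#' heat map of amalgamated spectral counts. Rendering (e.g. via
#' \pkg{pheatmap}) is cosmetic and left to the caller; [plot_heatmap()]
#' wraps it when the package is available.
#'
#' @param result a `cascade_result`.
#' @param path optional output TSV path.
#' @return The ordered integer matrix (invisibly when `path` is given).
#' @export
heatmap_export <- function(result, path = NULL) {
  m <- result$matrix
  ids <- result$stage2_survivors
  ids <- ids[order_c(-result$condition_sums[as.character(ids), "BAIT"],
                     result$groups$representative[
                       match(ids, result$groups$group_id)])]
  mat <- m$counts[as.character(ids), , drop = FALSE]
  rownames(mat) <- result$groups$representative[
    match(ids, result$groups$group_id)]
  if (!is.null(path)) {
    out <- data.frame(representative = rownames(mat), stringsAsFactors = FALSE)
    ann <- sprintf("%s (%s/%d)", m$design$run_id, m$design$label,
                   m$design$replicate)
    cm <- mat
    colnames(cm) <- ann
    out <- cbind(out, as.data.frame(cm, check.names = FALSE,
                                    row.names = seq_len(nrow(mat))))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    return(invisible(mat))
  }
  mat
}

#' Plot the candidate heat map
#'
#' Convenience wrapper around \pkg{pheatmap} for the matrix produced by
#' [heatmap_export()].
#'
#' @param result a `cascade_result`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_heatmap <- function(result, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    abort_nucenrich("package 'pheatmap' is required for plotting",
                    "nucenrich_io_error")
  }
  mat <- heatmap_export(result)
  if (!nrow(mat)) {
    abort_nucenrich("no stage-2 survivors to plot", "nucenrich_validation_error")
  }
  pheatmap::pheatmap(log10(mat + 1), cluster_rows = FALSE,
                     cluster_cols = FALSE, ...)
}
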