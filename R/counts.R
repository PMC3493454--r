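# Razor spectral counting over protein groups.

#' Razor-assign confident PSMs to protein groups
#'
#' Attributes each PSM to at most one group so no spectrum is counted
#' twice: a peptide found in exactly one group's peptide set sends its PSMs
#' to that group; a peptide spanning several groups sends them to the group
#' with more unique peptides (ties: lexicographically smaller
#' representative). PSMs whose peptide occurs in no group — possible after
#' the two-unique-peptide rule has removed weakly supported groups — stay
#' unassigned (`NA`).
#'
#' @param groups a `protein_groups` object.
#' @param psms confident target PSMs, a [psm_table()].
#' @return Integer vector of group ids, one per PSM (`NA` = unassigned).
#' @export
assign_razor <- function(groups, psms) {
  if (nrow(psms) == 0L) return(integer(0))
  pep2groups <- split(
    rep(seq_len(nrow(groups)), lengths(groups$peptides)),
    unlist(groups$peptides, use.names = FALSE))
  # resolve each distinct peptide once
  winner <- vapply(pep2groups, function(g) {
    if (length(g) == 1L) return(g)
    g <- g[groups$n_unique[g] == max(groups$n_unique[g])]
    g[order_c(groups$representative[g])[1L]]
  }, 0L)
  idx <- winner[psms$peptide]
  as.integer(groups$group_id[idx])
}

#' Build the spectral-count matrix
#'
#' Tabulates razor-assigned PSMs into a groups-by-runs integer matrix.
#' Runs with no assigned PSM appear as zero columns, so the matrix always
#' has one column per design run, annotated with condition and replicate.
#'
#' @param groups a `protein_groups` object.
#' @param assignment integer vector from [assign_razor()], parallel to
#'   `psms`.
#' @param psms the PSMs the assignment refers to.
#' @param design an [experiment_design()]; every assigned PSM's `run_id`
#'   must appear in it.
#' @return An object of class `spectral_counts`: list with `counts`
#'   (integer matrix, rownames = group ids, colnames = run ids), `groups`,
#'   `design`.
#' @export
count_matrix <- function(groups, assignment, psms, design) {
  stopifnot(length(assignment) == nrow(psms))
  assigned <- !is.na(assignment)
  unknown <- setdiff(unique(psms$run_id[assigned]), design$run_id)
  if (length(unknown)) {
    abort_nucenrich(
      sprintf("PSM run_id '%s' does not appear in the design", unknown[1]),
      "nucenrich_validation_error")
  }
  gid <- factor(assignment[assigned], levels = groups$group_id)
  run <- factor(psms$run_id[assigned], levels = design$run_id)
  counts <- table(gid, run)
  counts <- matrix(as.integer(counts), nrow = nrow(groups),
                   dimnames = list(as.character(groups$group_id),
                                   design$run_id))
  structure(list(counts = counts, groups = groups, design = design),
            class = "spectral_counts")
}

#' Construct a spectral-count matrix directly
#'
#' Wraps a ready-made groups-by-runs integer matrix (e.g. counts exported
#' by another tool, or a packaged fixture) into the `spectral_counts`
#' container the cascade operates on. Each row becomes a singleton protein
#' group.
#'
#' @param counts non-negative integer matrix; columns must match
#'   `design$run_id` (order included).
#' @param design an [experiment_design()].
#' @param representative accession labels, one per row; default rownames.
#' @return A `spectral_counts` object.
#' @export
spectral_counts <- function(counts, design, representative = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(representative)) representative <- sprintf("G%04d", seq_len(nrow(counts)))
  stopifnot(nrow(counts) == length(representative))
  if (!identical(colnames(counts), design$run_id)) {
    abort_nucenrich("count matrix columns must match the design run_ids",
                    "nucenrich_validation_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_nucenrich("counts must be non-negative integers",
                    "nucenrich_validation_error")
  }
  groups <- data.frame(group_id = seq_len(nrow(counts)),
                       representative = as.character(representative),
                       stringsAsFactors = FALSE)
  groups$members <- as.list(groups$representative)
  groups$peptides <- rep(list(character(0)), nrow(counts))
  groups$unique_peptides <- rep(list(character(0)), nrow(counts))
  groups$n_unique <- rep(NA_integer_, nrow(counts))
  class(groups) <- c("protein_groups", "data.frame")
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(groups$group_id)
  structure(list(counts = counts, groups = groups, design = design),
            class = "spectral_counts")
}

#' Read a spectral-count table
#'
#' Reads a TSV with columns `group_id`, `representative` and one column
#' per run (either bare run ids or the annotated
#' `run_id (condition/replicate)` headers written by
#' [write_count_table()]).
#'
#' @param path count table TSV.
#' @param design the [experiment_design()] the columns refer to.
#' @return A `spectral_counts` object.
#' @export
read_count_table <- function(path, design) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE)
  missing <- setdiff(c("group_id", "representative"), names(df))
  if (length(missing)) {
    abort_nucenrich(
      sprintf("count table '%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "nucenrich_format_error")
  }
  run_cols <- sub(" \\(.*\\)$", "", names(df))
  idx <- match(design$run_id, run_cols)
  if (anyNA(idx)) {
    abort_nucenrich(
      sprintf("count table '%s' lacks a column for run '%s'",
              path, design$run_id[which(is.na(idx))[1]]),
      "nucenrich_format_error")
  }
  counts <- as.matrix(df[, idx, drop = FALSE])
  colnames(counts) <- design$run_id
  spectral_counts(counts, design, representative = df$representative)
}

#' Detection matrix
#'
#' A group counts as "detected" in a run when at least one confident PSM
#' was assigned to it there; the replicate-presence rule of the enrichment
#' cascade (detected in at least two of three bait runs) is evaluated on
#' this matrix.
#'
#' @param m a `spectral_counts` object.
#' @return Logical matrix with the same dimensions as `m$counts`.
#' @export
detection_matrix <- function(m) {
  m$counts >= 1L
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf("spectral_counts: %d group(s) x %d run(s), %d spectra\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
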