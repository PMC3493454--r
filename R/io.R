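#' Construct a table of peptide-spectrum matches
#'
#' The atomic evidence unit of the pipeline is the PSM: one MS/MS spectrum
#' assigned to one peptide sequence with a search score. A PSM table is a
#' `data.frame` (class `psm_table`) with columns `run_id`, `spectrum_id`,
#' `peptide`, `charge`, `score`, `proteins` (a list column of accession
#' character vectors) and the derived logical `is_decoy`.
#'
#' Scores follow expectation-value semantics by default: lower is better.
#' A record is a decoy hit iff *every* mapped accession carries the decoy
#' prefix; rows mixing target and decoy accessions are rejected, because a
#' spectrum cannot simultaneously count for and against the error model.
#'
#' @param run_id,spectrum_id character vectors; `spectrum_id` must be unique
#'   within each run.
#' @param peptide uppercase peptide sequences over the 20 amino-acid letters.
#' @param charge positive integer precursor charges.
#' @param score non-negative numeric search scores (lower is better by
#'   default throughout the package).
#' @param proteins list of non-empty character vectors of accessions.
#' @param decoy_prefix accession prefix marking decoy entries.
#' @return A `psm_table` data.frame.
#' @export
psm_table <- function(run_id, spectrum_id, peptide, charge, score, proteins,
                      decoy_prefix = "DECOY_") {
  df <- data.frame(
    run_id = as.character(run_id),
    spectrum_id = as.character(spectrum_id),
    peptide = as.character(peptide),
    charge = as.integer(charge),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  stopifnot(is.list(proteins), length(proteins) == nrow(df))
  df$proteins <- lapply(proteins, as.character)
  validate_psm_table(df, decoy_prefix)
}

validate_psm_table <- function(df, decoy_prefix = "DECOY_") {
  if (nrow(df)) {
    bad_pep <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$peptide)
    if (any(bad_pep)) {
      abort_nucenrich(
        sprintf("invalid peptide sequence for spectrum '%s': '%s'",
                df$spectrum_id[which(bad_pep)[1]],
                df$peptide[which(bad_pep)[1]]),
        "nucenrich_validation_error")
    }
    if (any(lengths(df$proteins) == 0L)) {
      abort_nucenrich("every PSM must map to at least one accession",
                      "nucenrich_validation_error")
    }
    if (any(is.na(df$charge) | df$charge < 1L)) {
      abort_nucenrich("charge must be a positive integer",
                      "nucenrich_validation_error")
    }
    if (any(is.na(df$score) | df$score < 0)) {
      abort_nucenrich("score must be a non-negative number",
                      "nucenrich_validation_error")
    }
    n_decoy <- vapply(df$proteins,
                      function(p) sum(startsWith(p, decoy_prefix)), 0L)
    mixed <- n_decoy > 0L & n_decoy < lengths(df$proteins)
    if (any(mixed)) {
      abort_nucenrich(
        sprintf("spectrum '%s' maps to both target and decoy accessions",
                df$spectrum_id[which(mixed)[1]]),
        "nucenrich_validation_error")
    }
    df$is_decoy <- n_decoy == lengths(df$proteins)
    dup <- duplicated(df[c("run_id", "spectrum_id")])
    if (any(dup)) {
      abort_nucenrich(
        sprintf("duplicate spectrum_id '%s' within run '%s'",
                df$spectrum_id[which(dup)[1]], df$run_id[which(dup)[1]]),
        "nucenrich_validation_error")
    }
  } else {
    df$proteins <- list()
    df$is_decoy <- logical(0)
  }
  attr(df, "decoy_prefix") <- decoy_prefix
  class(df) <- c("psm_table", "data.frame")
  df
}

PSM_COLUMNS <- c("run_id", "spectrum_id", "peptide", "charge", "score",
                 "proteins")

#' Read a PSM table from a tab-separated file
#'
#' The canonical on-disk format is a flat UTF-8 TSV with header columns
#' `run_id`, `spectrum_id`, `peptide`, `charge`, `score`, `proteins`; the
#' `proteins` field is a `";"`-separated accession list. Row order is
#' preserved.
#'
#' @param path path to the TSV file.
#' @param decoy_prefix accession prefix marking decoy entries.
#' @return A [psm_table()] with one record per input row.
#' @export
read_psm_table <- function(path, decoy_prefix = "DECOY_") {
  if (!file.exists(path)) {
    abort_nucenrich(sprintf("PSM table not found: '%s'", path),
                    "nucenrich_io_error")
  }
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(PSM_COLUMNS, names(df))
  if (length(missing)) {
    abort_nucenrich(
      sprintf("PSM table '%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "nucenrich_format_error")
  }
  psm_table(df$run_id, df$spectrum_id, df$peptide,
            charge = as.integer(df$charge), score = as.numeric(df$score),
            proteins = strsplit(df$proteins, ";", fixed = TRUE),
            decoy_prefix = decoy_prefix)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: writing then re-reading reproduces the
#' same record sequence.
#'
#' @param psms a [psm_table()].
#' @param path output path.
#' @export
write_psm_table <- function(psms, path) {
  out <- data.frame(
    run_id = psms$run_id, spectrum_id = psms$spectrum_id,
    peptide = psms$peptide, charge = psms$charge,
    score = formatC(psms$score, format = "g", digits = 15),
    proteins = vapply(psms$proteins, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

CONDITION_ROLES <- c(
  BAIT = "BAIT", "H2A.Z" = "BAIT", H2AZ = "BAIT",
  COMPARATOR = "COMPARATOR", H2A = "COMPARATOR",
  CONTROL = "CONTROL", GFP = "CONTROL")

#' Construct an experiment design
#'
#' Maps LC-MS/MS runs to their pull-down condition and replicate index.
#' Condition labels are normalised to the roles `BAIT` (the variant
#' nucleosome, e.g. H2A.Z), `COMPARATOR` (the canonical nucleosome, H2A)
#' and `CONTROL` (the tag-only background, GFP); the original label is kept
#' for display. The reference design is three replicates per condition.
#'
#' @param run_id unique run identifiers.
#' @param condition condition labels; one of `BAIT`/`H2A.Z`/`H2AZ`,
#'   `COMPARATOR`/`H2A`, `CONTROL`/`GFP` (case-insensitive).
#' @param replicate positive integer replicate indices.
#' @return A data.frame of class `experiment_design` with columns `run_id`,
#'   `condition` (role), `label` (original), `replicate`.
#' @export
experiment_design <- function(run_id, condition, replicate) {
  run_id <- as.character(run_id)
  label <- as.character(condition)
  role <- unname(CONDITION_ROLES[toupper(label)])
  if (anyNA(role)) {
    abort_nucenrich(
      sprintf("unknown condition label '%s' (expected one of %s)",
              label[which(is.na(role))[1]],
              paste(unique(names(CONDITION_ROLES)), collapse = ", ")),
      "nucenrich_validation_error")
  }
  if (anyDuplicated(run_id)) {
    abort_nucenrich(
      sprintf("duplicate run_id '%s' in design",
              run_id[which(duplicated(run_id))[1]]),
      "nucenrich_validation_error")
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate) | replicate < 1L)) {
    abort_nucenrich("replicate must be a positive integer",
                    "nucenrich_validation_error")
  }
  df <- data.frame(run_id = run_id, condition = role, label = label,
                   replicate = replicate, stringsAsFactors = FALSE)
  class(df) <- c("experiment_design", "data.frame")
  df
}

#' Read an experiment design TSV
#'
#' Expects header columns `run_id`, `condition`, `replicate`. A design with
#' fewer than the three roles is accepted here (single-condition count
#' matrices are legal); the enrichment cascade itself refuses to run
#' without BAIT, COMPARATOR and CONTROL.
#'
#' @param path path to the design TSV.
#' @return An [experiment_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    abort_nucenrich(sprintf("design file not found: '%s'", path),
                    "nucenrich_io_error")
  }
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("run_id", "condition", "replicate"), names(df))
  if (length(missing)) {
    abort_nucenrich(
      sprintf("design file '%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "nucenrich_format_error")
  }
  experiment_design(df$run_id, df$condition, as.integer(df$replicate))
}

#' Write an experiment design TSV
#' @param design an [experiment_design()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  out <- data.frame(run_id = design$run_id, condition = design$label,
                    replicate = design$replicate)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

design_runs <- function(design, role) design$run_id[design$condition == role]

#' Read a target/decoy protein FASTA
#'
#' @param path FASTA file of protein sequences; decoy entries carry
#'   `decoy_prefix` on the accession.
#' @param decoy_prefix decoy accession prefix.
#' @return A list with `sequences` (named character vector, accession to
#'   amino-acid sequence), `decoy_prefix`, and logical `is_decoy`.
#' @export
read_protein_db <- function(path, decoy_prefix = "DECOY_") {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (anyDuplicated(names(seqs))) {
    abort_nucenrich("duplicate accession in protein FASTA",
                    "nucenrich_validation_error")
  }
  list(sequences = seqs, decoy_prefix = decoy_prefix,
       is_decoy = startsWith(names(seqs), decoy_prefix))
}

#' Write a protein database to FASTA
#' @param db list as returned by [read_protein_db()].
#' @param path output path.
#' @export
write_protein_db <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequences)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Write the candidate table of an enrichment cascade
#'
#' One row per stage-1 survivor (candidate), flagged with its stage-2
#' status, carrying the per-run spectral counts, per-condition sums and
#' both fold values. Rows are ordered by descending bait spectral-count
#' sum, ties broken by representative accession, so repeated writes of the
#' same result are byte-identical.
#'
#' @param result a `cascade_result` from [run_cascade()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_candidate_table <- function(result, path) {
  df <- candidate_frame(result)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

# Flat character data.frame behind the candidate table; shared by the
# writer and the run report.
candidate_frame <- function(result) {
  m <- result$matrix
  ids <- result$stage1_survivors
  ids <- ids[order_c(-result$condition_sums[as.character(ids), "BAIT"],
                     result$groups$representative[match(ids, result$groups$group_id)])]
  gidx <- match(ids, result$groups$group_id)
  counts <- m$counts[as.character(ids), , drop = FALSE]
  df <- data.frame(
    group_id = as.character(ids),
    representative = result$groups$representative[gidx],
    members = vapply(result$groups$members[gidx], paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  for (r in colnames(counts)) df[[paste0("count.", r)]] <- as.character(counts[, r])
  sums <- result$condition_sums
  df$bait_sum <- as.character(sums[as.character(ids), "BAIT"])
  df$comparator_sum <- as.character(sums[as.character(ids), "COMPARATOR"])
  df$control_sum <- as.character(sums[as.character(ids), "CONTROL"])
  df$fold_vs_control <- format_fold(result$fold_values[as.character(ids), "fold_vs_control"])
  df$fold_vs_comparator <- format_fold(result$fold_values[as.character(ids), "fold_vs_comparator"])
  df$stage1 <- rep("TRUE", length(ids))
  df$stage2 <- ifelse(ids %in% result$stage2_survivors, "TRUE", "FALSE")
  df
}

#' Write a protein-group table
#' @param groups a `protein_groups` object from [group_proteins()].
#' @param path output path.
#' @export
write_group_table <- function(groups, path) {
  out <- data.frame(
    group_id = groups$group_id,
    representative = groups$representative,
    members = vapply(groups$members, paste, "", collapse = ";"),
    peptides = vapply(groups$peptides, paste, "", collapse = ";"),
    n_unique = groups$n_unique,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a spectral-count matrix TSV
#'
#' Header annotates each run column as `run_id (condition/replicate)`.
#'
#' @param m a `spectral_counts` object from [count_matrix()].
#' @param path output path.
#' @export
write_count_table <- function(m, path) {
  ann <- sprintf("%s (%s/%d)", m$design$run_id, m$design$label,
                 m$design$replicate)
  out <- data.frame(group_id = rownames(m$counts),
                    representative = m$groups$representative,
                    stringsAsFactors = FALSE)
  cm <- m$counts
  colnames(cm) <- ann
  out <- cbind(out, as.data.frame(cm, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
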