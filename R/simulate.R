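# Ground-truthed synthetic PSM generator.
#
# Emulates a triplicate three-condition nucleosome AP-MS screen: per run,
# each protein contributes Poisson-many correct PSMs spread uniformly over
# its peptide repertoire; a configurable fraction of PSMs are incorrect
# identifications whose scores are exchangeable with decoy hits and whose
# protein mappings are uniform over the target+decoy database. Planted
# bait-preferring interactors are absent from the tag-only control and
# bound at the generic background rate by the comparator nucleosome, so
# their true bait/comparator enrichment equals `enrichment_fold`.
#
# Score model (expectation-value-like, lower is better):
#   correct:          10^U,  U ~ Uniform(-8, -4)
#   incorrect/decoy:  10^U,  U ~ Uniform(-3,  1)
# The two families are disjoint in location but the estimator never uses
# that fact; calibration tests rely only on target/decoy exchangeability
# of the incorrect population.

#' Simulation parameters
#'
#' Collects and validates the knobs of the synthetic AP-MS screen. The
#' defaults describe the reference study conditions: triplicate runs of
#' bait, comparator and control; 500 background proteins of which 20 are
#' planted bait-preferring interactors at 10-fold enrichment; mean spectral
#' count 3 per background protein per run.
#'
#' @param n_proteins total number of target proteins in the database.
#' @param n_enriched number of planted bait-preferring interactors
#'   (enriched over both control and comparator).
#' @param n_generic number of generic nucleosome binders: present equally
#'   in bait and comparator, absent from the tag-only control (they pass
#'   stage 1 but not stage 2 of the cascade).
#' @param enrichment_fold true bait enrichment of planted proteins over the
#'   background binding rate.
#' @param comparator_fold minimum true bait/comparator fold of planted
#'   proteins; must not exceed `enrichment_fold`.
#' @param peptides_per_protein integer range (length-2 vector) of
#'   repertoire sizes; each protein draws uniformly from it.
#' @param shared_peptide_fraction fraction of each protein's repertoire
#'   borrowed from another protein (degenerate peptides shared between the
#'   two), in `[0, 1)`.
#' @param base_abundance mean spectral count (Poisson rate) per background
#'   protein per run.
#' @param incorrect_psm_rate fraction of all PSMs that are incorrect
#'   identifications, in `[0, 1)`.
#' @param decoy_db logical; include a reversed-sequence decoy database and
#'   let incorrect PSMs map to targets and decoys with equal probability.
#' @param replicates runs per condition.
#' @param overdispersion numeric >= 0; 0 (default) gives Poisson counts,
#'   positive values negative-binomial counts with that dispersion
#'   (variance = mu + overdispersion * mu^2).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 500L, n_enriched = 20L, n_generic = 10L,
                       enrichment_fold = 10, comparator_fold = 2,
                       peptides_per_protein = c(5L, 12L),
                       shared_peptide_fraction = 0.1,
                       base_abundance = 3, incorrect_psm_rate = 0.1,
                       decoy_db = TRUE, replicates = 3L,
                       overdispersion = 0, seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            n_enriched = as.integer(n_enriched),
            n_generic = as.integer(n_generic),
            enrichment_fold = enrichment_fold,
            comparator_fold = comparator_fold,
            peptides_per_protein = as.integer(peptides_per_protein),
            shared_peptide_fraction = shared_peptide_fraction,
            base_abundance = base_abundance,
            incorrect_psm_rate = incorrect_psm_rate,
            decoy_db = isTRUE(decoy_db),
            replicates = as.integer(replicates),
            overdispersion = overdispersion,
            seed = as.integer(seed))
  ok <- p$n_proteins >= 1L && p$n_enriched >= 0L && p$n_generic >= 0L &&
    p$n_enriched + p$n_generic <= p$n_proteins &&
    p$enrichment_fold > 0 && p$comparator_fold > 0 &&
    p$comparator_fold <= p$enrichment_fold &&
    length(p$peptides_per_protein) == 2L &&
    p$peptides_per_protein[1] >= 1L &&
    p$peptides_per_protein[2] >= p$peptides_per_protein[1] &&
    p$shared_peptide_fraction >= 0 && p$shared_peptide_fraction < 1 &&
    p$base_abundance >= 0 && p$incorrect_psm_rate >= 0 &&
    p$incorrect_psm_rate < 1 && p$replicates >= 1L &&
    p$overdispersion >= 0 && !is.na(p$seed)
  if (!isTRUE(ok)) {
    abort_nucenrich("invalid simulation parameters",
                    "nucenrich_validation_error")
  }
  structure(p, class = "sim_params")
}

# fixed-width synthetic accessions: SYN0001, ...
syn_accessions <- function(n) sprintf("SYN%04d", seq_len(n))

random_peptides <- function(n, min_len = 8L, max_len = 15L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(AA_ALPHABET20, l, replace = TRUE), collapse = ""), "")
}

#' Simulate the planted ground truth
#'
#' Draws the protein database of the synthetic screen: accessions, peptide
#' repertoires (abstract tryptic-like peptides; shared peptides realised by
#' borrowing from another protein's repertoire), and per-condition Poisson
#' rates. Planted interactors get bait rate
#' `base_abundance * enrichment_fold`, comparator rate `base_abundance`
#' and control rate 0; generic nucleosome binders get the bait rate in both
#' bait and comparator and 0 in control; background proteins get
#' `base_abundance` everywhere.
#'
#' @param params a [sim_params()] object.
#' @return A data.frame of class `truth_table` with columns `accession`,
#'   `enriched_vs_control`, `enriched_vs_comparator`, `rate_bait`,
#'   `rate_comparator`, `rate_control`, and a list column `peptides`.
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_proteins
  acc <- syn_accessions(n)
  sizes <- sample(params$peptides_per_protein[1]:params$peptides_per_protein[2],
                  n, replace = TRUE)
  pool <- unique(random_peptides(sum(sizes) * 2L))
  if (length(pool) < sum(sizes)) {  # astronomically unlikely collision rate
    pool <- unique(c(pool, random_peptides(sum(sizes))))
  }
  own <- split(pool[seq_len(sum(sizes))], rep(seq_len(n), sizes))
  peptides <- unname(own)
  if (params$shared_peptide_fraction > 0 && n > 1L) {
    for (i in seq_len(n)) {
      k <- round(params$shared_peptide_fraction * sizes[i])
      if (k < 1L) next
      donor <- sample(seq_len(n)[-i], 1L)
      borrowed <- sample(peptides[[donor]], min(k, length(peptides[[donor]])))
      peptides[[i]] <- unique(c(peptides[[i]], borrowed))
    }
  }
  base <- params$base_abundance
  role <- rep("background", n)
  if (params$n_enriched > 0L) role[seq_len(params$n_enriched)] <- "enriched"
  if (params$n_generic > 0L) {
    role[params$n_enriched + seq_len(params$n_generic)] <- "generic"
  }
  bait_hi <- base * params$enrichment_fold
  rate_bait <- ifelse(role == "background", base, bait_hi)
  rate_comparator <- ifelse(role == "generic", bait_hi,
                            base)
  rate_control <- ifelse(role == "background", base, 0)
  out <- data.frame(
    accession = acc,
    enriched_vs_control = role != "background",
    enriched_vs_comparator = role == "enriched",
    rate_bait = rate_bait,
    rate_comparator = rate_comparator,
    rate_control = rate_control,
    stringsAsFactors = FALSE)
  out$peptides <- peptides
  class(out) <- c("truth_table", "data.frame")
  out
}

rcounts <- function(n, mu, overdispersion) {
  if (overdispersion > 0) {
    stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
  } else {
    rpois(n, mu)
  }
}

#' Simulate PSM tables for every run of the design
#'
#' Realises the screen described by a truth table: one PSM table per run
#' (triplicates of BAIT, COMPARATOR, CONTROL), a target(+decoy) protein
#' FASTA, and the experiment design. Correct PSMs carry low
#' expectation-value-like scores and map to every database protein sharing
#' the sampled peptide; incorrect PSMs carry high scores exchangeable with
#' decoy hits and map to one protein drawn uniformly from the target+decoy
#' database.
#'
#' @param truth a `truth_table` from [simulate_truth()].
#' @param params the same [sim_params()] used to build `truth`.
#' @param out_dir optional directory; when given, writes one
#'   `psm_<run>.tsv` per run plus `proteins.fasta`, `design.tsv` and
#'   `truth.tsv` there.
#' @return List with `psms` (a [psm_table()] pooled over runs, plus a
#'   logical column `correct` carrying the generative label), `design`,
#'   `db`, `truth`, and `files` (paths, when `out_dir` was given).
#' @export
simulate_psm_tables <- function(truth, params, out_dir = NULL) {
  stopifnot(inherits(truth, "truth_table"), inherits(params, "sim_params"))
  set.seed(params$seed + 1000003L)
  R <- params$replicates
  design <- experiment_design(
    run_id = c(sprintf("H2AZ_rep%d", seq_len(R)),
               sprintf("H2A_rep%d", seq_len(R)),
               sprintf("GFP_rep%d", seq_len(R))),
    condition = rep(c("H2A.Z", "H2A", "GFP"), each = R),
    replicate = rep(seq_len(R), 3L))

  # target + decoy database: protein sequence = concatenated repertoire
  seqs <- setNames(vapply(truth$peptides, paste, "", collapse = ""),
                   truth$accession)
  if (params$decoy_db) {
    rev_seq <- vapply(strsplit(seqs, ""), function(x)
      paste(rev(x), collapse = ""), "")
    seqs <- c(seqs, setNames(rev_seq, paste0("DECOY_", truth$accession)))
  }
  db <- list(sequences = seqs, decoy_prefix = "DECOY_",
             is_decoy = startsWith(names(seqs), "DECOY_"))

  # peptide -> all target accessions containing it (shared peptides map
  # to every donor), used for correct-PSM protein mappings
  pep_all <- unlist(truth$peptides, use.names = FALSE)
  acc_all <- rep(truth$accession, lengths(truth$peptides))
  pep2acc <- lapply(split(acc_all, pep_all), function(a) sort_c(unique(a)))

  rate_col <- c(BAIT = "rate_bait", COMPARATOR = "rate_comparator",
                CONTROL = "rate_control")
  # flattened repertoires allow vectorised per-PSM peptide draws
  pep_flat <- unlist(truth$peptides, use.names = FALSE)
  rep_len <- lengths(truth$peptides)
  rep_start <- cumsum(c(1L, rep_len[-length(rep_len)]))
  tabs <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    rates <- truth[[rate_col[[design$condition[r]]]]]
    n_per_protein <- rcounts(nrow(truth), rates, params$overdispersion)
    prot_idx <- rep(seq_len(nrow(truth)), n_per_protein)
    n_correct <- length(prot_idx)
    # uniform peptide choice within each protein's repertoire
    j <- floor(runif(n_correct) * rep_len[prot_idx])
    pep <- pep_flat[rep_start[prot_idx] + as.integer(j)]
    rate <- params$incorrect_psm_rate
    n_incorrect <- if (rate > 0) rpois(1L, n_correct * rate / (1 - rate)) else 0L
    inc_pep <- random_peptides(n_incorrect)
    inc_acc <- if (n_incorrect > 0) sample(names(seqs), n_incorrect,
                                           replace = TRUE) else character(0)
    n_tot <- n_correct + n_incorrect
    if (n_tot == 0L) next  # pre-allocated NULL slot stays empty
    score <- c(10^runif(n_correct, -8, -4), 10^runif(n_incorrect, -3, 1))
    proteins <- c(pep2acc[pep], as.list(inc_acc))
    tab <- data.frame(
      run_id = design$run_id[r],
      spectrum_id = sprintf("scan%06d", seq_len(n_tot)),
      peptide = c(pep, inc_pep),
      charge = sample(2:3, n_tot, replace = TRUE),
      score = score,
      stringsAsFactors = FALSE)
    tab$proteins <- proteins
    tab$correct <- c(rep(TRUE, n_correct), rep(FALSE, n_incorrect))
    tabs[[r]] <- tab
  }
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  if (length(tabs)) {
    pooled <- do.call(rbind, tabs)
  } else {
    pooled <- data.frame(run_id = character(0), spectrum_id = character(0),
                         peptide = character(0), charge = integer(0),
                         score = numeric(0), stringsAsFactors = FALSE)
    pooled$proteins <- list()
    pooled$correct <- logical(0)
  }
  correct <- pooled$correct
  pooled$correct <- NULL
  psms <- validate_psm_table(pooled, decoy_prefix = "DECOY_")
  psms$correct <- correct

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (rid in design$run_id) {
      f <- file.path(out_dir, paste0("psm_", rid, ".tsv"))
      write_psm_table(psms[psms$run_id == rid, , drop = FALSE], f)
      files <- c(files, f)
    }
    f_fa <- file.path(out_dir, "proteins.fasta")
    write_protein_db(db, f_fa)
    f_design <- file.path(out_dir, "design.tsv")
    write_design(design, f_design)
    f_truth <- file.path(out_dir, "truth.tsv")
    tt <- truth
    tt$peptides <- vapply(tt$peptides, paste, "", collapse = ";")
    write.table(tt, f_truth, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    files <- c(files, f_fa, f_design, f_truth)
  }
  list(psms = psms, design = design, db = db, truth = truth, files = files)
}

#' Score candidate recovery against the planted truth
#'
#' Sensitivity is the fraction of truly bait-enriched proteins (enriched
#' over both control and comparator) that appear among the members of
#' stage-2 survivor groups; false positives are stage-2 survivor groups
#' containing no truly enriched protein.
#'
#' @param result a `cascade_result` from [run_cascade()].
#' @param truth the `truth_table` the data were simulated from.
#' @return List with `sensitivity`, `n_false_positive_groups`,
#'   `n_enriched`, `n_recovered`.
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(result, "cascade_result"), inherits(truth, "truth_table"))
  members <- result$groups$members[
    match(result$stage2_survivors, result$groups$group_id)]
  all_members <- unique(unlist(members, use.names = FALSE))
  unknown <- setdiff(all_members, truth$accession)
  if (length(unknown)) {
    abort_nucenrich(
      sprintf("survivor accession '%s' is absent from the truth table",
              unknown[1]),
      "nucenrich_validation_error")
  }
  enriched <- truth$accession[truth$enriched_vs_control &
                                truth$enriched_vs_comparator]
  n_rec <- sum(enriched %in% all_members)
  fp <- sum(!vapply(members, function(m) any(m %in% enriched), TRUE))
  list(
    sensitivity = if (length(enriched)) n_rec / length(enriched) else NA_real_,
    n_false_positive_groups = fp,
    n_enriched = length(enriched),
    n_recovered = n_rec)
}
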