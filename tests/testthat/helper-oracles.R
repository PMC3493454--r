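# Independent oracles: deliberately naive implementations used only to
# check the package's algorithms on small instances.

# Exact minimum set cover by exhaustive enumeration over protein subsets.
# Returns the minimum cardinality and whether the minimum cover is unique
# (up to indistinguishable proteins, which are collapsed first).
exact_min_cover <- function(pepmap) {
  prot2pep <- list()
  for (pep in names(pepmap)) {
    for (acc in pepmap[[pep]]) prot2pep[[acc]] <- union(prot2pep[[acc]], pep)
  }
  # collapse proteins with identical peptide sets (mirrors the merge the
  # grouping performs before covering; cover cardinality is unaffected)
  sig <- vapply(prot2pep, function(p) paste(sort(p), collapse = "|"), "")
  sets <- prot2pep[!duplicated(sig)]
  all_pep <- names(pepmap)
  n <- length(sets)
  best <- Inf
  covers <- list()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) > best) next
    if (setequal(unique(unlist(sets[idx])), all_pep)) {
      if (length(idx) < best) {
        best <- length(idx)
        covers <- list(idx)
      } else if (length(idx) == best) {
        covers <- c(covers, list(idx))
      }
    }
  }
  list(size = best, unique = length(covers) == 1L)
}

# Brute-force FDR threshold selection: try every observed score as an
# inclusive cut and keep the most permissive one meeting the nominal level.
brute_force_threshold <- function(psms, nominal_fdr) {
  cuts <- sort(unique(psms$score))
  best <- NULL
  for (cut in cuts) {
    acc <- psms$score <= cut
    n_t <- sum(acc & !psms$is_decoy)
    n_d <- sum(acc & psms$is_decoy)
    est <- if (n_t + n_d == 0) 0 else min(n_d / max(n_t, 1), 1)
    if (n_t >= 1 && est <= nominal_fdr) best <- cut
  }
  best
}

# Random peptide-protein instance for grouping tests; peptide names stay
# inside the amino-acid alphabet so they can double as PSM peptides.
random_pepmap <- function(n_prot, n_pep, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prots <- sprintf("PR%s", aa[seq_len(n_prot)])
  peps <- paste0("PEPTIDE", aa[seq_len(n_pep)])
  m <- lapply(peps, function(p) {
    k <- sample(1:min(3, n_prot), 1)
    sort(sample(prots, k))
  })
  names(m) <- peps
  m
}

# One-PSM-per-peptide table realising a peptide->protein map.
pepmap_psms <- function(pepmap, run_id = "run1") {
  n <- length(pepmap)
  psm_table(run_id = rep(run_id, n),
            spectrum_id = sprintf("s%03d", seq_len(n)),
            peptide = names(pepmap),
            charge = rep(2L, n), score = rep(1e-6, n),
            proteins = unname(pepmap))
}

fixture_counts <- function() {
  design <- read_design(system.file("extdata", "fixture_design.tsv",
                                    package = "nucenrich"))
  read_count_table(system.file("extdata", "fixture_counts.tsv",
                               package = "nucenrich"), design)
}

# Random spectral-count matrix over a triplicate three-condition design.
random_counts <- function(n_groups, seed, lambda = 3) {
  set.seed(seed)
  design <- experiment_design(
    run_id = sprintf("r%d", 1:9),
    condition = rep(c("BAIT", "COMPARATOR", "CONTROL"), each = 3),
    replicate = rep(1:3, 3))
  counts <- matrix(rpois(n_groups * 9, lambda), nrow = n_groups,
                   dimnames = list(NULL, design$run_id))
  spectral_counts(counts, design,
                  representative = sprintf("G%03d", seq_len(n_groups)))
}
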