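# Parsimony protein inference.
#
# Confident peptides are explained by a minimal set of proteins:
#   (i)   proteins with identical peptide sets are merged (indistinguishable);
#   (ii)  proteins holding a peptide no other protein explains are
#         essential and enter the cover outright; the remaining peptides
#         are covered greedily, repeatedly selecting the protein explaining
#         the most still-uncovered peptides (ties: larger total peptide
#         set, then lexicographically smaller accession);
#   (iii) proteins whose peptide set is a subset of a selected protein's
#         set are subsumed into that protein's group.
# A peptide is "unique" when it occurs in exactly one group's peptide set;
# peptides shared only among indistinguishable members of one group
# therefore still count as unique.

#' Map confident peptides to their target accessions
#'
#' Builds the peptide-to-protein evidence map by pooling confident PSMs
#' across every run of every condition: each distinct peptide sequence maps
#' to the union of its accessions. Decoy PSMs must have been removed
#' upstream and are rejected here.
#'
#' @param psms confident target PSMs, a [psm_table()].
#' @return Named list: peptide sequence to sorted character vector of
#'   accessions.
#' @export
map_peptides <- function(psms) {
  if (nrow(psms) == 0L) return(setNames(list(), character(0)))
  if (any(psms$is_decoy)) {
    abort_nucenrich("decoy PSMs must be filtered out before peptide mapping",
                    "nucenrich_validation_error")
  }
  pep <- rep(psms$peptide, lengths(psms$proteins))
  acc <- unlist(psms$proteins, use.names = FALSE)
  sp <- split(acc, pep)  # split() orders names in C locale via factor levels
  lapply(sp, function(a) sort_c(unique(a)))
}

#' Group proteins by parsimony
#'
#' Collapses a peptide-to-protein map into protein groups via
#' indistinguishable-merge, greedy minimal set cover, and subset
#' subsumption (see the package vignette for the exact tie-breaking rules).
#' The result is deterministic: permuting the input PSM rows never changes
#' the grouping.
#'
#' @param pepmap named list from [map_peptides()] (peptide to accessions).
#' @return An object of class `protein_groups`: a data.frame with columns
#'   `group_id` (selection order), `representative`, list columns
#'   `members`, `peptides`, `unique_peptides`, and `n_unique`.
#' @export
group_proteins <- function(pepmap) {
  if (length(pepmap) == 0L) {
    abort_nucenrich("empty peptide map: nothing to group",
                    "nucenrich_validation_error")
  }
  peptides <- sort_c(names(pepmap))
  # invert: protein -> integer peptide ids
  acc_per_pep <- pepmap[peptides]
  pep_ids <- rep(seq_along(peptides), lengths(acc_per_pep))
  accs <- unlist(acc_per_pep, use.names = FALSE)
  prot2pep <- lapply(split(pep_ids, accs), function(p) sort(unique(p)))

  # (i) merge indistinguishable proteins (identical peptide sets)
  sig <- vapply(prot2pep, paste, "", collapse = ",")
  meta_members <- lapply(split(names(prot2pep), sig), sort_c)
  meta_rep <- vapply(meta_members, `[`, "", 1L)
  ord <- order_c(meta_rep)
  meta_members <- meta_members[ord]
  meta_rep <- unname(meta_rep[ord])
  meta_pep <- prot2pep[meta_rep]
  n_meta <- length(meta_rep)
  meta_size <- lengths(meta_pep)

  # (ii) greedy minimal cover over meta-proteins, via a sparse incidence
  # matrix (peptides x metas) so each round is one mat-vec product
  inc <- Matrix::sparseMatrix(
    i = unlist(meta_pep, use.names = FALSE),
    j = rep(seq_len(n_meta), meta_size),
    x = 1, dims = c(length(peptides), n_meta))
  uncovered <- rep(TRUE, length(peptides))
  selectable <- rep(TRUE, n_meta)
  # essential proteins first: a peptide explained by exactly one protein
  # forces that protein into every cover, so anchoring them before the
  # greedy rounds never hurts optimality and removes the classic
  # greedy-overshoot on instances with forced sets
  n_explaining <- Matrix::rowSums(inc)
  essential <- which(Matrix::colSums(inc[n_explaining == 1L, , drop = FALSE]) > 0)
  selected <- as.integer(essential)
  if (length(selected)) {
    selectable[selected] <- FALSE
    uncovered[unlist(meta_pep[selected], use.names = FALSE)] <- FALSE
  }
  while (any(uncovered)) {
    gain <- as.numeric(Matrix::crossprod(inc, uncovered))
    gain[!selectable] <- -1
    best <- max(gain)
    cand <- which(gain == best)
    # ties: larger total peptide set, then lexicographic accession;
    # cand is already in representative order, so take the first
    cand <- cand[meta_size[cand] == max(meta_size[cand])]
    pick <- cand[1L]
    selected <- c(selected, pick)
    selectable[pick] <- FALSE
    uncovered[meta_pep[[pick]]] <- FALSE
  }

  # (iii) subsume unselected metas into a selected group whose peptide set
  # contains theirs (preferring the larger group, then lexicographic rep)
  group_members <- meta_members[selected]
  sel_order <- order_c(-meta_size[selected], meta_rep[selected])
  for (m in which(selectable)) {
    pep_m <- meta_pep[[m]]
    for (g in sel_order) {
      if (all(pep_m %in% meta_pep[[selected[g]]])) {
        group_members[[g]] <- sort_c(c(group_members[[g]], meta_members[[m]]))
        break
      }
    }
  }

  group_pep <- lapply(meta_pep[selected], function(p) peptides[p])
  # unique peptides: in exactly one group's peptide set
  pep_group_count <- tabulate(unlist(meta_pep[selected], use.names = FALSE),
                              nbins = length(peptides))
  uniq <- lapply(meta_pep[selected],
                 function(p) peptides[p[pep_group_count[p] == 1L]])
  out <- data.frame(group_id = seq_along(selected),
                    representative = meta_rep[selected],
                    stringsAsFactors = FALSE)
  out$members <- group_members
  out$peptides <- group_pep
  out$unique_peptides <- uniq
  out$n_unique <- lengths(uniq)
  class(out) <- c("protein_groups", "data.frame")
  out
}

#' Apply the two-unique-peptide rule
#'
#' Retains only groups supported by at least `min_unique` distinct peptide
#' sequences that map to no other group. The rule is applied once, on
#' evidence pooled across all runs, before any enrichment ranking.
#'
#' @param groups a `protein_groups` object.
#' @param min_unique minimum number of unique peptides (default 2).
#' @return The surviving groups, order preserved.
#' @export
apply_two_peptide_rule <- function(groups, min_unique = 2L) {
  stopifnot(is_count(min_unique), min_unique >= 1)
  out <- groups[groups$n_unique >= min_unique, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(groups)
  out
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d group(s), %d protein(s), %d peptide(s)\n",
              nrow(x), length(unique(unlist(x$members))),
              length(unique(unlist(x$peptides)))))
  invisible(x)
}
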