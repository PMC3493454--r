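# Two-stage spectral-count enrichment cascade:
#   stage 1: bait vs tag-only control, fold >= fold1 (default 10), detected
#            in >= min_runs bait runs;
#   stage 2: bait vs comparator nucleosome, fold >= fold2 (default 2),
#            restricted to stage-1 survivors.
# Fold values are ratios of spectral-count sums over all replicates of a
# condition ("amalgamated" counts). A zero control/comparator sum with a
# positive bait sum yields +Inf (passes any threshold: absence from the
# background is the strongest possible enrichment evidence); a 0/0 ratio is
# undefined (NaN) and fails every threshold.

condition_sums <- function(m) {
  roles <- c("BAIT", "COMPARATOR", "CONTROL")
  n <- nrow(m$counts)
  out <- vapply(roles, function(role) {
    runs <- design_runs(m$design, role)
    if (!length(runs)) return(rep(NA_real_, n))
    rowSums(m$counts[, runs, drop = FALSE])
  }, numeric(n))
  matrix(out, nrow = n, ncol = length(roles),
         dimnames = list(rownames(m$counts), roles))
}

check_condition <- function(m, cond) {
  if (!cond %in% c("BAIT", "COMPARATOR", "CONTROL")) {
    abort_nucenrich(sprintf("unknown condition role '%s'", cond),
                    "nucenrich_validation_error")
  }
  if (!length(design_runs(m$design, cond))) {
    abort_nucenrich(sprintf("design has no '%s' runs", cond),
                    "nucenrich_validation_error")
  }
  invisible(TRUE)
}

#' Fold enrichment between two conditions
#'
#' Ratio of spectral-count sums, pooled over all replicate runs of each
#' condition. Returns `Inf` when the denominator sum is zero and the
#' numerator positive, and `NaN` (undefined; fails any threshold) when both
#' sums are zero.
#'
#' @param m a `spectral_counts` object.
#' @param group_id group id(s); default all groups.
#' @param cond_a,cond_b condition roles (`"BAIT"`, `"COMPARATOR"`,
#'   `"CONTROL"`).
#' @return Named numeric vector of fold values.
#' @export
fold_enrichment <- function(m, group_id = m$groups$group_id,
                            cond_a = "BAIT", cond_b = "CONTROL") {
  check_condition(m, cond_a)
  check_condition(m, cond_b)
  key <- as.character(group_id)
  a <- rowSums(m$counts[key, design_runs(m$design, cond_a), drop = FALSE])
  b <- rowSums(m$counts[key, design_runs(m$design, cond_b), drop = FALSE])
  setNames(a / b, key)
}

#' One stage of the enrichment filter
#'
#' A group survives when its fold enrichment of `cond_a` over `cond_b`
#' reaches `fold_min` (`Inf` passes any threshold; an undefined 0/0 fold
#' fails) *and* it is detected (>= 1 assigned spectrum) in at least
#' `min_runs` of `cond_a`'s replicate runs.
#'
#' @inheritParams fold_enrichment
#' @param fold_min positive fold threshold.
#' @param min_runs minimum number of `cond_a` runs with detection.
#' @return Integer vector of surviving group ids, in group-id order.
#' @export
stage_filter <- function(m, cond_a, cond_b, fold_min, min_runs) {
  stopifnot(is.numeric(fold_min), fold_min > 0, is_count(min_runs),
            min_runs >= 1)
  check_condition(m, cond_a)
  n_rep <- length(design_runs(m$design, cond_a))
  if (min_runs > n_rep) {
    abort_nucenrich(
      sprintf("min_runs (%d) exceeds the %d replicate(s) of %s",
              as.integer(min_runs), n_rep, cond_a),
      "nucenrich_validation_error")
  }
  fold <- fold_enrichment(m, cond_a = cond_a, cond_b = cond_b)
  det <- rowSums(detection_matrix(m)[, design_runs(m$design, cond_a),
                                     drop = FALSE])
  keep <- !is.nan(fold) & fold >= fold_min & det >= min_runs
  m$groups$group_id[keep]
}

#' Run the two-stage enrichment cascade
#'
#' Stage 1 filters all groups on bait-vs-control enrichment; stage 2
#' re-filters the stage-1 survivors on bait-vs-comparator enrichment. The
#' defaults (`fold1 = 10`, `fold2 = 2`, `min_runs = 2`) are the thresholds
#' of the reference ranking strategy.
#'
#' @param m a `spectral_counts` object whose design contains BAIT,
#'   COMPARATOR and CONTROL runs.
#' @param fold1 stage-1 (bait vs control) fold threshold.
#' @param fold2 stage-2 (bait vs comparator) fold threshold.
#' @param min_runs minimum bait runs with detection, per stage.
#' @return An object of class `cascade_result`: list with
#'   `stage1_survivors`, `stage2_survivors` (integer group ids),
#'   `fold_values` (groups x 2 matrix: `fold_vs_control`,
#'   `fold_vs_comparator`), `condition_sums`, `funnel`
#'   (`n_input`, `n_stage1`, `n_stage2`), `overlap_counts` (Venn region
#'   counts of per-condition detected sets), `groups`, `matrix`, `params`.
#' @export
run_cascade <- function(m, fold1 = 10, fold2 = 2, min_runs = 2L) {
  for (cond in c("BAIT", "COMPARATOR", "CONTROL")) check_condition(m, cond)
  stage1 <- stage_filter(m, "BAIT", "CONTROL", fold1, min_runs)
  stage2 <- intersect(stage_filter(m, "BAIT", "COMPARATOR", fold2, min_runs),
                      stage1)
  folds <- cbind(
    fold_vs_control = fold_enrichment(m, cond_b = "CONTROL"),
    fold_vs_comparator = fold_enrichment(m, cond_b = "COMPARATOR"))
  det <- detection_matrix(m)
  detected <- lapply(c(BAIT = "BAIT", COMPARATOR = "COMPARATOR",
                       CONTROL = "CONTROL"), function(role) {
    m$groups$group_id[rowSums(det[, design_runs(m$design, role),
                                  drop = FALSE]) >= 1L]
  })
  structure(list(
    stage1_survivors = stage1,
    stage2_survivors = stage2,
    fold_values = folds,
    condition_sums = condition_sums(m),
    funnel = c(n_input = nrow(m$counts), n_stage1 = length(stage1),
               n_stage2 = length(stage2)),
    overlap_counts = overlap_sets(detected),
    detected_sets = detected,
    groups = m$groups,
    matrix = m,
    params = list(fold1 = fold1, fold2 = fold2,
                  min_runs = as.integer(min_runs))),
    class = "cascade_result")
}

#' Venn region counts of per-condition detected sets
#'
#' Partitions the union of three detected-group sets into the seven regions
#' of a three-set Venn diagram (unique to each condition, each pairwise
#' overlap excluding the third, and the triple intersection) and counts
#' each region. Region counts always sum to the size of the union.
#'
#' @param detected named list of three vectors of group ids, with names
#'   `BAIT`, `COMPARATOR`, `CONTROL`.
#' @return Named integer vector over regions `BAIT_only`,
#'   `COMPARATOR_only`, `CONTROL_only`, `BAIT_COMPARATOR`, `BAIT_CONTROL`,
#'   `COMPARATOR_CONTROL`, `ALL_THREE`.
#' @export
overlap_sets <- function(detected) {
  stopifnot(all(c("BAIT", "COMPARATOR", "CONTROL") %in% names(detected)))
  u <- unique(unlist(detected, use.names = FALSE))
  inb <- u %in% detected$BAIT
  inc <- u %in% detected$COMPARATOR
  ing <- u %in% detected$CONTROL
  c(BAIT_only = sum(inb & !inc & !ing),
    COMPARATOR_only = sum(!inb & inc & !ing),
    CONTROL_only = sum(!inb & !inc & ing),
    BAIT_COMPARATOR = sum(inb & inc & !ing),
    BAIT_CONTROL = sum(inb & !inc & ing),
    COMPARATOR_CONTROL = sum(!inb & inc & ing),
    ALL_THREE = sum(inb & inc & ing))
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "cascade_result: funnel %d -> %d (fold >= %g vs control) -> %d (fold >= %g vs comparator), min %d bait run(s)\n",
    x$funnel["n_input"], x$funnel["n_stage1"], x$params$fold1,
    x$funnel["n_stage2"], x$params$fold2, x$params$min_runs))
  invisible(x)
}
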