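# Target/decoy FDR estimation and threshold selection.
#
# The decoy database is assumed to be the same size as the target database
# (reversed sequences), so the number of decoy hits above a score cut
# estimates the number of false target hits above the same cut.

# Signed score: after this transform "accept" always means score' <= t.
signed_scores <- function(score, lower_is_better) {
  if (lower_is_better) score else -score
}

#' Estimate the false-discovery proportion at a score threshold
#'
#' Counts target and decoy PSMs accepted at `score_threshold` (inclusive)
#' and returns the decoy-based FDR estimate. The default `"ratio"`
#' estimator is `D / max(T, 1)`, appropriate for an equal-size decoy
#' database; `"combined"` is the `2D / (T + D)` variant that treats the
#' decoy hits as part of the accepted population.
#'
#' @param psms a [psm_table()].
#' @param score_threshold finite score cut; PSMs scoring at or better than
#'   it are accepted.
#' @param lower_is_better logical; `TRUE` (default) for expectation-value
#'   style scores.
#' @param method `"ratio"` (default) or `"combined"`.
#' @return Estimated FDR in `[0, 1]`; 0 when nothing is accepted.
#' @export
estimate_fdr <- function(psms, score_threshold, lower_is_better = TRUE,
                         method = c("ratio", "combined")) {
  method <- match.arg(method)
  stopifnot(is.finite(score_threshold))
  s <- signed_scores(psms$score, lower_is_better)
  acc <- s <= signed_scores(score_threshold, lower_is_better)
  n_target <- sum(acc & !psms$is_decoy)
  n_decoy <- sum(acc & psms$is_decoy)
  fdr_estimate(n_target, n_decoy, method)
}

fdr_estimate <- function(n_target, n_decoy, method) {
  if (n_target + n_decoy == 0) return(0)
  est <- switch(method,
                ratio = n_decoy / max(n_target, 1),
                combined = 2 * n_decoy / (n_target + n_decoy))
  min(est, 1)
}

#' Select the score threshold attaining a nominal FDR
#'
#' Scans every observed score as a candidate cut (inclusive: ties at the
#' threshold are accepted) and returns the most permissive cut whose
#' decoy-estimated FDR is at or below `nominal_fdr` and which accepts at
#' least one target PSM. This cut operationalises the "high quality" PSM
#' notion used by the downstream two-unique-peptide rule.
#'
#' @inheritParams estimate_fdr
#' @param nominal_fdr target FDR in `(0, 1]`, e.g. `0.005` for the 0.5%
#'   level used by default in the pipeline.
#' @return An object of class `fdr_selection`: a list with
#'   `score_threshold`, `n_target_accepted`, `n_decoy_accepted`,
#'   `estimated_fdr`, `nominal_fdr`, `lower_is_better`, `method`.
#' @export
select_threshold <- function(psms, nominal_fdr, lower_is_better = TRUE,
                             method = c("ratio", "combined")) {
  method <- match.arg(method)
  stopifnot(is.numeric(nominal_fdr), length(nominal_fdr) == 1L,
            nominal_fdr > 0, nominal_fdr <= 1)
  if (nrow(psms) == 0L) {
    abort_nucenrich("no PSMs: cannot select a score threshold",
                    "nucenrich_no_threshold_error")
  }
  s <- signed_scores(psms$score, lower_is_better)
  ord <- order(s)
  s_sorted <- s[ord]
  decoy_sorted <- psms$is_decoy[ord]
  # evaluate at the last index of each distinct score (inclusive cut)
  cut_idx <- which(!duplicated(s_sorted, fromLast = TRUE))
  cum_target <- cumsum(!decoy_sorted)[cut_idx]
  cum_decoy <- cumsum(decoy_sorted)[cut_idx]
  est <- vapply(seq_along(cut_idx), function(i)
    fdr_estimate(cum_target[i], cum_decoy[i], method), 0)
  ok <- est <= nominal_fdr & cum_target >= 1L
  if (!any(ok)) {
    abort_nucenrich(
      sprintf("no score threshold attains nominal FDR %g", nominal_fdr),
      "nucenrich_no_threshold_error")
  }
  i <- max(which(ok))  # most permissive passing cut
  thr_signed <- s_sorted[cut_idx[i]]
  structure(list(
    score_threshold = if (lower_is_better) thr_signed else -thr_signed,
    n_target_accepted = cum_target[i],
    n_decoy_accepted = cum_decoy[i],
    estimated_fdr = est[i],
    nominal_fdr = nominal_fdr,
    lower_is_better = lower_is_better,
    method = method), class = "fdr_selection")
}

#' @export
print.fdr_selection <- function(x, ...) {
  cat(sprintf(
    "fdr_selection: threshold %g (%s), %d targets / %d decoys accepted, estimated FDR %.4g (nominal %g)\n",
    x$score_threshold, if (x$lower_is_better) "score <=" else "score >=",
    x$n_target_accepted, x$n_decoy_accepted, x$estimated_fdr, x$nominal_fdr))
  invisible(x)
}

#' Keep the confident target PSMs
#'
#' Returns the target PSMs passing the selected threshold; decoy PSMs are
#' excluded from all downstream stages regardless of score.
#'
#' @param psms a [psm_table()].
#' @param selection an `fdr_selection` from [select_threshold()], produced
#'   under the same score convention.
#' @return The filtered [psm_table()].
#' @export
confident_psms <- function(psms, selection) {
  stopifnot(inherits(selection, "fdr_selection"))
  s <- signed_scores(psms$score, selection$lower_is_better)
  thr <- signed_scores(selection$score_threshold, selection$lower_is_better)
  keep <- !psms$is_decoy & s <= thr
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(psms)
  out
}
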