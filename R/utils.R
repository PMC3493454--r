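# Internal helpers shared across modules.

# C-locale character sort: ordering must not depend on the host locale,
# otherwise grouping and output files are not byte-reproducible.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

#' @keywords internal
abort_nucenrich <- function(msg, class) {
  stop(structure(
    class = c(class, "nucenrich_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == as.integer(x)

# Deterministic number formatting for result tables (fold values may be Inf).
format_fold <- function(x) {
  ifelse(is.nan(x), "NA",
         ifelse(is.infinite(x), "Inf", formatC(x, format = "g", digits = 8)))
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
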