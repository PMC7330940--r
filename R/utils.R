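# Shared helpers: condition constructors, rounding, interval utilities.

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "homoeosplice_config_error", field = field)
}

stop_input <- function(msg, class = "homoeosplice_input_error") {
  abort(msg, class = class)
}

stop_dependency <- function(stage, missing) {
  abort(
    sprintf("stage '%s' requires missing upstream output: %s", stage, missing),
    class = "homoeosplice_dependency_error", stage = stage
  )
}

#' Round half-even to two decimals
#'
#' All printed percentages in the summary tables use banker's rounding
#' (R's own `round()`), which reproduces the conventional 2-decimal
#' renderings of the worked examples.
#'
#' @param x numeric vector.
#' @return numeric vector rounded to 2 decimals.
#' @keywords internal
round2 <- function(x) round(x, 2)

# Percentage of `count` within `total`, half-even rounded to 2 decimals.
# total == 0 yields 0 (callers flag degenerate columns themselves).
pct2 <- function(count, total) {
  ifelse(total == 0, 0, round2(100 * count / total))
}

# Format a percentage with exactly two decimals ("18.96").
fmt_pct <- function(x) sprintf("%.2f", x)

# ---- interval helpers (0-based, half-open) --------------------------------

# exon matrix: integer matrix with columns start, end; rows sorted.
as_exon_matrix <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1L]), , drop = FALSE]
}

validate_chain <- function(m, label = "chain") {
  if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 1L) {
    stop_input(sprintf("%s: malformed exon chain (need >=1 start/end row)", label),
               class = "homoeosplice_validation_error")
  }
  if (any(m[, 2L] <= m[, 1L])) {
    stop_input(sprintf("%s: empty or reversed exon interval", label),
               class = "homoeosplice_validation_error")
  }
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L])) {
    stop_input(sprintf("%s: exons unsorted or overlapping", label),
               class = "homoeosplice_validation_error")
  }
  invisible(m)
}

# introns of a chain: (end_i, start_{i+1}) pairs; 0-row matrix for 1 exon.
chain_introns <- function(m) {
  n <- nrow(m)
  if (n < 2L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = m[-n, 2L], end = m[-1L, 1L])
}

interval_key <- function(m) paste(m[, 1L], m[, 2L], sep = "-")

DNA_BASES <- c("A", "C", "G", "T")

# deterministic substitute base (never equal to `base`)
other_base <- function(base, shift) {
  idx <- match(base, DNA_BASES)
  DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
}

# Draw seeded integers for sub-streams without touching the global stream
# ordering guarantees: derive child seeds from a base seed.
child_seed <- function(seed, k) {
  (as.integer(seed) + 1009L * as.integer(k)) %% 2147483641L
}
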