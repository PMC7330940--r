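# Publication-shaped summary tables: AS-event composition per homoeolog
# column, full-length read summary, homoeolog AS shares.

#' AS-event summary table
#'
#' Builds the event-type composition of one or more homoeolog-by-hybrid
#' columns: per type the event count, its percentage of the column total
#' (half-even rounded to two decimals) and, when available, the gene
#' count; plus a `Total` row per column. Every emission self-audits:
#' totals are recomputed from the type rows.
#'
#' @param counts tibble with `column` (label, e.g. `"TC-TBF3"`), `type`
#'   (from `r paste(AS_TYPES_ALL, collapse = ", ")`), `n_events` and
#'   optionally `n_genes`.
#' @return tibble of class `as_summary`: `column`, `type`, `n_events`,
#'   `pct`, `n_genes`, with `Total` rows appended; all-zero columns are
#'   flagged in attribute `degenerate_columns`.
#' @examples
#' tc_tbf3 <- tibble::tibble(
#'   column = "TC-TBF3",
#'   type = c("A3SS", "A5SS", "AP", "SE", "RI", "OTHER"),
#'   n_events = c(1430, 1603, 2520, 3869, 4091, 8064)
#' )
#' as_summary_table(tc_tbf3) # Total 21577, RI 18.96%
#' @export
as_summary_table <- function(counts) {
  stopifnot(all(c("column", "type", "n_events") %in% names(counts)))
  if (any(counts$n_events < 0)) {
    stop_input("as_summary_table: negative event count")
  }
  if (!"n_genes" %in% names(counts)) counts$n_genes <- NA_integer_
  body <- counts |>
    group_by(.data$column) |>
    mutate(.col_total = sum(.data$n_events)) |>
    ungroup() |>
    mutate(pct = pct2(.data$n_events, .data$.col_total))
  totals <- body |>
    group_by(.data$column) |>
    summarise(
      type = "Total",
      n_events = sum(.data$n_events),
      pct = ifelse(.data$.col_total[[1L]] == 0, 0, 100),
      n_genes = if (all(is.na(.data$n_genes))) NA_integer_ else
        sum(.data$n_genes, na.rm = TRUE),
      .groups = "drop"
    )
  degenerate <- totals$column[totals$n_events == 0]
  out <- bind_rows(body |> select(-".col_total"), totals) |>
    arrange(.data$column,
            match(.data$type, c(AS_TYPES_ALL, "Total")))
  # self-audit: the rendered totals must equal recomputed sums
  audit <- out |>
    group_by(.data$column) |>
    summarise(ok = sum(.data$n_events[.data$type != "Total"]) ==
                .data$n_events[.data$type == "Total"][[1L]],
              .groups = "drop")
  stopifnot(all(audit$ok))
  structure(out, class = c("as_summary", class(out)),
            degenerate_columns = degenerate)
}

#' Summarise classified AS events into table columns
#'
#' Convenience bridge from [classify_as_events()] output to
#' [as_summary_table()] input: counts deduplicated events and distinct
#' genes per type within each `homoeolog` (and any `hybrid` column).
#'
#' @param events classified event table with `gene_id`, `type` and
#'   grouping columns `homoeolog` and/or `hybrid`.
#' @return counts tibble suitable for [as_summary_table()].
#' @export
count_as_events <- function(events) {
  grp <- intersect(c("homoeolog", "hybrid"), names(events))
  if (length(grp) == 0) {
    stop_input("count_as_events: need a 'homoeolog' and/or 'hybrid' column")
  }
  events |>
    group_by(across(all_of(c(grp, "type")))) |>
    summarise(n_events = dplyr::n(),
              n_genes = dplyr::n_distinct(.data$gene_id),
              .groups = "drop") |>
    tidyr::unite("column", all_of(grp), sep = "-") |>
    arrange(.data$column, match(.data$type, AS_TYPES_ALL))
}

#' Render an AS summary as aligned text
#'
#' @param x an `as_summary` table.
#' @return character vector of aligned lines (one header + one per row).
#' @export
render_as_summary <- function(x) {
  d <- x |>
    mutate(cell = ifelse(.data$type == "Total",
                         format(.data$n_events, big.mark = ","),
                         sprintf("%s (%s%%)",
                                 format(.data$n_events, big.mark = ","),
                                 fmt_pct(.data$pct)))) |>
    select("column", "type", "cell") |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell")
  lines <- utils::capture.output(print(as.data.frame(d), row.names = FALSE))
  lines
}

#' Full-length read summary table
#'
#' Per sample: consensus-read count and the five-prime, three-prime and
#' full-length counts with their percentage of consensus reads
#' (half-even, two decimals).
#'
#' @param counts tibble with `sample`, `consensus_reads`,
#'   `five_prime_reads`, `three_prime_reads`, `full_length_reads`.
#' @return tibble with `*_pct` columns added.
#' @examples
#' fl_summary_table(tibble::tibble(
#'   sample = "TBF3", consensus_reads = 663834,
#'   five_prime_reads = 622119, three_prime_reads = 628065,
#'   full_length_reads = 586075
#' )) # full_length_pct 88.29
#' @export
fl_summary_table <- function(counts) {
  need <- c("sample", "consensus_reads", "five_prime_reads",
            "three_prime_reads", "full_length_reads")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop_input(paste("fl_summary_table: missing columns:",
                     paste(miss, collapse = ", ")))
  }
  if (any(unlist(counts[need[-1]]) < 0)) {
    stop_input("fl_summary_table: negative counts")
  }
  counts |>
    mutate(
      five_prime_pct = pct2(.data$five_prime_reads, .data$consensus_reads),
      three_prime_pct = pct2(.data$three_prime_reads, .data$consensus_reads),
      full_length_pct = pct2(.data$full_length_reads, .data$consensus_reads)
    )
}

#' Summarise classified long reads
#'
#' @param reads output of [classify_full_length()].
#' @param sample sample label.
#' @return one-row input for [fl_summary_table()], already summarised.
#' @export
fl_summary_from_reads <- function(reads, sample = "sample") {
  fl_summary_table(tibble(
    sample = sample,
    consensus_reads = nrow(reads),
    five_prime_reads = sum(reads$has_5prime_primer),
    three_prime_reads = sum(reads$has_3prime_primer),
    full_length_reads = sum(reads$full_length)
  ))
}

#' Homoeolog shares of AS events
#'
#' Splits a tissue's AS events between the TC and BSB homoeologs as
#' percentages of their sum (half-even, two decimals).
#'
#' @param tc_events,bsb_events non-negative event counts (not both 0).
#' @return one-row tibble: `tc_pct`, `bsb_pct`.
#' @examples
#' homoeolog_as_share(3103, 315) # 90.78 / 9.22
#' @export
homoeolog_as_share <- function(tc_events, bsb_events) {
  if (tc_events < 0 || bsb_events < 0) {
    stop_input("homoeolog_as_share: negative counts")
  }
  tot <- tc_events + bsb_events
  if (tot == 0) {
    stop_input("homoeolog_as_share: both counts are zero")
  }
  tibble(tc_pct = pct2(tc_events, tot), bsb_pct = pct2(bsb_events, tot))
}
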