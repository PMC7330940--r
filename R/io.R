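# Plain-text emissions: seed-stamped TSV, GTF and BED exports.

#' Write a seed-stamped TSV
#'
#' Writes a `# homoeosplice seed=<seed> config=<hash>` comment line
#' followed by the tibble as TSV. List columns are flattened to
#' comma-separated strings.
#'
#' @param x tibble.
#' @param path output path.
#' @param seed integer seed to stamp.
#' @param config_hash short configuration hash to stamp.
#' @return `path`, invisibly.
#' @export
write_tsv_stamped <- function(x, path, seed = NA, config_hash = "") {
  x <- x |> mutate(across(where(is.list),
                          ~ purrr::map_chr(.x, paste, collapse = ",")))
  header <- sprintf("# homoeosplice seed=%s config=%s", seed, config_hash)
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a seed-stamped TSV
#'
#' @param path path written by [write_tsv_stamped()].
#' @return tibble (comment lines skipped).
#' @export
read_tsv_stamped <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Export gene models as GTF
#'
#' Internal coordinates are 0-based half-open; GTF is 1-based inclusive,
#' so exported starts are `start + 1` and ends are unchanged.
#'
#' @param exons tibble with `gene_id`, `exon`, `start`, `end`.
#' @param genes tibble with `gene_id`, `strand` (and optionally
#'   `subgenome`, used as the seqname).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, genes, path) {
  meta <- genes |> select("gene_id", "strand",
                          any_of("subgenome"))
  if (!"subgenome" %in% names(meta)) meta$subgenome <- "chr1"
  d <- exons |> inner_join(meta, by = "gene_id")
  lines <- sprintf(
    "%s\thomoeosplice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; exon_number \"%d\";",
    d$subgenome, d$start + 1L, d$end, d$strand, d$gene_id, d$exon
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export AS-event anchors as BED
#'
#' BED is 0-based half-open, matching the internal convention. The
#' anchor's extremal coordinates define the interval; the name column
#' carries `gene|type|anchor`.
#'
#' @param events classified event table with a `coords` list-column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_bed <- function(events, path) {
  if (nrow(events) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lo <- purrr::map_int(events$coords, ~ min(.x))
  hi <- purrr::map_int(events$coords, ~ max(.x))
  lines <- sprintf("%s\t%d\t%d\t%s",
                   events$gene_id, lo, pmax(hi, lo + 1L),
                   paste(events$gene_id, events$type, events$anchor,
                         sep = "|"))
  writeLines(lines, path)
  invisible(path)
}
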