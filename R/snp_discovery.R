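# Species-specific SNP discovery from parental pileups over a pairwise
# coordinate map.

#' Build a pairwise coordinate map
#'
#' Turns a pairwise alignment of one ortholog pair into a coordinate
#' map of aligned columns. Indel columns (a gap on either side) are kept
#' but flagged, and are excluded from SNP calling downstream; the map is
#' invertible on the retained columns.
#'
#' @param alignment either a data frame with `bsb_pos` and `tc_pos`
#'   columns (`NA` marks a gap on that side), or a character vector of
#'   two equal-length aligned sequences (BSB first) using `-` for gaps.
#' @param pair_id pair label stored in the map.
#' @return tibble with `pair_id`, `bsb_pos`, `tc_pos`, `indel`.
#' @examples
#' build_coordinate_map(c("ACGT-A", "AC-TGA"), pair_id = "p1")
#' @export
build_coordinate_map <- function(alignment, pair_id = "pair") {
  if (is.character(alignment)) {
    if (length(alignment) != 2L || nchar(alignment[1]) != nchar(alignment[2]) ||
        nchar(alignment[1]) == 0L) {
      stop_input("build_coordinate_map: need two equal-length aligned sequences",
                 class = "homoeosplice_mapping_error")
    }
    a <- strsplit(alignment[[1L]], "")[[1L]]
    b <- strsplit(alignment[[2L]], "")[[1L]]
    alignment <- tibble(
      bsb_pos = ifelse(a == "-", NA_integer_, cumsum(a != "-") - 1L),
      tc_pos = ifelse(b == "-", NA_integer_, cumsum(b != "-") - 1L)
    )
  }
  if (!is.data.frame(alignment) ||
      !all(c("bsb_pos", "tc_pos") %in% names(alignment)) ||
      nrow(alignment) == 0L) {
    stop_input("build_coordinate_map: empty or malformed alignment",
               class = "homoeosplice_mapping_error")
  }
  out <- as_tibble(alignment) |>
    mutate(pair_id = pair_id,
           indel = is.na(.data$bsb_pos) | is.na(.data$tc_pos)) |>
    select("pair_id", "bsb_pos", "tc_pos", "indel")
  kept <- out |> filter(!.data$indel)
  if (nrow(kept) > 1L &&
      (any(diff(kept$bsb_pos) <= 0L) || any(diff(kept$tc_pos) <= 0L))) {
    stop_input("build_coordinate_map: positions not strictly increasing",
               class = "homoeosplice_mapping_error")
  }
  out
}

#' Call species-specific SNPs from parental pileups
#'
#' An aligned column is emitted as a species-specific SNP iff (a) the
#' observed allele sets of the two parents are disjoint (a "complete
#' difference", covering homozygous and heterozygous parental loci),
#' (b) each parent's allele set is consistent across its biological
#' replicates, (c) read coverage is at least 1 in every replicate of
#' both parents, and (d) the column is not an indel column of the map.
#' Bases enter a replicate's allele set when their count is at least 1
#' and their fraction of the column's coverage is at least
#' `min_minor_frac` (suppresses sequencing error).
#'
#' @param coord_maps coordinate map table from [build_coordinate_map()]
#'   (or the cohort's `coord_maps`), keyed by `pair_id`, `bsb_pos`.
#' @param pileups parental pileup table: `pair_id`, `bsb_pos`, `parent`
#'   (`"BSB"`/`"TC"`), `replicate`, and base counts `A`, `C`, `G`, `T`.
#' @param n_replicates expected replicates per parent (input-shape
#'   check).
#' @param min_minor_frac minimum within-replicate allele fraction for a
#'   base to enter the allele set.
#' @param consistency `"strict"` requires identical allele sets across
#'   replicates; `"majority"` takes bases supported in a majority of
#'   replicates (coverage and disjointness still required everywhere).
#' @return tibble of SNPs: `pair_id`, `bsb_pos`, `tc_pos`,
#'   `bsb_alleles`, `tc_alleles` (sorted `"A/T"`-style strings) and
#'   `min_coverage`.
#' @export
call_species_snps <- function(coord_maps, pileups, n_replicates = 3L,
                              min_minor_frac = 0.2,
                              consistency = c("strict", "majority")) {
  consistency <- match.arg(consistency)
  need <- c("pair_id", "bsb_pos", "parent", "replicate", "A", "C", "G", "T")
  miss <- setdiff(need, names(pileups))
  if (length(miss) > 0) {
    stop_input(paste("call_species_snps: pileups missing columns:",
                     paste(miss, collapse = ", ")))
  }
  n_rep_seen <- pileups |>
    distinct(.data$parent, .data$replicate) |>
    count(.data$parent)
  if (nrow(n_rep_seen) > 0 && any(n_rep_seen$n != n_replicates)) {
    stop_input(sprintf(
      "call_species_snps: expected %d replicates per parent", n_replicates),
      class = "homoeosplice_shape_error")
  }

  long <- pileups |>
    tidyr::pivot_longer(all_of(DNA_BASES), names_to = "base",
                        values_to = "count") |>
    group_by(.data$pair_id, .data$bsb_pos, .data$parent, .data$replicate) |>
    mutate(coverage = sum(.data$count)) |>
    ungroup()

  per_rep <- long |>
    filter(.data$count >= 1,
           .data$count / .data$coverage >= min_minor_frac) |>
    group_by(.data$pair_id, .data$bsb_pos, .data$parent, .data$replicate,
             .data$coverage) |>
    summarise(alleles = paste(sort(unique(.data$base)), collapse = "/"),
              .groups = "drop")

  # columns must have coverage >= 1 in all replicates of both parents
  full_cols <- per_rep |>
    group_by(.data$pair_id, .data$bsb_pos) |>
    filter(dplyr::n() == 2L * n_replicates, all(.data$coverage >= 1)) |>
    ungroup()

  per_parent <- if (consistency == "strict") {
    full_cols |>
      group_by(.data$pair_id, .data$bsb_pos, .data$parent) |>
      summarise(
        consistent = dplyr::n_distinct(.data$alleles) == 1L,
        min_coverage = min(c(.data$coverage, Inf)),
        alleles = dplyr::first(.data$alleles),
        .groups = "drop"
      )
  } else {
    full_cols |>
      tidyr::separate_rows("alleles", sep = "/") |>
      group_by(.data$pair_id, .data$bsb_pos, .data$parent, .data$alleles) |>
      mutate(n_support = dplyr::n()) |>
      group_by(.data$pair_id, .data$bsb_pos, .data$parent) |>
      summarise(
        min_coverage = min(c(.data$coverage, Inf)),
        alleles = paste(sort(unique(
          .data$alleles[.data$n_support > n_replicates / 2])), collapse = "/"),
        consistent = !is.na(dplyr::first(alleles)) &
          nchar(dplyr::first(alleles)) > 0,
        .groups = "drop"
      )
  }

  empty_snps <- tibble(pair_id = character(), bsb_pos = integer(),
                       tc_pos = integer(), bsb_alleles = character(),
                       tc_alleles = character(), min_coverage = integer())
  wide <- per_parent |>
    filter(.data$consistent) |>
    tidyr::pivot_wider(id_cols = c("pair_id", "bsb_pos"),
                       names_from = "parent",
                       values_from = c("alleles", "min_coverage"))
  if (!all(c("alleles_BSB", "alleles_TC") %in% names(wide))) {
    return(empty_snps)
  }
  wide <- wide |>
    filter(!is.na(.data$alleles_BSB), !is.na(.data$alleles_TC))

  disjoint <- purrr::map2_lgl(
    strsplit(wide$alleles_BSB, "/"), strsplit(wide$alleles_TC, "/"),
    function(a, b) length(intersect(a, b)) == 0L
  )
  wide <- wide[disjoint, , drop = FALSE]

  map_ok <- coord_maps |>
    filter(!.data$indel) |>
    select("pair_id", "bsb_pos", "tc_pos")
  wide |>
    inner_join(map_ok, by = c("pair_id", "bsb_pos")) |>
    transmute(.data$pair_id, .data$bsb_pos, .data$tc_pos,
              bsb_alleles = .data$alleles_BSB, tc_alleles = .data$alleles_TC,
              min_coverage = pmin(.data$min_coverage_BSB,
                                  .data$min_coverage_TC)) |>
    arrange(.data$pair_id, .data$bsb_pos)
}
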