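# Partition hybrid short reads by subgenome at species-specific SNPs,
# filter abnormal SNP counts, and build normalized per-gene homoeolog
# count matrices.

#' Assign short reads to a subgenome by majority vote
#'
#' Each read is called for the parent matched by a strict majority of
#' its base calls at covered species-specific SNPs; reads covering no
#' SNP, ties, and majorities matching neither parental allele set are
#' ambiguous.
#'
#' @param read_calls per-read base calls: `read_id`, `pair_id`, `pos`
#'   (BSB coordinate), `base`.
#' @param snps SNP table from [call_species_snps()].
#' @param strict error (rather than skip) when a call's position is
#'   absent from the SNP table. The default skips such calls: discovery
#'   filters legitimately drop loci, and partitioning uses the loci that
#'   survived.
#' @param read_ids optional vector of all read ids so SNP-free reads
#'   appear as ambiguous rows.
#' @return tibble: `read_id`, `covered`, `matches_bsb`, `matches_tc`,
#'   `call` in `BSB`/`TC`/`ambiguous`. Attribute `n_unknown_positions`
#'   counts skipped calls.
#' @export
assign_short_reads <- function(read_calls, snps, strict = FALSE,
                               read_ids = NULL) {
  tallies <- tally_snp_matches(read_calls, snps, strict = strict)
  out <- tallies |>
    mutate(call = case_when(
      .data$matches_bsb > .data$matches_tc ~ "BSB",
      .data$matches_tc > .data$matches_bsb ~ "TC",
      TRUE ~ "ambiguous"
    )) |>
    select("read_id", "covered", "matches_bsb", "matches_tc", "call")
  if (!is.null(read_ids)) {
    absent <- setdiff(read_ids, out$read_id)
    if (length(absent) > 0) {
      out <- bind_rows(out, tibble(
        read_id = absent, covered = 0L, matches_bsb = 0L,
        matches_tc = 0L, call = "ambiguous"
      ))
    }
  }
  attr(out, "n_unknown_positions") <- attr(tallies, "n_unknown_positions")
  out
}

#' Per-SNP parent-allele read counts
#'
#' Counts, for every SNP and library (hybrid x tissue x replicate), the
#' reads supporting each parental allele. SNPs without at least one read
#' in every replicate of every library group of the contrast are
#' dropped.
#'
#' @param read_calls per-read base calls (`read_id`, `pair_id`, `pos`,
#'   `base`) of one tissue.
#' @param reads read table carrying `read_id`, `hybrid`, `replicate`
#'   (and optionally `tissue`).
#' @param snps SNP table.
#' @param n_replicates replicates per hybrid.
#' @param require_all_libraries drop SNPs lacking coverage in any of the
#'   `2 * n_replicates` libraries of the contrast (the
#'   "reads >= 1 in all accessions and replicates" rule).
#' @return tibble: `pair_id`, `bsb_pos`, `hybrid`, `tissue`,
#'   `replicate`, `n_bsb`, `n_tc`.
#' @export
snp_allele_counts <- function(read_calls, reads, snps, n_replicates = 3L,
                              require_all_libraries = TRUE) {
  if (!"tissue" %in% names(reads)) reads$tissue <- "all"
  snp_key <- snps |>
    transmute(.data$pair_id, pos = .data$bsb_pos,
              .data$bsb_alleles, .data$tc_alleles)
  counts <- read_calls |>
    inner_join(snp_key, by = c("pair_id", "pos")) |>
    inner_join(reads |> select("read_id", "hybrid", "tissue", "replicate"),
               by = "read_id") |>
    mutate(in_bsb = allele_set_has(.data$bsb_alleles, .data$base),
           in_tc = allele_set_has(.data$tc_alleles, .data$base)) |>
    group_by(.data$pair_id, bsb_pos = .data$pos, .data$hybrid, .data$tissue,
             .data$replicate) |>
    summarise(n_bsb = sum(.data$in_bsb), n_tc = sum(.data$in_tc),
              .groups = "drop")
  # complete to the full library grid so zero cells are visible
  libs <- reads |> distinct(.data$hybrid, .data$tissue, .data$replicate)
  grid <- counts |>
    distinct(.data$pair_id, .data$bsb_pos, .data$tissue) |>
    inner_join(libs, by = "tissue",
               relationship = "many-to-many")
  counts <- grid |>
    left_join(counts,
              by = c("pair_id", "bsb_pos", "hybrid", "tissue", "replicate")) |>
    mutate(n_bsb = tidyr::replace_na(.data$n_bsb, 0L),
           n_tc = tidyr::replace_na(.data$n_tc, 0L))
  if (require_all_libraries) {
    counts <- counts |>
      group_by(.data$pair_id, .data$bsb_pos, .data$tissue) |>
      filter(all(.data$n_bsb + .data$n_tc >= 1)) |>
      ungroup()
  }
  counts |>
    arrange(.data$pair_id, .data$bsb_pos, .data$tissue, .data$hybrid,
            .data$replicate)
}

#' Filter abnormal SNP read counts (mean +/- 2 SD)
#'
#' Discards SNP count cells falling outside mean plus or minus two
#' sample standard deviations. Two axes are available:
#'
#' * `"across_snps_within_gene"` (default): a SNP's count is compared
#'   with all SNP counts of the same gene in the same library. This is
#'   the operative reading: with only three biological replicates the
#'   literal across-replicate rule can never flag anything (see below),
#'   while abnormal single-SNP counts within a gene are exactly what the
#'   filter is meant to remove.
#' * `"across_replicates"`: the literal rule, comparing a SNP's three
#'   replicate values. With n = 3 the largest possible deviation is
#'   (n-1)/sqrt(n) = 2/sqrt(3) < 2 sample SDs, so this mode is provably
#'   vacuous; it is provided (and unit-tested) to document the fact.
#'
#' Groups with fewer than 2 values are retained with a warning.
#'
#' @param snp_counts table from [snp_allele_counts()].
#' @param mode filtering axis, see above.
#' @return the filtered table; attribute `n_dropped` records the number
#'   of removed cells.
#' @export
filter_outlier_snps <- function(snp_counts,
                                mode = c("across_snps_within_gene",
                                         "across_replicates")) {
  mode <- match.arg(mode)
  x <- snp_counts |> mutate(.total = .data$n_bsb + .data$n_tc)
  grp <- if (mode == "across_snps_within_gene") {
    c("pair_id", "hybrid", "tissue", "replicate")
  } else {
    c("pair_id", "bsb_pos", "hybrid", "tissue")
  }
  x <- x |>
    group_by(across(all_of(grp))) |>
    mutate(
      .n = dplyr::n(),
      .m = mean(.data$.total),
      .s = sd(.data$.total),
      .keep_cell = .data$.n < 2L | is.na(.data$.s) |
        abs(.data$.total - .data$.m) <= 2 * .data$.s
    ) |>
    ungroup()
  if (any(x$.n < 2L)) {
    warn("filter_outlier_snps: groups with < 2 values retained unfiltered")
  }
  n_dropped <- sum(!x$.keep_cell)
  out <- x |>
    filter(.data$.keep_cell) |>
    select(-dplyr::starts_with("."))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-gene homoeolog counts
#'
#' Sums parent-allele read counts over all species-specific SNPs of each
#' gene, per library. Genes whose SNPs were all filtered away appear
#' with zero counts and `all_filtered = TRUE` when a gene universe is
#' supplied.
#'
#' @param snp_counts (filtered) table from [snp_allele_counts()].
#' @param all_pairs optional vector of pair ids defining the gene
#'   universe.
#' @return tibble: `pair_id`, `hybrid`, `tissue`, `replicate`,
#'   `bsb_count`, `tc_count`, `all_filtered`.
#' @export
gene_homoeolog_counts <- function(snp_counts, all_pairs = NULL) {
  out <- snp_counts |>
    group_by(.data$pair_id, .data$hybrid, .data$tissue, .data$replicate) |>
    summarise(bsb_count = sum(.data$n_bsb), tc_count = sum(.data$n_tc),
              .groups = "drop") |>
    mutate(all_filtered = FALSE)
  if (!is.null(all_pairs)) {
    libs <- out |> distinct(.data$hybrid, .data$tissue, .data$replicate)
    grid <- tidyr::expand_grid(pair_id = all_pairs, libs)
    out <- grid |>
      left_join(out, by = c("pair_id", "hybrid", "tissue", "replicate")) |>
      mutate(
        all_filtered = is.na(.data$bsb_count),
        bsb_count = tidyr::replace_na(.data$bsb_count, 0L),
        tc_count = tidyr::replace_na(.data$tc_count, 0L)
      )
  }
  out |> arrange(.data$pair_id, .data$tissue, .data$hybrid, .data$replicate)
}

#' Library-size normalization and expression filtering
#'
#' Treats each subgenome partition of each hybrid library (hybrid x
#' tissue x replicate x subgenome) as its own mapping file, scales gene
#' counts to counts per million within it, and flags genes retained for
#' the differential-expression contrast: raw count at least `min_count`
#' in all replicates of both hybrids (per tissue and subgenome).
#'
#' @param gene_counts table from [gene_homoeolog_counts()].
#' @param min_count retention threshold (inclusive).
#' @return long tibble: `pair_id`, `hybrid`, `tissue`, `replicate`,
#'   `subgenome`, `count`, `cpm`, `retained`.
#' @export
normalize_and_filter <- function(gene_counts, min_count = 5) {
  long <- gene_counts |>
    tidyr::pivot_longer(c("bsb_count", "tc_count"),
                        names_to = "subgenome", values_to = "count") |>
    mutate(subgenome = ifelse(.data$subgenome == "bsb_count", "BSB", "TC"))
  totals <- long |>
    group_by(.data$hybrid, .data$tissue, .data$replicate, .data$subgenome) |>
    mutate(.lib_total = sum(.data$count)) |>
    ungroup()
  if (any(totals$.lib_total == 0)) {
    stop_input("normalize_and_filter: a library has zero total mapped reads",
               class = "homoeosplice_normalization_error")
  }
  out <- totals |>
    mutate(cpm = 1e6 * .data$count / .data$.lib_total) |>
    select(-".lib_total") |>
    group_by(.data$pair_id, .data$tissue, .data$subgenome) |>
    mutate(retained = all(.data$count >= min_count)) |>
    ungroup()
  out
}

#' Maternal-origin call from mitochondrial read counts
#'
#' Calls the mitogenome attracting at least `threshold` of a hybrid's
#' mitochondrial reads as the maternal one; anything less (or zero
#' reads) is undetermined.
#'
#' @param mito_counts tibble: `hybrid`, `bsb_mito_reads`,
#'   `tc_mito_reads`.
#' @param threshold minimum fraction of mitochondrial reads (inclusive).
#' @return tibble with `hybrid`, `maternal_call` (`"BSB"`, `"TC"` or
#'   `"undetermined"`) and `frac_top`.
#' @examples
#' mito_origin_check(tibble::tibble(hybrid = "h", bsb_mito_reads = 1000,
#'                                  tc_mito_reads = 2))
#' @export
mito_origin_check <- function(mito_counts, threshold = 0.95) {
  mito_counts |>
    mutate(
      .tot = .data$bsb_mito_reads + .data$tc_mito_reads,
      frac_top = ifelse(.data$.tot == 0, 0,
                        pmax(.data$bsb_mito_reads, .data$tc_mito_reads) /
                          .data$.tot),
      maternal_call = case_when(
        .data$.tot == 0 ~ "undetermined",
        .data$bsb_mito_reads / .data$.tot >= threshold ~ "BSB",
        .data$tc_mito_reads / .data$.tot >= threshold ~ "TC",
        TRUE ~ "undetermined"
      )
    ) |>
    select(-".tot")
}
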