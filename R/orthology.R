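# Ortholog pairing between the two parental gene sets and comparative
# gene-structure statistics.

#' Filter transcripts by CDS annotation and length
#'
#' Retains gene models with an annotated CDS (`cds_length > 0`) and a
#' total transcript length of at least 100 bp (the `< 100 bp` rule is
#' strict, so exactly 100 bp is kept).
#'
#' @param models tibble of gene models with `cds_length` and `tx_length`
#'   columns (total exonic length in bp).
#' @return the retained rows, unchanged.
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                     tx_length = c(99, 100, 500),
#'                     cds_length = c(90, 90, 0))
#' filter_transcripts(m)$gene_id # only "b"
#' @export
filter_transcripts <- function(models) {
  stopifnot(all(c("cds_length", "tx_length") %in% names(models)))
  models |>
    filter(.data$cds_length > 0, .data$tx_length >= 100)
}

#' Similarity scores from shared k-mer content
#'
#' A light-weight in-package scorer for synthetic sequences: the directed
#' score of query q against subject s is the fraction of q's distinct
#' k-mers found in s (k-mer containment). A pseudo-significance value
#' `evalue_like = 1 - score` accompanies each hit so the reciprocal-best-
#' hit selection can threshold it like an alignment e-value.
#'
#' @param query,subject tibbles with `gene_id` and `seq` columns.
#' @param k k-mer size.
#' @param min_score hits below this containment are not reported.
#' @return tibble of directed hits: `query`, `subject`, `score`,
#'   `evalue_like`.
#' @export
kmer_similarity_scores <- function(query, subject, k = 10L,
                                   min_score = 0.05) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  qk <- lapply(query$seq, kmers)
  sk <- lapply(subject$seq, kmers)
  rows <- list()
  for (i in seq_along(qk)) {
    for (j in seq_along(sk)) {
      sc <- mean(qk[[i]] %in% sk[[j]])
      if (is.nan(sc) || sc < min_score) next
      rows[[length(rows) + 1L]] <- tibble(
        query = query$gene_id[[i]], subject = subject$gene_id[[j]],
        score = sc, evalue_like = 1 - sc
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(query = character(), subject = character(),
                  score = double(), evalue_like = double()))
  }
  bind_rows(rows)
}

#' Reciprocal best hits
#'
#' Pairs gene `a` (query side) with gene `b` (subject side) when `b` is
#' `a`'s unique best-scoring hit, `a` is `b`'s unique best-scoring hit,
#' and both directed hits pass the significance threshold. A tie for
#' best hit excludes the gene (with a warning).
#'
#' @param hits directed hit table: `query`, `subject`, `score` and
#'   optionally `evalue_like`.
#' @param max_evalue keep hits with `evalue_like <= max_evalue` (ignored
#'   when the column is absent).
#' @return tibble of pairs sorted by gene id: `bsb_gene` (query side),
#'   `tc_gene` (subject side), `score`, `evalue_like`.
#' @export
reciprocal_best_hits <- function(hits, max_evalue = 1e-5) {
  stopifnot(all(c("query", "subject", "score") %in% names(hits)))
  if ("evalue_like" %in% names(hits)) {
    hits <- hits |> filter(.data$evalue_like <= max_evalue)
  }
  if (nrow(hits) == 0) {
    return(tibble(bsb_gene = character(), tc_gene = character(),
                  score = double(), evalue_like = double()))
  }
  unique_best <- function(tbl, by) {
    tbl |>
      group_by(across(all_of(by))) |>
      filter(.data$score == max(.data$score)) |>
      mutate(.tied = dplyr::n() > 1L) |>
      ungroup()
  }
  best_q <- unique_best(hits, "query")
  best_s <- unique_best(hits, "subject")
  tied <- unique(c(best_q$query[best_q$.tied], best_s$subject[best_s$.tied]))
  if (length(tied) > 0) {
    warn(sprintf("reciprocal_best_hits: %d gene(s) excluded for tied best hits",
                 length(tied)))
  }
  best_q <- best_q |> filter(!.data$.tied) |> select(-".tied")
  best_s <- best_s |> filter(!.data$.tied) |> select(-".tied")
  out <- best_q |>
    semi_join(best_s, by = c("query", "subject")) |>
    filter(!.data$query %in% tied, !.data$subject %in% tied) |>
    transmute(bsb_gene = .data$query, tc_gene = .data$subject,
              score = .data$score,
              evalue_like = if ("evalue_like" %in% names(hits))
                .data$evalue_like else NA_real_) |>
    arrange(.data$bsb_gene, .data$tc_gene)
  out
}

#' Comparative gene-structure statistics over ortholog pairs
#'
#' For each ortholog pair compares exon number and CDS length between
#' the two subgenomes: per-subgenome means, counts of pairs with equal
#' values, Wilcoxon signed-rank p-values for the paired differences, and
#' the Pearson correlation (with p-value) of exon number against CDS
#' length within each subgenome.
#'
#' @param pairs tibble with `bsb_gene`, `tc_gene`.
#' @param models gene-model tibble with `gene_id`, `n_exons`,
#'   `cds_length`.
#' @return a one-row tibble of class `structure_stats`.
#' @export
structure_stats <- function(pairs, models) {
  if (nrow(pairs) < 3) {
    stop_input("structure_stats: need at least 3 ortholog pairs",
               class = "homoeosplice_statistics_error")
  }
  m <- models |> select("gene_id", "n_exons", "cds_length")
  d <- pairs |>
    inner_join(m, by = c(bsb_gene = "gene_id")) |>
    rename(exons_bsb = "n_exons", cds_bsb = "cds_length") |>
    inner_join(m, by = c(tc_gene = "gene_id")) |>
    rename(exons_tc = "n_exons", cds_tc = "cds_length")
  if (nrow(d) < nrow(pairs)) {
    stop_input("structure_stats: some paired genes lack a model",
               class = "homoeosplice_integrity_error")
  }
  safe_wilcox <- function(x, y) {
    if (all(x == y)) return(1)
    suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
  }
  safe_cor <- function(x, y) {
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  cb <- safe_cor(d$exons_bsb, d$cds_bsb)
  ct <- safe_cor(d$exons_tc, d$cds_tc)
  out <- tibble(
    n_pairs = nrow(d),
    mean_exons_bsb = mean(d$exons_bsb),
    mean_exons_tc = mean(d$exons_tc),
    mean_cds_bsb = mean(d$cds_bsb),
    mean_cds_tc = mean(d$cds_tc),
    n_equal_exon_number = sum(d$exons_bsb == d$exons_tc),
    n_equal_cds_length = sum(d$cds_bsb == d$cds_tc),
    p_exon_number = safe_wilcox(d$exons_bsb, d$exons_tc),
    p_cds_length = safe_wilcox(d$cds_bsb, d$cds_tc),
    pearson_r_bsb = cb[["r"]], pearson_p_bsb = cb[["p"]],
    pearson_r_tc = ct[["r"]], pearson_p_tc = ct[["p"]]
  )
  class(out) <- c("structure_stats", class(out))
  out
}
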