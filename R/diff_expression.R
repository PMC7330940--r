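# Homoeolog differential expression between the two reciprocal-cross
# hybrids: common-dispersion NB exact test with BH-FDR.

#' Method-of-moments common dispersion
#'
#' Pooled estimate of the negative-binomial dispersion: counts are
#' scaled to a common library size, then for each gene the within-group
#' moment term `(s^2 - m) / m^2` is computed per group (clamped at zero
#' after averaging) and the estimate is the mean over genes.
#'
#' @param counts integer matrix, genes x samples.
#' @param group factor/vector of two group labels, one per column.
#' @return a single dispersion `phi >= 0`.
#' @export
estimate_common_dispersion <- function(counts, group) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) {
    stop_input("estimate_common_dispersion: all-zero count matrix",
               class = "homoeosplice_estimation_error")
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L || any(table(group) < 2L)) {
    stop_input("estimate_common_dispersion: need two groups with >= 2 replicates")
  }
  lib <- colSums(counts)
  scaled <- sweep(counts, 2L, mean(lib) / lib, `*`)
  per_group <- vapply(levels(group), function(g) {
    x <- scaled[, group == g, drop = FALSE]
    m <- rowMeans(x)
    s2 <- apply(x, 1L, stats::var)
    ifelse(m > 0, (s2 - m) / m^2, NA_real_)
  }, numeric(nrow(counts)))
  per_group <- matrix(per_group, nrow = nrow(counts))
  per_gene <- pmax(0, rowMeans(per_group, na.rm = TRUE))
  mean(per_gene, na.rm = TRUE)
}

#' Exact negative-binomial test on replicate counts
#'
#' Two-sided conditional exact test for a difference in means between
#' two groups of pre-scaled counts (equal effective library sizes).
#' Group sums are NB with sizes `n_a/phi` and `n_b/phi`; conditioning on
#' the pooled total, all splits are enumerated and the p-value sums the
#' probabilities of splits no more probable than the observed one (the
#' standard exact-test convention, not doubling). `phi = 0` reduces to
#' the binomial split of a Poisson total.
#'
#' @param group_a,group_b non-negative integer count vectors.
#' @param phi common NB dispersion.
#' @return two-sided p-value in (0, 1].
#' @examples
#' nb_exact_test(c(3, 3, 3), c(3, 3, 3), phi = 0.1) # 1
#' @export
nb_exact_test <- function(group_a, group_b, phi = 0) {
  if (any(group_a < 0) || any(group_b < 0)) {
    stop_input("nb_exact_test: negative counts")
  }
  na <- length(group_a); nb <- length(group_b)
  ya <- sum(group_a); total <- ya + sum(group_b)
  if (total == 0) return(1)
  y <- 0:total
  if (phi <= 0) {
    probs <- dbinom(y, size = total, prob = na / (na + nb))
  } else {
    mu <- total / (na + nb)
    probs <- dnbinom(y, size = na / phi, mu = na * mu) *
      dnbinom(total - y, size = nb / phi, mu = nb * mu)
    probs <- probs / sum(probs)
  }
  p_obs <- probs[ya + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return FDR values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_input("bh_adjust: p-values outside [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Homoeolog differential expression between the hybrids
#'
#' For each homoeolog (subgenome) and tissue, tests every retained gene
#' for differential expression of TBF3 against BTF3 with the exact NB
#' test at a common dispersion estimated from the same stratum. Counts
#' are first scaled to the geometric-mean library size of the stratum
#' and rounded, making the conditional test's equal-library assumption
#' hold by construction.
#'
#' @param normalized long table from [normalize_and_filter()].
#' @param fdr_threshold FDR cutoff (inclusive) for calling DEGs.
#' @param prior_count pseudo-count used in the log2 fold-change and
#'   log2 CPM summaries.
#' @return an object of class `homoeolog_de`: a tibble with `pair_id`,
#'   `homoeolog`, `tissue`, `log2fc` (TBF3 over BTF3), `log2cpm`,
#'   `p_value`, `fdr`, `direction`.
#' @export
homoeolog_de <- function(normalized, fdr_threshold = 0.05,
                         prior_count = 0.5) {
  strata <- normalized |>
    filter(.data$retained) |>
    group_by(.data$tissue, .data$subgenome)
  res <- strata |>
    group_split() |>
    purrr::map(function(d) {
      wide <- d |>
        tidyr::pivot_wider(id_cols = "pair_id",
                           names_from = c("hybrid", "replicate"),
                           values_from = "count")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      grp <- factor(sub("_.*$", "", colnames(mat)), levels = c("TBF3", "BTF3"))
      # scale to the geometric-mean library size and round
      lib <- colSums(mat)
      geo <- exp(mean(log(lib)))
      scaled <- round(sweep(mat, 2L, geo / lib, `*`))
      phi <- estimate_common_dispersion(scaled, grp)
      a <- scaled[, grp == "TBF3", drop = FALSE]
      b <- scaled[, grp == "BTF3", drop = FALSE]
      p <- vapply(seq_len(nrow(scaled)), function(i) {
        nb_exact_test(a[i, ], b[i, ], phi)
      }, numeric(1))
      mean_a <- rowMeans(a); mean_b <- rowMeans(b)
      tibble(
        pair_id = wide$pair_id,
        homoeolog = d$subgenome[[1L]],
        tissue = d$tissue[[1L]],
        log2fc = log2((mean_a + prior_count) / (mean_b + prior_count)),
        log2cpm = log2(1e6 * (mean_a + mean_b + 2 * prior_count) /
                         (2 * geo)),
        p_value = p,
        phi = phi
      )
    }) |>
    bind_rows()
  res <- res |>
    group_by(.data$homoeolog, .data$tissue) |>
    mutate(fdr = bh_adjust(.data$p_value)) |>
    ungroup() |>
    mutate(direction = case_when(
      .data$fdr <= fdr_threshold & .data$log2fc > 0 ~ "up-in-TBF3",
      .data$fdr <= fdr_threshold & .data$log2fc < 0 ~ "up-in-BTF3",
      TRUE ~ "ns"
    ))
  structure(res, class = c("homoeolog_de", class(res)),
            fdr_threshold = fdr_threshold)
}

#' Call differentially expressed genes
#'
#' @param results a `homoeolog_de` table (or any table with `fdr`).
#' @param threshold FDR threshold (inclusive).
#' @return the DEG rows.
#' @export
call_degs <- function(results, threshold = 0.05) {
  results |> filter(.data$fdr <= threshold)
}

#' Venn counts and direction concordance of shared DEGs
#'
#' Over ortholog pairs of one tissue: how many genes are differentially
#' expressed only in the BSB homoeolog, only in the TC homoeolog, or in
#' both; and among the shared ones, the fraction moving in the same
#' direction.
#'
#' @param bsb_degs,tc_degs DEG tables (rows of a `homoeolog_de` object)
#'   with `pair_id` and `direction`.
#' @param pairs optional ortholog table; when given, DEGs outside it are
#'   an integrity error.
#' @return one-row tibble: `bsb_only`, `tc_only`, `shared`,
#'   `concordance` (NA when no shared DEGs).
#' @export
shared_deg_summary <- function(bsb_degs, tc_degs, pairs = NULL) {
  if (!is.null(pairs)) {
    bad <- setdiff(c(bsb_degs$pair_id, tc_degs$pair_id), pairs$pair_id)
    if (length(bad) > 0) {
      stop_input(paste("shared_deg_summary: DEGs outside the ortholog table:",
                       paste(head(bad, 5), collapse = ", ")),
                 class = "homoeosplice_integrity_error")
    }
  }
  shared_ids <- intersect(bsb_degs$pair_id, tc_degs$pair_id)
  conc <- if (length(shared_ids) == 0) NA_real_ else {
    b <- bsb_degs$direction[match(shared_ids, bsb_degs$pair_id)]
    t <- tc_degs$direction[match(shared_ids, tc_degs$pair_id)]
    mean(b == t)
  }
  tibble(
    bsb_only = length(setdiff(bsb_degs$pair_id, shared_ids)),
    tc_only = length(setdiff(tc_degs$pair_id, shared_ids)),
    shared = length(shared_ids),
    concordance = conc
  )
}

#' @method tidy homoeolog_de
#' @export
tidy.homoeolog_de <- function(x, ...) {
  as_tibble(x) |>
    select("pair_id", "homoeolog", "tissue", "log2fc", "log2cpm",
           "p_value", "fdr", "direction")
}

#' @method glance homoeolog_de
#' @export
glance.homoeolog_de <- function(x, ...) {
  thr <- attr(x, "fdr_threshold") %||% 0.05
  as_tibble(x) |>
    group_by(.data$homoeolog, .data$tissue) |>
    summarise(
      n_genes = dplyr::n(),
      n_deg = sum(.data$fdr <= thr),
      phi = .data$phi[[1L]],
      .groups = "drop"
    )
}

#' @importFrom rlang %||%
NULL
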