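# Read partitioning, SNP count filtering, gene-level homoeolog counts,
# normalization and the maternal-origin check.

snp_tbl <- function(n = 4) {
  tibble::tibble(pair_id = "p", bsb_pos = seq_len(n) * 10L,
                 tc_pos = seq_len(n) * 10L,
                 bsb_alleles = "A", tc_alleles = "G")
}

calls_for <- function(read_id, pos, base) {
  tibble::tibble(read_id = read_id, pair_id = "p", pos = pos, base = base)
}

test_that("short-read calls follow strict majority with ties ambiguous", {
  snps <- snp_tbl(4)
  calls <- dplyr::bind_rows(
    calls_for("r1", c(10L, 20L, 30L), c("A", "A", "A")),  # unanimous BSB
    calls_for("r2", c(10L, 20L, 30L, 40L), c("A", "A", "G", "G")), # tie
    calls_for("r3", c(10L, 20L, 30L), c("G", "G", "A")),  # majority TC
    calls_for("r4", c(10L, 20L), c("C", "C"))             # matches neither
  )
  got <- assign_short_reads(calls, snps, read_ids = sprintf("r%d", 1:5))
  got <- got[match(sprintf("r%d", 1:5), got$read_id), ]
  expect_equal(got$call, c("BSB", "ambiguous", "TC", "ambiguous",
                           "ambiguous"))
  expect_equal(got$covered[5], 0L)
  # conservation: matches never exceed coverage
  expect_true(all(got$matches_bsb + got$matches_tc <= got$covered))
})

test_that("unknown SNP positions error under strict mode, skip otherwise", {
  snps <- snp_tbl(2)
  calls <- calls_for("r1", c(10L, 99L), c("A", "A"))
  expect_error(assign_short_reads(calls, snps, strict = TRUE),
               class = "homoeosplice_integrity_error")
  got <- assign_short_reads(calls, snps)
  expect_equal(got$covered, 1L)
  expect_equal(attr(got, "n_unknown_positions"), 1L)
})

test_that("error-free assignment matches true origin for all covered reads", {
  co <- clean_cohort()
  snps <- clean_snps()
  asg <- assign_short_reads(co$short_read_calls, snps)
  j <- dplyr::inner_join(asg, co$short_reads[, c("read_id", "true_origin")],
                         by = "read_id")
  covered <- j$covered >= 1
  expect_true(all(j$call[covered] == j$true_origin[covered]))
  # read conservation over the full table
  full <- assign_short_reads(co$short_read_calls, snps,
                             read_ids = co$short_reads$read_id)
  n_cov <- sum(full$covered >= 1)
  expect_equal(sum(full$call %in% c("BSB", "TC")) +
                 sum(full$call == "ambiguous" & full$covered >= 1), n_cov)
})

mk_reads <- function(n_rep = 3, hybrids = c("TBF3", "BTF3")) {
  tidyr::expand_grid(hybrid = hybrids, replicate = seq_len(n_rep)) |>
    dplyr::mutate(read_id = sprintf("x%d", dplyr::row_number()),
                  tissue = "gonad")
}

test_that("per-SNP counts tally allele support and drop uncovered SNPs", {
  snps <- snp_tbl(2)
  # SNP 10: 5 BSB + 3 TC reads in every library; SNP 20: replicate 2 of
  # TBF3 has no reads
  libs <- mk_reads()
  reads <- list(); calls <- list()
  k <- 0
  for (i in seq_len(nrow(libs))) {
    for (r in 1:8) {
      k <- k + 1
      id <- sprintf("r%04d", k)
      reads[[k]] <- tibble::tibble(read_id = id, hybrid = libs$hybrid[i],
                                   tissue = "gonad",
                                   replicate = libs$replicate[i])
      b <- if (r <= 5) "A" else "G"
      pos <- if (libs$hybrid[i] == "TBF3" && libs$replicate[i] == 2) 10L
             else c(10L, 20L)
      calls[[k]] <- calls_for(id, pos, rep(b, length(pos)))
    }
  }
  reads <- dplyr::bind_rows(reads); calls <- dplyr::bind_rows(calls)
  got <- snp_allele_counts(calls, reads, snps)
  expect_true(all(got$bsb_pos == 10L))          # SNP 20 dropped
  expect_true(all(got$n_bsb == 5 & got$n_tc == 3))
  # totals over SNPs equal totals over SNP-covering assignments
  expect_equal(sum(got$n_bsb) + sum(got$n_tc),
               nrow(calls |> dplyr::filter(pos == 10L)))
})

test_that("the literal across-replicates mean±2SD filter is vacuous at n = 3", {
  # analytic bound: for any 3 values, max |x - mean| <= 2/sqrt(3) * SD < 2 SD
  set.seed(99)
  x <- tidyr::expand_grid(pair_id = sprintf("g%d", 1:50),
                          bsb_pos = c(10L, 20L),
                          hybrid = "TBF3", tissue = "gonad",
                          replicate = 1:3) |>
    dplyr::mutate(n_bsb = rpois(dplyr::n(), 20) +
                    rpois(dplyr::n(), 1) * 50L,   # wild values too
                  n_tc = rpois(dplyr::n(), 5))
  got <- filter_outlier_snps(x, mode = "across_replicates")
  expect_equal(nrow(got), nrow(x))
  expect_equal(attr(got, "n_dropped"), 0L)
})

test_that("within-gene filtering follows the hand mean/SD computation", {
  # Five SNPs {10, 12, 11, 9, 120}: mean 32.4, sample SD 48.98.
  # |120 - 32.4| = 87.6 < 2 SD = 97.97, so even this extreme value is
  # retained -- with sample SD a group of n values can never exceed
  # (n-1)/sqrt(n) SDs, which stays below 2 until n >= 6.
  x5 <- tibble::tibble(
    pair_id = "g", bsb_pos = c(10L, 20L, 30L, 40L, 50L),
    hybrid = "TBF3", tissue = "gonad", replicate = 1L,
    n_bsb = c(10L, 12L, 11L, 9L, 120L), n_tc = 0L
  )
  got5 <- filter_outlier_snps(x5)
  expect_equal(attr(got5, "n_dropped"), 0L)
  # Ten SNPs, nine at 10 and one at 100: mean 19, sample SD 28.46;
  # |100 - 19| = 81 > 2 SD = 56.9, so the inflated cell is dropped.
  x10 <- tibble::tibble(
    pair_id = "g", bsb_pos = seq_len(10) * 10L,
    hybrid = "TBF3", tissue = "gonad", replicate = 1L,
    n_bsb = c(rep(10L, 9), 100L), n_tc = 0L
  )
  got10 <- filter_outlier_snps(x10)
  expect_equal(attr(got10, "n_dropped"), 1L)
  expect_false(100L %in% got10$n_bsb)
  expect_equal(sort(got10$n_bsb), rep(10L, 9))
})

test_that("groups too small to filter are retained with a warning", {
  x <- tibble::tibble(pair_id = "g", bsb_pos = 10L, hybrid = "TBF3",
                      tissue = "gonad", replicate = 1L,
                      n_bsb = 1000L, n_tc = 0L)
  expect_warning(got <- filter_outlier_snps(x), "< 2 values")
  expect_equal(nrow(got), 1)
})

test_that("planted outliers are removed without harming clean genes", {
  # reads span the whole transcript, so within a library every SNP of a
  # gene sees the same reads and per-SNP totals are equal by
  # construction; a 10x inflated cell is then the only deviant value
  cfg <- sim_config(n_genes = 15, seed = 55, depth = 40, read_len = Inf,
                    tissues = "gonad", error_rate = 0,
                    outlier_snp_rate = 0.08, outlier_factor = 10,
                    as_gene_frac = 0, snp_rate = 0.015,
                    exons_per_gene = c(6L, 10L))
  co <- cached_cohort("outlier_recovery", cfg)
  snps <- call_species_snps(co$coord_maps, co$parent_pileups)
  counts <- snp_allele_counts(co$short_read_calls, co$short_reads, snps)
  got <- filter_outlier_snps(counts)
  truth <- co$truth$outliers
  # require genes with enough SNPs for a stable mean/SD
  n_snps <- counts |> dplyr::distinct(pair_id, bsb_pos) |>
    dplyr::count(pair_id)
  deep <- n_snps$pair_id[n_snps$n >= 8]
  truth_deep <- truth |> dplyr::filter(pair_id %in% deep)
  kept_keys <- with(got, paste(pair_id, bsb_pos, hybrid, tissue, replicate))
  truth_keys <- with(truth_deep,
                     paste(pair_id, bsb_pos, hybrid, tissue, replicate))
  expect_gt(nrow(truth_deep), 3)
  expect_gte(mean(!truth_keys %in% kept_keys), 0.9)
  # no false removals on clean cells of well-covered genes
  dropped <- counts |>
    dplyr::filter(pair_id %in% deep) |>
    dplyr::anti_join(got, by = c("pair_id", "bsb_pos", "hybrid", "tissue",
                                 "replicate"))
  clean_dropped <- dropped |>
    dplyr::anti_join(truth, by = c("pair_id", "bsb_pos", "hybrid",
                                   "tissue", "replicate"))
  expect_equal(nrow(clean_dropped), 0)
})

test_that("gene counts add SNP counts and flag fully filtered genes", {
  x <- tibble::tibble(
    pair_id = "g", bsb_pos = c(10L, 20L), hybrid = "TBF3",
    tissue = "gonad", replicate = 1L,
    n_bsb = c(5L, 4L), n_tc = c(3L, 2L)
  )
  got <- gene_homoeolog_counts(x, all_pairs = c("g", "empty"))
  g <- got |> dplyr::filter(pair_id == "g")
  expect_equal(c(g$bsb_count, g$tc_count), c(9L, 5L))
  e <- got |> dplyr::filter(pair_id == "empty")
  expect_true(e$all_filtered)
  expect_equal(c(e$bsb_count, e$tc_count), c(0L, 0L))
  # conservation against the SNP table
  expect_equal(sum(got$bsb_count) + sum(got$tc_count),
               sum(x$n_bsb) + sum(x$n_tc))
})

test_that("CPM normalization and the >=5-in-all-replicates filter", {
  grid <- tidyr::expand_grid(pair_id = c("g1", "g2"),
                             hybrid = c("TBF3", "BTF3"),
                             tissue = "gonad", replicate = 1:3)
  counts <- grid |>
    dplyr::mutate(
      bsb_count = dplyr::case_when(
        pair_id == "g1" ~ 5L,
        hybrid == "TBF3" & replicate == 3 ~ 4L,
        TRUE ~ 5L),
      tc_count = 100L, all_filtered = FALSE)
  nm <- normalize_and_filter(counts)
  # per-library CPM totals are exactly one million
  sums <- nm |>
    dplyr::group_by(hybrid, tissue, replicate, subgenome) |>
    dplyr::summarise(s = sum(cpm), .groups = "drop")
  expect_true(all(abs(sums$s - 1e6) < 1e-6))
  ret <- nm |> dplyr::distinct(pair_id, subgenome, retained)
  expect_true(ret$retained[ret$pair_id == "g1" & ret$subgenome == "BSB"])
  expect_false(ret$retained[ret$pair_id == "g2" & ret$subgenome == "BSB"])
  # CPM arithmetic: count 4 in a 2e6-read library -> 2.0
  big <- tibble::tibble(pair_id = c("a", "b"), hybrid = "TBF3",
                        tissue = "gonad", replicate = 1L,
                        bsb_count = c(4L, 2e6L - 4L), tc_count = 1L,
                        all_filtered = FALSE)
  nb <- normalize_and_filter(big, min_count = 0)
  expect_equal(nb$cpm[nb$pair_id == "a" & nb$subgenome == "BSB"], 2)
  # zero-total library errors
  zero <- big |> dplyr::mutate(tc_count = 0L)
  expect_error(normalize_and_filter(zero),
               class = "homoeosplice_normalization_error")
})

test_that("filtering never increases any count", {
  co <- cached_cohort("outliers",
                      sim_config(n_genes = 10, seed = 31,
                                 outlier_snp_rate = 0.2))
  snps <- call_species_snps(co$coord_maps, co$parent_pileups)
  counts <- snp_allele_counts(co$short_read_calls, co$short_reads, snps)
  filt <- filter_outlier_snps(counts)
  g_before <- gene_homoeolog_counts(counts)
  g_after <- gene_homoeolog_counts(filt)
  j <- dplyr::inner_join(g_before, g_after,
                         by = c("pair_id", "hybrid", "tissue", "replicate"))
  expect_true(all(j$bsb_count.y <= j$bsb_count.x))
  expect_true(all(j$tc_count.y <= j$tc_count.x))
})

test_that("maternal origin is called from mitochondrial read fractions", {
  m <- tibble::tibble(hybrid = c("h1", "h2", "h3"),
                      bsb_mito_reads = c(1000L, 60L, 0L),
                      tc_mito_reads = c(2L, 40L, 0L))
  got <- mito_origin_check(m)
  expect_equal(got$maternal_call, c("BSB", "undetermined", "undetermined"))
  # synthetic hybrids: calls equal the maternal truth labels
  co <- small_cohort()
  mc <- mito_origin_check(co$mito)
  expect_equal(mc$maternal_call, co$truth$maternal$maternal)
})
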