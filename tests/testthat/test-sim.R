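# Synthetic cohort generator: determinism, planted truth bookkeeping,
# distributional sanity of planted SNPs and read depth.

test_that("config validation names the offending field", {
  expect_error(sim_config(snp_rate = 1.5), "snp_rate")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(exon_len = c(300, 80)), "exon_len")
  expect_error(sim_config(as_events_per_gene = c(XX = 1)),
               "as_events_per_gene")
  err <- tryCatch(sim_config(de_frac = -0.1), error = identity)
  expect_s3_class(err, "homoeosplice_config_error")
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- sim_config(n_genes = 8, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (nm in setdiff(names(a), "config")) {
    expect_identical(a[[nm]], b[[nm]], label = nm)
  }
})

test_that("snp_rate = 0 plants no species-specific markers", {
  co <- simulate_cohort(sim_config(n_genes = 5, seed = 2, snp_rate = 0,
                                   shared_poly_rate = 0))
  expect_equal(nrow(co$snps), 0)
  expect_equal(nrow(co$short_read_calls), 0)
  # downstream: nothing is assignable
  asg <- assign_short_reads(co$short_read_calls, co$snps,
                            read_ids = co$short_reads$read_id)
  expect_true(all(asg$call == "ambiguous"))
})

test_that("planted SNP count is binomial at the configured rate", {
  cfg <- sim_config(n_genes = 50, seed = 13, exon_len = c(150L, 250L))
  co <- simulate_cohort(cfg, reads = FALSE)
  aligned_bp <- sum(co$genes$tx_length[co$genes$subgenome == "BSB"])
  expected <- aligned_bp * cfg$snp_rate
  sigma <- sqrt(aligned_bp * cfg$snp_rate * (1 - cfg$snp_rate))
  expect_lt(abs(nrow(co$snps) - expected), 3 * sigma)
})

test_that("read depth is Poisson at the configured mean", {
  co <- simulate_cohort(sim_config(n_genes = 20, seed = 4, depth = 100,
                                   tissues = "gonad", bias_frac = 0,
                                   de_frac = 0))
  per_gene <- co$short_reads |>
    dplyr::filter(hybrid == "BTF3") |>
    dplyr::count(pair_id)
  # 3 replicates at depth 100 -> Poisson(300) per gene
  expect_true(all(abs(per_gene$n - 300) < 3 * sqrt(300)))
})

test_that("error-free reads carry the true parent's alleles at every SNP", {
  co <- clean_cohort()
  calls <- co$short_read_calls |>
    dplyr::inner_join(co$short_reads[, c("read_id", "true_origin")],
                      by = "read_id") |>
    dplyr::inner_join(co$snps[, c("pair_id", "bsb_pos", "bsb_hap", "tc_hap")],
                      by = c("pair_id", pos = "bsb_pos"))
  expect_true(all(ifelse(calls$true_origin == "BSB",
                         calls$base == calls$bsb_hap,
                         calls$base == calls$tc_hap)))
})

test_that("planted outlier cells are recorded in the truth table", {
  co <- cached_cohort("outliers",
                      sim_config(n_genes = 10, seed = 31,
                                 outlier_snp_rate = 0.2))
  out <- co$truth$outliers
  expect_gt(nrow(out), 0)
  expect_true(all(c("pair_id", "bsb_pos", "hybrid", "tissue", "replicate")
                  %in% names(out)))
  # inflated read ids are tagged and present in the read table
  expect_gt(sum(grepl("_out\\d", co$short_reads$read_id)), 0)
})

test_that("true read origins reproduce the planted homoeolog ratio", {
  co <- cached_cohort("bias",
                      sim_config(n_genes = 20, seed = 77, depth = 120,
                                 tissues = "gonad", bias_frac = 0.5,
                                 bias_log2 = 1))
  obs <- co$short_reads |>
    dplyr::count(pair_id, true_origin) |>
    tidyr::pivot_wider(names_from = true_origin, values_from = n,
                       values_fill = 0L) |>
    dplyr::inner_join(dplyr::distinct(co$truth$bias, pair_id, log2_ratio),
                      by = "pair_id")
  p_hat <- obs$BSB / (obs$BSB + obs$TC)
  p_true <- 2^obs$log2_ratio / (1 + 2^obs$log2_ratio)
  n <- obs$BSB + obs$TC
  expect_true(all(abs(p_hat - p_true) < 4 * sqrt(p_true * (1 - p_true) / n)))
})

test_that("mitochondrial reads encode maternal origin", {
  co <- small_cohort()
  expect_equal(co$mito$tc_mito_reads[co$mito$hybrid == "TBF3"],
               co$config$mito_reads)
  expect_equal(co$mito$bsb_mito_reads[co$mito$hybrid == "TBF3"], 0L)
})

test_that("coordinate maps have no indels at planted SNP columns", {
  co <- small_cohort()
  snp_cols <- co$snps |>
    dplyr::inner_join(co$coord_maps, by = c("pair_id", "bsb_pos"))
  expect_equal(nrow(snp_cols), nrow(co$snps))
  expect_false(any(snp_cols$indel))
  expect_true(all(snp_cols$tc_pos.x == snp_cols$tc_pos.y))
})

# ---- plant_as_isoforms ----------------------------------------------------

ref3 <- cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L))

test_that("an all-zero request returns only the reference chain", {
  p <- plant_as_isoforms(ref3, c(SE = 0L))
  expect_equal(unique(p$chains$chain_id), "iso0")
  expect_equal(nrow(p$events), 0)
})

test_that("a skipped-exon request drops exactly the middle exon", {
  p <- plant_as_isoforms(ref3, c(SE = 1L))
  v <- p$chains |> dplyr::filter(chain_id == "iso1")
  expect_equal(v$start, c(0L, 400L))
  expect_equal(v$end, c(100L, 500L))
  expect_equal(p$events$type, "SE")
  expect_equal(p$events$coords[[1]], c(200L, 300L))
})

test_that("planted events round-trip through the classifier", {
  ref5 <- cbind(start = c(0L, 200L, 400L, 600L, 800L),
                end = c(100L, 300L, 500L, 700L, 900L))
  for (strand in c("+", "-")) {
    p <- plant_as_isoforms(ref5, c(RI = 1L, A3SS = 1L), strand = strand)
    ev <- classify_as_events(
      p$chains |> dplyr::mutate(gene_id = "g", strand = strand))
    expect_setequal(ev$anchor, p$events$anchor)
    expect_setequal(ev$type, c("RI", "A3SS"))
  }
})

test_that("each planted type is recovered exactly, alone and combined", {
  ref <- {
    n <- 13L
    s <- seq(0L, by = 300L, length.out = n)
    cbind(start = s, end = s + 150L)
  }
  for (type in c("SE", "RI", "A5SS", "A3SS", "MXE", "AP")) {
    req <- setNames(1L, type)
    p <- plant_as_isoforms(ref, req, strand = "+")
    ev <- classify_as_events(
      p$chains |> dplyr::mutate(gene_id = "g", strand = "+"))
    expect_equal(ev$type, type, label = type)
    expect_equal(ev$anchor, p$events$anchor, label = type)
  }
  all6 <- c(SE = 1L, RI = 1L, A5SS = 1L, A3SS = 1L, MXE = 1L, AP = 1L)
  p <- plant_as_isoforms(ref, all6, strand = "+")
  ev <- classify_as_events(
    p$chains |> dplyr::mutate(gene_id = "g", strand = "+"))
  expect_setequal(ev$anchor, p$events$anchor)
})

test_that("unrealizable requests raise a capability error", {
  two_exons <- cbind(start = c(0L, 200L), end = c(100L, 300L))
  expect_error(plant_as_isoforms(two_exons, c(MXE = 1L)),
               class = "homoeosplice_capability_error")
  expect_error(plant_as_isoforms(two_exons, c(SE = 1L)),
               class = "homoeosplice_capability_error")
})
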