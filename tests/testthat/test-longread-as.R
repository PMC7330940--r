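# Full-length classification, long-read subgenome assignment, AS event
# classification and cross-homoeolog sharing.

test_that("full-length calls need strict length > 300 and all three flags", {
  r <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    length = c(301, 300, 5000, 400),
    has_5prime_primer = c(TRUE, TRUE, TRUE, TRUE),
    has_3prime_primer = c(TRUE, TRUE, TRUE, TRUE),
    has_polyA = c(TRUE, TRUE, FALSE, TRUE)
  )
  got <- classify_full_length(r)
  expect_equal(got$full_length, c(TRUE, FALSE, FALSE, TRUE))
  # cohort: classification equals the recorded truth exactly
  co <- small_cohort()
  fl <- classify_full_length(co$long_reads)
  expect_equal(fl$full_length, co$long_reads$fl_truth)
})

test_that("long-read assignment uses an inclusive 85% concordance rule", {
  snps <- tibble::tibble(pair_id = "p", bsb_pos = seq_len(20) * 10L,
                         tc_pos = seq_len(20) * 10L,
                         bsb_alleles = "A", tc_alleles = "G")
  mk <- function(id, n_bsb, n_total) {
    tibble::tibble(read_id = id, pair_id = "p",
                   pos = seq_len(n_total) * 10L,
                   base = c(rep("A", n_bsb), rep("G", n_total - n_bsb)))
  }
  calls <- dplyr::bind_rows(mk("r17", 17, 20), mk("r16", 16, 20),
                            mk("r9", 9, 10), mk("r8", 8, 10))
  got <- assign_long_read(calls, snps, read_ids = c("r17", "r16", "r9",
                                                    "r8", "r0"))
  expect_equal(got$call, c("BSB", "unassigned", "BSB", "unassigned",
                           "unassigned"))
  expect_equal(got$reason[got$read_id == "r0"], "no_snps")
  # error-free cohort long reads all agree with their true origin
  co <- clean_cohort()
  al <- assign_long_read(co$long_read_calls, clean_snps())
  j <- dplyr::inner_join(al, co$long_reads[, c("read_id", "true_origin")],
                         by = "read_id")
  expect_true(all(j$call[j$covered > 0] == j$true_origin[j$covered > 0]))
})

chain_tbl <- function(...) {
  chains <- list(...)
  dplyr::bind_rows(purrr::imap(chains, function(m, i) {
    tibble::tibble(gene_id = "g", chain_id = paste0("c", i),
                   start = m[, 1], end = m[, 2])
  }))
}

test_that("textbook chain pairs classify to their defining events", {
  A <- cbind(c(0L, 200L, 400L), c(100L, 300L, 500L))
  # identical chains: nothing
  expect_equal(nrow(classify_as_events(chain_tbl(A, A))), 0)
  # SE anchored at the missing exon
  B <- A[-2, ]
  se <- classify_as_events(chain_tbl(A, B))
  expect_equal(se$anchor, "SE:200-300")
  # RI anchored at the retained intron
  ri <- classify_as_events(chain_tbl(
    cbind(c(0L, 200L), c(100L, 300L)), cbind(0L, 300L)))
  expect_equal(ri$anchor, "RI:100-200")
  # A5SS on + strand: donor 100 vs 120, shared acceptor 200
  a5 <- classify_as_events(chain_tbl(
    cbind(c(0L, 200L), c(100L, 300L)), cbind(c(0L, 200L), c(120L, 300L))))
  expect_equal(a5$type, "A5SS")
  expect_equal(a5$anchor, "A5SS:200-100-120")
  # MXE: exclusive internal exons with shared flanks
  X <- cbind(c(0L, 200L, 400L), c(100L, 300L, 500L))
  Y <- cbind(c(0L, 320L, 400L), c(100L, 380L, 500L))
  mx <- classify_as_events(chain_tbl(X, Y))
  expect_equal(mx$anchor, "MXE:200-300-320-380")
  # AP: identical introns, different first-exon start
  Z <- X; Z[1, 1] <- 20L
  ap <- classify_as_events(chain_tbl(X, Z))
  expect_equal(ap$type, "AP")
  # OTHER: structural difference matching no named rule
  W <- cbind(c(0L, 150L), c(100L, 300L))
  V <- cbind(c(0L, 210L), c(120L, 280L))
  ot <- classify_as_events(chain_tbl(W, V))
  expect_equal(ot$type, "OTHER")
})

test_that("classification is symmetric and strand flips A5SS <-> A3SS", {
  A <- cbind(c(0L, 200L), c(100L, 300L))
  B <- cbind(c(0L, 200L), c(120L, 300L))
  ab <- classify_as_events(chain_tbl(A, B))
  ba <- classify_as_events(chain_tbl(B, A))
  expect_equal(ab$anchor, ba$anchor)
  minus <- classify_as_events(chain_tbl(A, B) |>
                                dplyr::mutate(strand = "-"))
  expect_equal(minus$type, "A3SS")
  expect_equal(sub("A3SS", "A5SS", minus$anchor), ab$anchor)
})

test_that("distinct chains always yield at least one event", {
  set.seed(42)
  for (i in 1:200) {
    A <- random_chain(); B <- random_chain()
    if (identical(A, B)) next
    ev <- classify_as_events(chain_tbl(A, B))
    expect_gte(nrow(ev), 1)
  }
})

test_that("the classifier agrees with the brute-force rule oracle", {
  set.seed(7)
  for (i in 1:300) {
    A <- random_chain()
    B <- if (i %% 2 == 0) random_chain() else mutate_chain(A)
    C <- mutate_chain(A)
    strand <- sample(c("+", "-"), 1)
    chains <- list(A, B, C)
    got <- classify_as_events(chains_to_tibble(chains, strand = strand))
    expect_identical(event_keys(got),
                     oracle_classify(chains, strand = strand),
                     label = sprintf("case %d", i))
  }
})

test_that("planted events are recovered from cohort chains exactly", {
  co <- small_cohort()
  ev <- classify_as_events(
    co$chains |> dplyr::select(gene_id, homoeolog, strand, chain_id,
                               start, end))
  truth <- co$truth$as_events
  expect_identical(sort(paste(ev$gene_id, ev$anchor)),
                   sort(paste(truth$gene_id, truth$anchor)))
})

test_that("events shared across homoeologs match through the map", {
  co <- small_cohort()
  ev <- classify_as_events(
    co$chains |> dplyr::select(gene_id, homoeolog, strand, chain_id,
                               start, end))
  sh <- shared_as_across_homoeologs(
    ev |> dplyr::filter(homoeolog == "BSB"),
    ev |> dplyr::filter(homoeolog == "TC"),
    co$pairs, co$coord_maps
  )
  truth_shared <- co$truth$as_events |>
    dplyr::filter(shared, homoeolog == "BSB")
  expect_equal(nrow(sh), nrow(truth_shared))
  expect_setequal(paste(sh$pair_id, sh$anchor_bsb),
                  paste(truth_shared$pair_id, truth_shared$anchor))
  # same coordinates but different types never match
  fake <- ev |> dplyr::filter(homoeolog == "TC") |>
    dplyr::mutate(type = "OTHER")
  expect_equal(nrow(shared_as_across_homoeologs(
    ev |> dplyr::filter(homoeolog == "BSB"), fake,
    co$pairs, co$coord_maps)), 0)
})

test_that("high-AS genes use an inclusive >= 5 threshold and intersect", {
  ev <- tibble::tibble(
    gene_id = c(rep("g4", 4), rep("g5", 5), rep("g6", 6)),
    type = "SE",
    anchor = sprintf("SE:%d", 1:15)
  )
  got <- high_as_genes(ev)
  expect_setequal(got$gene_id, c("g5", "g6"))
  expect_equal(got$n_events[got$gene_id == "g5"], 5)
  sets <- list(c("a", "b", "c"), c("b", "c", "d"), c("c", "b"))
  expect_equal(shared_high_as_genes(sets), c("b", "c"))
})
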