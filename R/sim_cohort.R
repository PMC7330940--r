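# Synthetic reciprocal-cross cohort: two diverged parental gene sets,
# fixed inter-species SNPs, two hybrids x tissues x replicates of short
# reads with planted homoeolog bias / DE / outliers, long reads with
# full-length structure and planted AS isoforms, and full ground truth.

#' Plant alternative-splicing isoforms on a gene model
#'
#' Builds one variant exon chain per requested event so that classifying
#' the returned chains recovers exactly the requested events. Events are
#' placed on separated internal exon/intron slots so variants do not
#' interfere with one another (for `AP`, at most one event per gene keeps
#' the round trip exact).
#'
#' @param exons reference exon intervals: a 2-column matrix or a
#'   data frame with `start`, `end` (0-based half-open, sorted).
#' @param counts named integer vector of requested event counts; names
#'   from `SE, RI, A5SS, A3SS, MXE, AP`.
#' @param strand `"+"` or `"-"`.
#' @param gene_id label used in the returned tables.
#' @return list with `chains` (tibble `chain_id`, `start`, `end`;
#'   `"iso0"` is the reference) and `events` (tibble `chain_id`, `type`,
#'   `anchor`, `coords` list-column of classifier anchor coordinates).
#' @examples
#' ref <- cbind(start = c(0, 200, 400), end = c(100, 300, 500))
#' plant_as_isoforms(ref, c(SE = 1))$chains
#' @export
plant_as_isoforms <- function(exons, counts, strand = "+",
                              gene_id = "gene") {
  if (is.data.frame(exons)) exons <- as_exon_matrix(exons$start, exons$end)
  E <- validate_chain(exons, label = gene_id)
  counts <- counts[counts > 0]
  if (length(counts) > 0 && !all(names(counts) %in% AS_TYPES_NAMED)) {
    stop_input(paste("plant_as_isoforms: unknown event type(s):",
                     paste(setdiff(names(counts), AS_TYPES_NAMED),
                           collapse = ", ")))
  }
  chains <- list(iso0 = E)
  events <- list()
  n <- nrow(E)
  slotted <- rep(names(counts)[names(counts) != "AP"],
                 counts[names(counts) != "AP"])
  n_ap <- if ("AP" %in% names(counts)) counts[["AP"]] else 0L
  if (length(slotted) > 0 && n < 2L * length(slotted) + 1L) {
    stop_input(sprintf(
      "%s: %d internal events need >= %d exons, gene has %d",
      gene_id, length(slotted), 2L * length(slotted) + 1L, n),
      class = "homoeosplice_capability_error")
  }
  if (n_ap > 0 && E[1L, 2L] - E[1L, 1L] < 16L) {
    stop_input(sprintf("%s: first exon too short for an AP variant", gene_id),
               class = "homoeosplice_capability_error")
  }

  emit <- function(type, variant, coords) {
    id <- sprintf("iso%d", length(chains))
    chains[[id]] <<- validate_chain(variant, label = paste(gene_id, id))
    events[[length(events) + 1L]] <<- tibble(
      chain_id = id, type = type,
      anchor = paste0(type, ":", paste(coords, collapse = "-")),
      coords = list(as.integer(coords))
    )
  }

  for (i in seq_along(slotted)) {
    type <- slotted[[i]]
    k <- 2L * i                       # internal exon slot; introns k-1, k
    gap <- E[k + 1L, 1L] - E[k, 2L]   # intron following the slot exon
    if (type == "SE") {
      emit("SE", E[-k, , drop = FALSE], E[k, ])
    } else if (type == "RI") {
      v <- E
      v[k, 2L] <- E[k + 1L, 2L]
      v <- v[-(k + 1L), , drop = FALSE]
      emit("RI", v, c(E[k, 2L], E[k + 1L, 1L]))
    } else if (type == "A5SS" || type == "A3SS") {
      d <- min(12L, gap - 2L)
      if (d < 1L) {
        stop_input(sprintf("%s: intron %d too short for %s", gene_id, k, type),
                   class = "homoeosplice_capability_error")
      }
      # donor-side change on "+" = shift of the upstream exon end;
      # acceptor-side change on "+" = shift of the downstream exon start
      donor_side <- (type == "A5SS") == (strand == "+")
      v <- E
      if (donor_side) {
        v[k, 2L] <- E[k, 2L] + d
        coords <- c(E[k + 1L, 1L], sort(c(E[k, 2L], E[k, 2L] + d)))
      } else {
        v[k + 1L, 1L] <- E[k + 1L, 1L] - d
        coords <- c(E[k, 2L], sort(c(E[k + 1L, 1L] - d, E[k + 1L, 1L])))
      }
      emit(type, v, coords)
    } else if (type == "MXE") {
      ylen <- min(40L, gap - 4L)
      if (n < 3L || ylen < 8L) {
        stop_input(sprintf(
          "%s: cannot place a mutually exclusive exon in a %d bp intron",
          gene_id, gap), class = "homoeosplice_capability_error")
      }
      ys <- E[k, 2L] + max(2L, (gap - ylen) %/% 2L)
      y <- c(ys, ys + ylen)
      v <- E
      v[k, ] <- y
      emit("MXE", v, c(E[k, ], y))
    }
  }
  for (i in seq_len(n_ap)) {
    d <- 8L + 4L * i
    v <- chains$iso0
    if (i %% 2L == 1L) {
      v[1L, 1L] <- v[1L, 1L] + d
      coords <- c(sort(c(E[1L, 1L], E[1L, 1L] + d)), E[n, 2L], E[n, 2L])
    } else {
      v[n, 2L] <- v[n, 2L] - d
      coords <- c(E[1L, 1L], E[1L, 1L], sort(c(E[n, 2L] - d, E[n, 2L])))
    }
    emit("AP", v, coords)
  }

  chain_tbl <- purrr::imap(chains, function(m, id) {
    tibble(chain_id = id, start = m[, 1L], end = m[, 2L])
  }) |> bind_rows()
  list(
    chains = chain_tbl,
    events = if (length(events) > 0) bind_rows(events) else
      tibble(chain_id = character(), type = character(),
             anchor = character(), coords = list())
  )
}

#' Simulate a reciprocal-cross cohort with ground truth
#'
#' Generates the full study scaffold: parental gene models with shared
#' exon structure per ortholog pair (TC introns optionally lengthened,
#' producing indel columns in the coordinate map), exonic fixed
#' inter-species SNPs, parental pileups at polymorphic columns, isoform
#' chains with planted AS events, and mitochondrial read counts encoding
#' maternal origin (TBF3 carries the TC mitogenome, BTF3 the BSB one).
#' With `reads = TRUE` (default) short and long hybrid reads are
#' simulated too (see [simulate_reads()]).
#'
#' All draws are fixed by `config$seed`: the same configuration always
#' yields an identical cohort.
#'
#' @param config a [sim_config()] object.
#' @param reads whether to simulate short and long reads immediately.
#' @return an object of class `sim_cohort`: a list of tibbles (`genes`,
#'   `exons`, `transcripts`, `pairs`, `coord_maps`, `snps`,
#'   `parent_pileups`, `chains`, `mito`, and with reads
#'   `short_reads`, `short_read_calls`, `long_reads`,
#'   `long_read_calls`) plus a `truth` list (`bias`, `de`, `as_events`,
#'   `outliers`, `maternal`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_genes = 5, seed = 1))
#' cohort$snps
#' @export
simulate_cohort <- function(config, reads = TRUE) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  gene_num <- sprintf("g%04d", seq_len(ng))

  genes_l <- vector("list", ng); exons_l <- vector("list", ng)
  maps_l <- vector("list", ng); snps_l <- vector("list", ng)
  tx_l <- vector("list", ng); chains_l <- vector("list", ng)
  as_truth_l <- vector("list", ng); pile_l <- vector("list", ng)
  poly_l <- vector("list", ng)

  n_as_total <- sum(config$as_events_per_gene)
  min_exons_as <- 2L * sum(config$as_events_per_gene[
    setdiff(names(config$as_events_per_gene), "AP")]) + 1L

  for (i in seq_len(ng)) {
    pid <- gene_num[[i]]
    bsb_gene <- paste0(pid, "_bsb"); tc_gene <- paste0(pid, "_tc")
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
    ex_w <- sample(config$exon_len[1]:config$exon_len[2], n_ex, replace = TRUE)
    in_w <- if (n_ex > 1L) {
      sample(config$intron_len[1]:config$intron_len[2], n_ex - 1L,
             replace = TRUE)
    } else integer()
    strand <- sample(c("+", "-"), 1L)

    starts <- cumsum(c(0L, head(ex_w, -1L) + in_w))
    E <- cbind(start = starts, end = starts + ex_w)
    glen_b <- E[n_ex, 2L]

    # TC structure: same exons, introns optionally lengthened
    indel_extra <- integer(max(0L, n_ex - 1L))
    if (n_ex > 1L) {
      hit <- runif(n_ex - 1L) < config$intron_indel_rate
      indel_extra[hit] <- sample(
        config$intron_indel_len[1]:config$intron_indel_len[2],
        sum(hit), replace = TRUE)
    }
    tc_in_w <- in_w + indel_extra
    tc_starts <- cumsum(c(0L, head(ex_w, -1L) + tc_in_w))
    Et <- cbind(start = tc_starts, end = tc_starts + ex_w)
    glen_t <- Et[n_ex, 2L]

    # coordinate map: exon columns aligned 1:1; intron columns aligned
    # head-to-head and tail-to-tail, TC-only middle columns are indels
    mp_b <- vector("list", 2L * n_ex - 1L)
    mp_t <- vector("list", 2L * n_ex - 1L)
    mp_i <- vector("list", 2L * n_ex - 1L)
    for (k in seq_len(n_ex)) {
      mp_b[[2L * k - 1L]] <- seq.int(E[k, 1L], E[k, 2L] - 1L)
      mp_t[[2L * k - 1L]] <- seq.int(Et[k, 1L], Et[k, 2L] - 1L)
      mp_i[[2L * k - 1L]] <- rep(FALSE, ex_w[k])
      if (k < n_ex) {
        lb <- in_w[k]; lt <- tc_in_w[k]
        h <- (lb + 1L) %/% 2L; t <- lb - h
        b_cols <- seq.int(E[k, 2L], length.out = lb)
        t_cols <- c(seq.int(Et[k, 2L], length.out = h),
                    if (t > 0L) seq.int(Et[k + 1L, 1L] - t, length.out = t))
        extra <- lt - lb
        mp_b[[2L * k]] <- c(b_cols, rep(NA_integer_, extra))
        mp_t[[2L * k]] <- c(t_cols,
                            if (extra > 0L)
                              seq.int(Et[k, 2L] + h, length.out = extra))
        mp_i[[2L * k]] <- c(rep(FALSE, lb), rep(TRUE, extra))
      }
    }
    cmap <- tibble(pair_id = pid, bsb_pos = unlist(mp_b),
                   tc_pos = unlist(mp_t), indel = unlist(mp_i)) |>
      arrange(.data$tc_pos)

    # sequence and SNPs (exonic only; never on indel columns by design)
    ex_pos_b <- unlist(lapply(seq_len(n_ex),
                              function(k) seq.int(E[k, 1L], E[k, 2L] - 1L)))
    ex_pos_t <- unlist(lapply(seq_len(n_ex),
                              function(k) seq.int(Et[k, 1L], Et[k, 2L] - 1L)))
    tx_len <- length(ex_pos_b)
    ref <- sample(DNA_BASES, tx_len, replace = TRUE)
    is_snp <- runif(tx_len) < config$snp_rate
    snp_idx <- which(is_snp)
    tc_allele <- other_base(ref[snp_idx],
                            sample(1:3, length(snp_idx), replace = TRUE))
    het <- runif(length(snp_idx)) < config$het_rate
    het_allele <- rep(NA_character_, length(snp_idx))
    if (any(het)) {
      # second BSB allele distinct from both ref and the TC allele
      het_allele[het] <- purrr::map2_chr(
        ref[snp_idx[het]], tc_allele[het],
        function(r, t) setdiff(DNA_BASES, c(r, t))[sample.int(2L, 1L)])
    }
    bsb_sets <- ifelse(het, paste(ref[snp_idx], het_allele, sep = "/"),
                       ref[snp_idx])
    snps_l[[i]] <- tibble(
      pair_id = pid, bsb_pos = ex_pos_b[snp_idx], tc_pos = ex_pos_t[snp_idx],
      tx_pos = snp_idx - 1L,
      bsb_alleles = bsb_sets, tc_alleles = tc_allele,
      bsb_hap = ref[snp_idx], tc_hap = tc_allele
    )

    # non-diagnostic polymorphic columns (parents share the ref allele)
    free <- setdiff(seq_len(tx_len), snp_idx)
    n_poly <- rbinom(1L, length(free), config$shared_poly_rate)
    poly_idx <- if (n_poly > 0L) sort(sample(free, n_poly)) else integer()
    poly_l[[i]] <- if (n_poly > 0L) {
      tibble(pair_id = pid, bsb_pos = ex_pos_b[poly_idx],
             tc_pos = ex_pos_t[poly_idx],
             bsb_alleles = paste(ref[poly_idx],
                                 other_base(ref[poly_idx], 1L), sep = "/"),
             tc_alleles = paste(ref[poly_idx],
                                other_base(ref[poly_idx], 2L), sep = "/"))
    } else NULL

    tc_seq <- ref
    tc_seq[snp_idx] <- tc_allele
    tx_l[[i]] <- tibble(
      gene_id = c(bsb_gene, tc_gene),
      seq = c(paste(ref, collapse = ""), paste(tc_seq, collapse = ""))
    )

    # isoform chains and planted AS events
    bsb_chains <- tibble(chain_id = "iso0", start = E[, 1L], end = E[, 2L])
    gene_events <- NULL
    plant_here <- n_as_total > 0 && n_ex >= min_exons_as &&
      runif(1L) < config$as_gene_frac
    shared_here <- FALSE
    if (plant_here) {
      planted <- plant_as_isoforms(E, config$as_events_per_gene,
                                   strand = strand, gene_id = bsb_gene)
      bsb_chains <- planted$chains
      shared_here <- runif(1L) < config$as_shared_frac
      gene_events <- planted$events |>
        mutate(pair_id = pid, gene_id = bsb_gene, homoeolog = "BSB",
               shared = shared_here)
    }
    tc_chains <- if (shared_here) {
      bsb_chains |>
        mutate(start = map_boundary(.data$start, cmap$bsb_pos, cmap$tc_pos),
               end = map_boundary(.data$end, cmap$bsb_pos, cmap$tc_pos))
    } else {
      tibble(chain_id = "iso0", start = Et[, 1L], end = Et[, 2L])
    }
    if (shared_here) {
      tc_events <- gene_events |>
        mutate(
          gene_id = tc_gene, homoeolog = "TC",
          coords = purrr::map(.data$coords, map_boundary,
                              from = cmap$bsb_pos, to = cmap$tc_pos),
          anchor = paste0(.data$type, ":",
                          purrr::map_chr(.data$coords, paste, collapse = "-"))
        )
      gene_events <- bind_rows(gene_events, tc_events)
    }
    if (!is.null(gene_events)) as_truth_l[[i]] <- gene_events
    chains_l[[i]] <- bind_rows(
      bsb_chains |> mutate(gene_id = bsb_gene, homoeolog = "BSB"),
      tc_chains |> mutate(gene_id = tc_gene, homoeolog = "TC")
    ) |> mutate(pair_id = pid, strand = strand)

    # gene models; CDS length = exonic length minus independent UTR trims
    trim <- function() min(sum(ex_w) - 90L, sample(30:200, 1L))
    genes_l[[i]] <- tibble(
      gene_id = c(bsb_gene, tc_gene), pair_id = pid,
      subgenome = c("BSB", "TC"), strand = strand,
      n_exons = n_ex, tx_length = sum(ex_w),
      cds_length = c(max(90L, sum(ex_w) - trim()),
                     max(90L, sum(ex_w) - trim())),
      gene_length = c(glen_b, glen_t)
    )
    exons_l[[i]] <- bind_rows(
      tibble(gene_id = bsb_gene, exon = seq_len(n_ex),
             start = E[, 1L], end = E[, 2L]),
      tibble(gene_id = tc_gene, exon = seq_len(n_ex),
             start = Et[, 1L], end = Et[, 2L])
    )
    maps_l[[i]] <- cmap
  }

  genes <- bind_rows(genes_l)
  pairs <- tibble(pair_id = gene_num,
                  bsb_gene = paste0(gene_num, "_bsb"),
                  tc_gene = paste0(gene_num, "_tc"))
  snps <- bind_rows(snps_l)
  shared_poly <- bind_rows(poly_l)

  # planted homoeolog bias (log2 BSB/TC) and between-hybrid DE
  n_bias <- round(config$bias_frac * ng)
  n_de <- round(config$de_frac * ng)
  bias_genes <- sort(sample(gene_num, n_bias))
  de_genes <- sort(sample(gene_num, n_de))
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  bias <- tidyr::expand_grid(pair_id = gene_num, tissue = config$tissues) |>
    mutate(log2_ratio = ifelse(.data$pair_id %in% bias_genes,
                               config$bias_log2, 0))
  de <- tibble(pair_id = de_genes,
               log2fc = de_sign * config$de_log2,
               direction = ifelse(de_sign > 0, "up-in-TBF3", "up-in-BTF3"))

  # parental pileups at polymorphic candidate columns
  cand <- bind_rows(
    snps |> select("pair_id", "bsb_pos", "tc_pos",
                   "bsb_alleles", "tc_alleles"),
    shared_poly
  )
  pileups <- sim_parent_pileups(cand, config)

  mito <- tibble(
    hybrid = c("TBF3", "BTF3"),
    maternal = c("TC", "BSB"),
    bsb_mito_reads = c(0L, config$mito_reads),
    tc_mito_reads = c(config$mito_reads, 0L)
  )

  cohort <- structure(list(
    config = config,
    genes = genes,
    exons = bind_rows(exons_l),
    transcripts = bind_rows(tx_l),
    pairs = pairs,
    coord_maps = bind_rows(maps_l),
    snps = snps,
    parent_pileups = pileups,
    chains = bind_rows(chains_l) |>
      select("pair_id", "gene_id", "homoeolog", "strand", "chain_id",
             "start", "end"),
    mito = mito,
    truth = list(
      bias = bias, de = de,
      as_events = {
        at <- bind_rows(as_truth_l)
        if (nrow(at) == 0) {
          tibble(pair_id = character(), gene_id = character(),
                 homoeolog = character(), chain_id = character(),
                 type = character(), anchor = character(), coords = list(),
                 shared = logical())
        } else {
          at |> select("pair_id", "gene_id", "homoeolog", "chain_id",
                       "type", "anchor", "coords", "shared")
        }
      },
      outliers = NULL,
      maternal = mito |> select("hybrid", "maternal")
    )
  ), class = "sim_cohort")

  if (reads) {
    cohort <- simulate_reads(cohort, "short")
    cohort <- simulate_reads(cohort, "long")
  }
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$pairs), "ortholog pairs,",
      nrow(x$snps), "planted SNPs,",
      if (!is.null(x$short_reads)) nrow(x$short_reads) else 0, "short reads,",
      if (!is.null(x$long_reads)) nrow(x$long_reads) else 0, "long reads\n")
  invisible(x)
}

# per-column parental base counts, 3 replicates per parent
sim_parent_pileups <- function(cand, config) {
  if (nrow(cand) == 0) {
    return(tibble(pair_id = character(), bsb_pos = integer(),
                  parent = character(), replicate = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer()))
  }
  nrep <- config$n_replicates
  grid <- tidyr::expand_grid(
    cand |> mutate(.row = dplyr::row_number()),
    parent = c("BSB", "TC"), replicate = seq_len(nrep)
  )
  alleles <- ifelse(grid$parent == "BSB", grid$bsb_alleles, grid$tc_alleles)
  cov <- rpois(nrow(grid), config$parent_depth)
  counts <- matrix(0L, nrow(grid), 4L, dimnames = list(NULL, DNA_BASES))
  split_sets <- strsplit(alleles, "/", fixed = TRUE)
  for (r in seq_len(nrow(grid))) {
    if (cov[r] == 0L) next
    al <- split_sets[[r]]
    draw <- sample(al, cov[r], replace = TRUE)
    err <- runif(cov[r]) < config$error_rate
    if (any(err)) {
      draw[err] <- other_base(draw[err], sample(1:3, sum(err), replace = TRUE))
    }
    tb <- table(factor(draw, levels = DNA_BASES))
    counts[r, ] <- as.integer(tb)
  }
  tibble(pair_id = grid$pair_id, bsb_pos = grid$bsb_pos,
         parent = grid$parent, replicate = grid$replicate,
         A = counts[, "A"], C = counts[, "C"],
         G = counts[, "G"], T = counts[, "T"])
}

#' Simulate hybrid reads over a cohort scaffold
#'
#' Short reads (`kind = "short"`) carry hybrid/tissue/replicate labels,
#' a transcript-placement window and base calls at every covered SNP
#' column; read counts are Poisson at the configured depth, scaled by
#' planted DE on TBF3, and each read's true subgenome of origin follows
#' the planted homoeolog bias. Planted outlier SNP cells
#' (`outlier_snp_rate > 0`) receive duplicated reads at
#' `outlier_factor`-fold inflation and are recorded in
#' `truth$outliers`. Long reads (`kind = "long"`) sample an isoform
#' chain of their true homoeolog and carry primer/poly(A)/length
#' structure at the configured full-length rate.
#'
#' With `error_rate = 0`, every base call equals the true parent's
#' haplotype allele.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param kind `"short"` or `"long"`.
#' @return the cohort with read tables (and truth) filled in.
#' @export
simulate_reads <- function(cohort, kind = c("short", "long")) {
  kind <- match.arg(kind)
  if (kind == "short") sim_short_reads(cohort) else sim_long_reads(cohort)
}

sim_short_reads <- function(cohort) {
  config <- cohort$config
  set.seed(child_seed(config$seed, 1L))
  nrep <- config$n_replicates
  libs <- tidyr::expand_grid(hybrid = c("TBF3", "BTF3"),
                             tissue = config$tissues,
                             replicate = seq_len(nrep))
  de <- cohort$truth$de
  bias1 <- cohort$truth$bias |>
    distinct(.data$pair_id, .data$log2_ratio)

  reads_l <- list(); calls_l <- list()
  snps_by_pair <- split(cohort$snps, cohort$snps$pair_id)
  exons_bsb <- cohort$exons |>
    inner_join(cohort$pairs |> select(pair_id = "pair_id", gene_id = "bsb_gene"),
               by = "gene_id")
  exons_by_pair <- split(exons_bsb, exons_bsb$pair_id)

  for (pid in cohort$pairs$pair_id) {
    ex <- exons_by_pair[[pid]]
    widths <- ex$end - ex$start
    tx_len <- sum(widths)
    cum0 <- cumsum(c(0L, head(widths, -1L)))
    rl <- as.integer(min(config$read_len, tx_len))
    sn <- snps_by_pair[[pid]]
    lfc <- if (pid %in% de$pair_id) de$log2fc[de$pair_id == pid] else 0
    b <- bias1$log2_ratio[bias1$pair_id == pid]
    p_bsb <- 2^b / (1 + 2^b)

    mult <- ifelse(libs$hybrid == "TBF3", 2^lfc, 1)
    n_lib <- rpois(nrow(libs), config$depth * mult)
    total <- sum(n_lib)
    if (total == 0L) next
    lib_idx <- rep(seq_len(nrow(libs)), n_lib)
    origin <- ifelse(runif(total) < p_bsb, "BSB", "TC")
    start_t <- if (tx_len > rl) {
      sample.int(tx_len - rl + 1L, total, replace = TRUE) - 1L
    } else rep(0L, total)
    read_id <- sprintf("%s_sr%06d", pid, seq_len(total))

    # genomic span of the transcript window on the reference chain
    first_ex <- findInterval(start_t, cum0)
    last_ex <- findInterval(start_t + rl - 1L, cum0)
    g_start <- ex$start[first_ex] + (start_t - cum0[first_ex])
    g_end <- ex$start[last_ex] + (start_t + rl - cum0[last_ex])

    reads_l[[pid]] <- tibble(
      read_id = read_id, pair_id = pid,
      hybrid = libs$hybrid[lib_idx], tissue = libs$tissue[lib_idx],
      replicate = libs$replicate[lib_idx],
      true_origin = origin, start = g_start, end = g_end
    )

    if (!is.null(sn) && nrow(sn) > 0L) {
      cov <- outer(start_t, sn$tx_pos, function(s, p) p >= s & p < s + rl)
      hit <- which(cov, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        ord <- order(hit[, 1L], hit[, 2L])
        ridx <- hit[ord, 1L]
        sidx <- hit[ord, 2L]
        base <- ifelse(origin[ridx] == "BSB", sn$bsb_hap[sidx],
                       sn$tc_hap[sidx])
        err <- runif(length(base)) < config$error_rate
        if (any(err)) {
          base[err] <- other_base(base[err],
                                  sample(1:3, sum(err), replace = TRUE))
        }
        calls_l[[pid]] <- tibble(
          read_id = read_id[ridx], pair_id = pid,
          pos = sn$bsb_pos[sidx], base = base
        )
      }
    }
  }

  empty_reads <- tibble(
    read_id = character(), pair_id = character(), hybrid = character(),
    tissue = character(), replicate = integer(), true_origin = character(),
    start = integer(), end = integer()
  )
  empty_calls <- tibble(read_id = character(), pair_id = character(),
                        pos = integer(), base = character())
  reads <- bind_rows(c(list(empty_reads), unname(reads_l)))
  calls <- bind_rows(c(list(empty_calls), unname(calls_l)))

  # planted outlier SNP cells: duplicate the covering reads of one
  # random library cell to `outlier_factor`-fold inflation
  outliers <- NULL
  if (config$outlier_snp_rate > 0 && nrow(cohort$snps) > 0 &&
      nrow(calls) > 0) {
    pick <- runif(nrow(cohort$snps)) < config$outlier_snp_rate
    out_snps <- cohort$snps[pick, c("pair_id", "bsb_pos")]
    if (nrow(out_snps) > 0) {
      cell <- libs[sample.int(nrow(libs), nrow(out_snps), replace = TRUE), ]
      out_snps <- bind_cols(out_snps, cell)
      planted_ok <- logical(nrow(out_snps))
      extra_reads <- list(); extra_calls <- list()
      read_meta <- reads |>
        select("read_id", "hybrid", "tissue", "replicate")
      for (r in seq_len(nrow(out_snps))) {
        o <- out_snps[r, ]
        cover <- calls |>
          filter(.data$pair_id == o$pair_id, .data$pos == o$bsb_pos) |>
          inner_join(read_meta, by = "read_id") |>
          filter(.data$hybrid == o$hybrid, .data$tissue == o$tissue,
                 .data$replicate == o$replicate)
        if (nrow(cover) == 0L) next
        planted_ok[r] <- TRUE
        src <- reads |> filter(.data$read_id %in% cover$read_id)
        times <- as.integer(round(config$outlier_factor)) - 1L
        for (tcopy in seq_len(times)) {
          suffix <- sprintf("_out%d_%d", r, tcopy)
          dup <- src |> mutate(read_id = paste0(.data$read_id, suffix))
          # artifact reads support only the inflated locus
          dupc <- calls |>
            filter(.data$read_id %in% src$read_id,
                   .data$pos == o$bsb_pos) |>
            mutate(read_id = paste0(.data$read_id, suffix))
          extra_reads[[length(extra_reads) + 1L]] <- dup
          extra_calls[[length(extra_calls) + 1L]] <- dupc
        }
      }
      reads <- bind_rows(reads, bind_rows(extra_reads))
      calls <- bind_rows(calls, bind_rows(extra_calls))
      outliers <- out_snps[planted_ok, , drop = FALSE]
    }
  }

  cohort$short_reads <- reads
  cohort$short_read_calls <- calls
  cohort$truth$outliers <- outliers
  cohort
}

sim_long_reads <- function(cohort) {
  config <- cohort$config
  set.seed(child_seed(config$seed, 2L))
  chains <- cohort$chains
  chain_tbl <- chains |>
    group_by(.data$pair_id, .data$homoeolog, .data$chain_id) |>
    summarise(tx_len = sum(.data$end - .data$start), .groups = "drop")
  snps_by_pair <- split(cohort$snps, cohort$snps$pair_id)
  chains_by <- split(chains, paste(chains$pair_id, chains$homoeolog,
                                   sep = "|"))

  # SNP columns inside each chain's exons, precomputed once per chain;
  # positions tested in the chain's own subgenome coordinates, calls
  # keyed by the pair (BSB) frame
  chain_snps <- new.env(parent = emptyenv())
  chain_info <- function(pid, homoeolog, cid) {
    key <- paste(pid, homoeolog, cid, sep = "|")
    got <- chain_snps[[key]]
    if (!is.null(got)) return(got)
    cm <- chains_by[[paste(pid, homoeolog, sep = "|")]]
    cm <- cm[cm$chain_id == cid, ]
    sn <- snps_by_pair[[pid]]
    inside <- integer()
    if (!is.null(sn) && nrow(sn) > 0L) {
      own_pos <- if (homoeolog == "BSB") sn$bsb_pos else sn$tc_pos
      inside <- which(purrr::map_lgl(own_pos, function(p) {
        any(cm$start <= p & p < cm$end)
      }))
    }
    got <- list(len = sum(cm$end - cm$start), snp_idx = inside)
    chain_snps[[key]] <- got
    got
  }

  reads_l <- list(); calls_l <- list()
  for (hyb in c("TBF3", "BTF3")) {
    for (pid in cohort$pairs$pair_id) {
      n <- rpois(1L, config$long_read_depth)
      if (n == 0L) next
      origin <- sample(c("BSB", "TC"), n, replace = TRUE)
      ids <- sprintf("%s_%s_lr%04d", hyb, pid, seq_len(n))
      cid <- character(n)
      for (hom in c("BSB", "TC")) {
        sel <- origin == hom
        if (!any(sel)) next
        pool <- unique(chains_by[[paste(pid, hom, sep = "|")]]$chain_id)
        cid[sel] <- sample(pool, sum(sel), replace = TRUE)
      }
      info <- purrr::map2(origin, cid, ~ chain_info(pid, .x, .y))
      len <- purrr::map_int(info, "len")
      intact <- runif(n) < config$fl_rate
      flags <- matrix(TRUE, n, 3L)
      drop_flag <- sample.int(3L, n, replace = TRUE)
      flags[cbind(which(!intact), drop_flag[!intact])] <- FALSE
      reads_l[[length(reads_l) + 1L]] <- tibble(
        read_id = ids, hybrid = hyb, pair_id = pid,
        true_origin = origin, chain_id = cid, length = len,
        has_5prime_primer = flags[, 1L], has_3prime_primer = flags[, 2L],
        has_polyA = flags[, 3L],
        fl_truth = len > 300 & intact
      )
      sn <- snps_by_pair[[pid]]
      if (!is.null(sn) && nrow(sn) > 0L) {
        n_hit <- purrr::map_int(info, ~ length(.x$snp_idx))
        if (sum(n_hit) > 0L) {
          ridx <- rep(seq_len(n), n_hit)
          sidx <- unlist(purrr::map(info, "snp_idx"))
          base <- ifelse(origin[ridx] == "BSB", sn$bsb_hap[sidx],
                         sn$tc_hap[sidx])
          err <- runif(length(base)) < config$error_rate
          if (any(err)) {
            base[err] <- other_base(base[err],
                                    sample(1:3, sum(err), replace = TRUE))
          }
          calls_l[[length(calls_l) + 1L]] <- tibble(
            read_id = ids[ridx], pair_id = pid,
            pos = sn$bsb_pos[sidx], base = base
          )
        }
      }
    }
  }
  cohort$long_reads <- bind_rows(c(list(tibble(
    read_id = character(), hybrid = character(),
    pair_id = character(), true_origin = character(),
    chain_id = character(), length = integer(),
    has_5prime_primer = logical(), has_3prime_primer = logical(),
    has_polyA = logical(), fl_truth = logical())), unname(reads_l)))
  cohort$long_read_calls <- bind_rows(c(list(tibble(
    read_id = character(), pair_id = character(),
    pos = integer(), base = character())), unname(calls_l)))
  cohort
}

#' Simulate negative-binomial count matrices
#'
#' Draws a gene-by-sample count matrix with per-group means and a common
#' dispersion, for calibrating and power-testing the exact test.
#'
#' @param n_genes number of genes.
#' @param mu baseline mean count per sample.
#' @param phi common NB dispersion (`0` gives Poisson).
#' @param n_per_group replicates per group (two groups).
#' @param log2fc per-gene log2 fold change of group B over group A;
#'   recycled.
#' @return list with integer `counts` (genes x 2*n_per_group), `group`
#'   factor and the `log2fc` vector used.
#' @export
simulate_nb_counts <- function(n_genes, mu = 200, phi = 0.1,
                               n_per_group = 3L, log2fc = 0) {
  log2fc <- rep_len(log2fc, n_genes)
  mu_a <- rep(mu, n_genes)
  mu_b <- mu * 2^log2fc
  draw <- function(m, n) {
    if (phi == 0) {
      matrix(rpois(n_genes * n, rep(m, n)), nrow = n_genes)
    } else {
      matrix(rnbinom(n_genes * n, size = 1 / phi, mu = rep(m, n)),
             nrow = n_genes)
    }
  }
  counts <- cbind(draw(mu_a, n_per_group), draw(mu_b, n_per_group))
  colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                        paste0("B", seq_len(n_per_group)))
  list(counts = counts,
       group = factor(rep(c("A", "B"), each = n_per_group)),
       log2fc = log2fc)
}
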