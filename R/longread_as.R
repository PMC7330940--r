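#' Classify long reads as full-length
#'
#' A long read is full-length when it exceeds the minimum length
#' (strictly greater than `min_length`) and carries a 5' primer, a 3'
#' primer and a poly(A) tail.
#'
#' @param reads tibble with columns `length`, `has_5prime_primer`,
#'   `has_3prime_primer`, `has_polyA` (plus anything else, passed
#'   through).
#' @param min_length minimum read length in bp; the bound is strict.
#' @return the input tibble with a logical `full_length` column added.
#' @examples
#' classify_full_length(tibble::tibble(
#'   read_id = "r1", length = 301,
#'   has_5prime_primer = TRUE, has_3prime_primer = TRUE, has_polyA = TRUE
#' ))
#' @export
classify_full_length <- function(reads, min_length = 300) {
  need <- c("length", "has_5prime_primer", "has_3prime_primer", "has_polyA")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    stop_input(paste("classify_full_length: missing columns:",
                     paste(miss, collapse = ", ")))
  }
  reads |>
    mutate(full_length = .data$length > min_length &
             .data$has_5prime_primer & .data$has_3prime_primer &
             .data$has_polyA)
}

#' Assign long reads to a subgenome by SNP concordance
#'
#' A long read is assigned to the parent whose alleles it matches at a
#' fraction of at least `threshold` (inclusive) of the species-specific
#' SNPs it covers; otherwise it is left unassigned. Reads covering no
#' SNP are unassigned with reason `"no_snps"`.
#'
#' @param read_calls tibble of per-read base calls with columns
#'   `read_id`, `pair_id`, `pos` (BSB gene coordinate of the SNP
#'   column), `base`.
#' @param snps species-specific SNP table from [call_species_snps()]
#'   (columns `pair_id`, `bsb_pos`, `bsb_alleles`, `tc_alleles`;
#'   allele sets as `"A"` or `"A/T"` strings).
#' @param threshold concordance fraction required for assignment
#'   (inclusive).
#' @param read_ids optional character vector of all read ids, so reads
#'   with no SNP calls still appear in the output.
#' @return tibble with one row per read: `read_id`, `covered`,
#'   `matches_bsb`, `matches_tc`, `call` (`"BSB"`, `"TC"` or
#'   `"unassigned"`) and `reason`.
#' @export
assign_long_read <- function(read_calls, snps, threshold = 0.85,
                             read_ids = NULL) {
  tallies <- tally_snp_matches(read_calls, snps)
  out <- tallies |>
    mutate(
      frac_bsb = ifelse(.data$covered > 0, .data$matches_bsb / .data$covered, 0),
      frac_tc = ifelse(.data$covered > 0, .data$matches_tc / .data$covered, 0),
      call = case_when(
        .data$covered == 0 ~ "unassigned",
        .data$frac_bsb >= threshold ~ "BSB",
        .data$frac_tc >= threshold ~ "TC",
        TRUE ~ "unassigned"
      ),
      reason = case_when(
        .data$covered == 0 ~ "no_snps",
        .data$call == "unassigned" ~ "below_threshold",
        TRUE ~ NA_character_
      )
    ) |>
    select("read_id", "covered", "matches_bsb", "matches_tc", "call", "reason")
  if (!is.null(read_ids)) {
    absent <- setdiff(read_ids, out$read_id)
    if (length(absent) > 0) {
      out <- bind_rows(out, tibble(
        read_id = absent, covered = 0L, matches_bsb = 0L, matches_tc = 0L,
        call = "unassigned", reason = "no_snps"
      ))
    }
    out <- out[match(read_ids, out$read_id), ]
  }
  out
}

# Shared by short- and long-read assignment: per-read counts of calls
# matching each parent's allele set at covered species-specific SNPs.
tally_snp_matches <- function(read_calls, snps, strict = FALSE) {
  stopifnot(all(c("read_id", "pair_id", "pos", "base") %in% names(read_calls)))
  snp_key <- snps |>
    transmute(.data$pair_id, pos = .data$bsb_pos,
              bsb_alleles = .data$bsb_alleles, tc_alleles = .data$tc_alleles)
  joined <- read_calls |>
    left_join(snp_key, by = c("pair_id", "pos"))
  unknown <- sum(is.na(joined$bsb_alleles))
  if (unknown > 0 && strict) {
    stop_input(sprintf(
      "%d read calls at positions absent from the SNP table", unknown),
      class = "homoeosplice_integrity_error")
  }
  joined <- joined |> filter(!is.na(.data$bsb_alleles))
  out <- joined |>
    mutate(
      in_bsb = allele_set_has(.data$bsb_alleles, .data$base),
      in_tc = allele_set_has(.data$tc_alleles, .data$base)
    ) |>
    group_by(.data$read_id) |>
    summarise(
      covered = dplyr::n(),
      matches_bsb = sum(.data$in_bsb),
      matches_tc = sum(.data$in_tc),
      .groups = "drop"
    )
  attr(out, "n_unknown_positions") <- unknown
  out
}

# vectorised membership in "A/T"-style allele sets
allele_set_has <- function(sets, base) {
  stringr::str_detect(sets, stringr::fixed(base))
}

# ---- AS event classification ----------------------------------------------

#' Classify alternative-splicing events from exon chains
#'
#' Compares every unordered pair of isoform exon chains within a gene and
#' classifies their structural differences into the named event types:
#'
#' * `SE` (skipped exon): an exon of one chain is absent from the other,
#'   whose intron spans the exon with both outer splice sites shared.
#' * `RI` (retained intron): an intron of one chain lies inside a single
#'   exon of the other with outer exon edges shared.
#' * `A5SS` / `A3SS`: two introns share one boundary and differ at the
#'   donor (5') or acceptor (3') side; strand-aware, and the alternative
#'   boundary exons must share their far edge.
#' * `MXE` (mutually exclusive exons): two internal exons, each exclusive
#'   to one chain, non-overlapping, flanked by shared splice sites.
#' * `AP` (alternative position): the chains share every intron and
#'   differ only at transcript-terminal exon boundaries.
#' * `OTHER`: any chain pair that differs but matches none of the named
#'   patterns.
#'
#' Events are deduplicated by `(gene, type, anchor coordinates)` across
#' chain pairs; supporting chain ids are aggregated.
#'
#' @param chains tibble of exon intervals with columns `gene_id`,
#'   `chain_id`, `start`, `end` (0-based half-open) and optionally
#'   `strand` (`"+"`/`"-"`, default `"+"`) and `homoeolog` (kept as a
#'   grouping column).
#' @return tibble of events: `gene_id` (and `homoeolog` if supplied),
#'   `type`, `anchor` (canonical coordinate string), `coords` (list of
#'   integer anchor coordinates), `chains` (supporting chain ids,
#'   comma-separated) and `n_support` (number of supporting chain pairs).
#' @examples
#' ch <- tibble::tibble(
#'   gene_id = "g1", chain_id = rep(c("ref", "alt"), c(3, 2)),
#'   start = c(0, 200, 400, 0, 400), end = c(100, 300, 500, 100, 500)
#' )
#' classify_as_events(ch) # one SE anchored at 200-300
#' @export
classify_as_events <- function(chains) {
  need <- c("gene_id", "chain_id", "start", "end")
  miss <- setdiff(need, names(chains))
  if (length(miss) > 0) {
    stop_input(paste("classify_as_events: missing columns:",
                     paste(miss, collapse = ", ")))
  }
  has_hom <- "homoeolog" %in% names(chains)
  if (!"strand" %in% names(chains)) chains$strand <- "+"
  grp_cols <- c("gene_id", if (has_hom) "homoeolog")
  groups <- chains |> group_by(across(all_of(grp_cols))) |> group_split()
  ev <- purrr::map(groups, function(g) {
    strand <- g$strand[[1L]]
    mats <- split(g[c("start", "end")], g$chain_id)
    mats <- lapply(mats, function(d) {
      validate_chain(as_exon_matrix(d$start, d$end),
                     label = paste0(g$gene_id[[1L]], " chain"))
    })
    ids <- names(mats)
    if (length(ids) < 2L) return(NULL)
    rows <- list()
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq.int(i + 1L, length(ids))) {
        evs <- compare_chain_pair(mats[[i]], mats[[j]], strand)
        for (e in evs) {
          rows[[length(rows) + 1L]] <- tibble(
            gene_id = g$gene_id[[1L]],
            homoeolog = if (has_hom) g$homoeolog[[1L]] else NA_character_,
            type = e$type,
            anchor = paste0(e$type, ":", paste(e$coords, collapse = "-")),
            coords = list(as.integer(e$coords)),
            pair = paste(ids[[i]], ids[[j]], sep = ",")
          )
        }
      }
    }
    if (length(rows) == 0) return(NULL)
    bind_rows(rows)
  })
  ev <- bind_rows(ev)
  if (nrow(ev) == 0) {
    out <- tibble(gene_id = character(), type = character(),
                  anchor = character(), coords = list(),
                  chains = character(), n_support = integer())
    if (has_hom) out <- mutate(out, homoeolog = character(), .after = "gene_id")
    return(out)
  }
  out <- ev |>
    group_by(across(all_of(c(grp_cols, "type", "anchor")))) |>
    summarise(
      coords = list(.data$coords[[1L]]),
      chains = paste(sort(unique(unlist(strsplit(.data$pair, ",")))),
                     collapse = ","),
      n_support = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(across(all_of(c(grp_cols, "type", "anchor"))))
  if (!has_hom) out$homoeolog <- NULL
  out
}

# All named events between two chains; OTHER iff no named event fires and
# the chains differ. Returns a list of list(type, coords).
compare_chain_pair <- function(A, B, strand = "+") {
  if (identical(unname(A), unname(B))) return(list())
  events <- list()
  add <- function(type, coords) {
    events[[length(events) + 1L]] <<- list(type = type,
                                           coords = as.integer(coords))
  }
  intrA <- chain_introns(A)
  intrB <- chain_introns(B)
  keyA <- interval_key(intrA)
  keyB <- interval_key(intrB)
  exon_keyA <- interval_key(A)
  exon_keyB <- interval_key(B)

  # SE: internal exon of one chain spanned by a single intron of the other
  find_se <- function(X, intron_keys_other) {
    n <- nrow(X)
    if (n >= 3L) {
      for (k in 2:(n - 1L)) {
        span <- paste(X[k - 1L, 2L], X[k + 1L, 1L], sep = "-")
        if (span %in% intron_keys_other) add("SE", X[k, ])
      }
    }
  }
  find_se(A, keyB)
  find_se(B, keyA)

  # RI: intron of one chain inside a single exon of the other, outer
  # exon edges shared
  find_ri <- function(X, intrX, exon_keys_other) {
    if (nrow(intrX) == 0L) return(invisible())
    for (k in seq_len(nrow(intrX))) {
      outer <- paste(X[k, 1L], X[k + 1L, 2L], sep = "-")
      if (outer %in% exon_keys_other) add("RI", intrX[k, ])
    }
  }
  find_ri(A, intrA, exon_keyB)
  find_ri(B, intrB, exon_keyA)

  # A5SS / A3SS: introns sharing one boundary; the alternative-boundary
  # exons must share their far edge (rules out skipped-exon artefacts)
  if (nrow(intrA) > 0L && nrow(intrB) > 0L) {
    exon_start_of_end <- function(X, e) {
      hit <- which(X[, 2L] == e)
      if (length(hit) == 1L) X[hit, 1L] else NA_integer_
    }
    exon_end_of_start <- function(X, s) {
      hit <- which(X[, 1L] == s)
      if (length(hit) == 1L) X[hit, 2L] else NA_integer_
    }
    for (a in seq_len(nrow(intrA))) {
      for (b in seq_len(nrow(intrB))) {
        s1 <- intrA[a, 1L]; e1 <- intrA[a, 2L]
        s2 <- intrB[b, 1L]; e2 <- intrB[b, 2L]
        if (e1 == e2 && s1 != s2) {
          # boundary difference at the intron start (upstream exon end)
          fa <- exon_start_of_end(A, s1)
          fb <- exon_start_of_end(B, s2)
          if (!is.na(fa) && !is.na(fb) && fa == fb) {
            type <- if (strand == "+") "A5SS" else "A3SS"
            add(type, c(e1, sort(c(s1, s2))))
          }
        } else if (s1 == s2 && e1 != e2) {
          # boundary difference at the intron end (downstream exon start)
          fa <- exon_end_of_start(A, e1)
          fb <- exon_end_of_start(B, e2)
          if (!is.na(fa) && !is.na(fb) && fa == fb) {
            type <- if (strand == "+") "A3SS" else "A5SS"
            add(type, c(s1, sort(c(e1, e2))))
          }
        }
      }
    }
  }

  # MXE: internal exons exclusive to each chain, disjoint, shared flanks
  nA <- nrow(A); nB <- nrow(B)
  if (nA >= 3L && nB >= 3L) {
    for (k in 2:(nA - 1L)) {
      if (exon_keyA[k] %in% exon_keyB) next
      for (l in 2:(nB - 1L)) {
        if (exon_keyB[l] %in% exon_keyA) next
        flanks_shared <- A[k - 1L, 2L] == B[l - 1L, 2L] &&
          A[k + 1L, 1L] == B[l + 1L, 1L]
        disjoint <- A[k, 2L] <= B[l, 1L] || B[l, 2L] <= A[k, 1L]
        if (flanks_shared && disjoint) {
          x <- A[k, ]; y <- B[l, ]
          if (y[1L] < x[1L]) { tmp <- x; x <- y; y <- tmp }
          add("MXE", c(x, y))
        }
      }
    }
  }

  # AP: identical intron sets, terminal boundaries differ
  if (nrow(intrA) == nrow(intrB) &&
      (nrow(intrA) == 0L || all(intrA == intrB))) {
    add("AP", c(sort(c(A[1L, 1L], B[1L, 1L])), sort(c(A[nA, 2L], B[nB, 2L]))))
  }

  if (length(events) == 0L) {
    d <- coverage_difference_hull(A, B)
    add("OTHER", d)
  }
  # within-pair dedup (symmetric A5/A3 scans can find the same pair twice)
  keys <- vapply(events, function(e) paste(e$type, paste(e$coords, collapse = ",")),
                 character(1))
  events[!duplicated(keys)]
}

# [lo, hi) hull of bases covered by exactly one of the two chains
coverage_difference_hull <- function(A, B) {
  bounds <- sort(unique(c(A, B)))
  lo <- NA_integer_; hi <- NA_integer_
  covered <- function(X, s, e) {
    any(X[, 1L] <= s & e <= X[, 2L])
  }
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    inA <- covered(A, s, e); inB <- covered(B, s, e)
    if (xor(inA, inB)) {
      if (is.na(lo)) lo <- s
      hi <- e
    }
  }
  if (is.na(lo)) c(min(A[, 1L], B[, 1L]), max(A[, 2L], B[, 2L])) else c(lo, hi)
}

#' Match AS events between homoeologs through a coordinate map
#'
#' An event found in the BSB homoeolog matches one in the TC homoeolog of
#' the same ortholog pair when both have the same type and every anchor
#' coordinate maps exactly through the pairwise coordinate map.
#'
#' @param events_bsb,events_tc event tables from [classify_as_events()],
#'   with `gene_id` naming the BSB and TC gene respectively.
#' @param pairs ortholog pair table (`pair_id`, `bsb_gene`, `tc_gene`).
#' @param coord_maps coordinate map table (`pair_id`, `bsb_pos`,
#'   `tc_pos`, `indel`).
#' @return tibble of matched events: `pair_id`, `type`, `anchor_bsb`,
#'   `anchor_tc`. Unmapped anchors leave events unmatched; their count is
#'   in attribute `n_unmapped`.
#' @export
shared_as_across_homoeologs <- function(events_bsb, events_tc, pairs,
                                        coord_maps) {
  if (nrow(events_bsb) == 0 || nrow(events_tc) == 0) {
    return(tibble(pair_id = character(), type = character(),
                  anchor_bsb = character(), anchor_tc = character()))
  }
  maps <- coord_maps |> filter(!.data$indel)
  ev_b <- events_bsb |>
    inner_join(pairs, by = c(gene_id = "bsb_gene"))
  n_unmapped <- 0L
  mapped <- purrr::pmap(
    list(ev_b$pair_id, ev_b$type, ev_b$coords, ev_b$anchor),
    function(pid, type, coords, anchor) {
      m <- maps |> filter(.data$pair_id == pid)
      tc <- map_boundary(coords, m$bsb_pos, m$tc_pos)
      if (anyNA(tc)) {
        n_unmapped <<- n_unmapped + 1L
        return(NULL)
      }
      tibble(pair_id = pid, type = type, anchor_bsb = anchor,
             anchor_tc = paste0(type, ":", paste(tc, collapse = "-")))
    }
  )
  mapped <- bind_rows(mapped)
  if (nrow(mapped) == 0) {
    out <- tibble(pair_id = character(), type = character(),
                  anchor_bsb = character(), anchor_tc = character())
    attr(out, "n_unmapped") <- n_unmapped
    return(out)
  }
  ev_t <- events_tc |>
    inner_join(pairs, by = c(gene_id = "tc_gene")) |>
    transmute(.data$pair_id, .data$type, anchor_tc = .data$anchor)
  out <- mapped |>
    inner_join(ev_t, by = c("pair_id", "type", "anchor_tc"))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# Map boundary coordinates through aligned columns. A boundary c maps via
# column c when present, else via column c-1 shifted by one (half-open
# interval ends sit one past the last aligned base).
map_boundary <- function(coords, from, to) {
  idx <- match(coords, from)
  res <- to[idx]
  missing <- is.na(res)
  if (any(missing)) {
    idx2 <- match(coords[missing] - 1L, from)
    res[missing] <- to[idx2] + 1L
  }
  as.integer(res)
}

#' Genes with many alternative-splicing events
#'
#' Counts deduplicated events per gene (within any `homoeolog`/`tissue`
#' grouping columns present) and keeps genes at or above `min_events`.
#'
#' @param events event table from [classify_as_events()].
#' @param min_events inclusive threshold on the per-gene event count.
#' @return tibble of `gene_id` (plus grouping columns) and `n_events`.
#' @seealso [shared_high_as_genes()] for the cross-tissue intersection.
#' @export
high_as_genes <- function(events, min_events = 5) {
  grp <- intersect(c("gene_id", "homoeolog", "tissue"), names(events))
  events |>
    group_by(across(all_of(grp))) |>
    summarise(n_events = dplyr::n(), .groups = "drop") |>
    filter(.data$n_events >= min_events) |>
    arrange(across(all_of(grp)))
}

#' Genes with high AS in every tissue
#'
#' @param gene_sets list of character vectors of gene ids (one per
#'   tissue).
#' @return sorted character vector of genes present in every set.
#' @export
shared_high_as_genes <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  sort(Reduce(intersect, gene_sets))
}
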