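# Independent brute-force implementations used as oracles. These are
# deliberately written in a different style from the package code
# (plain vectors, explicit scans) so they can disagree if either side
# misimplements a rule.

# ---- AS event rules, naive re-implementation ------------------------------

oracle_classify_pair <- function(A, B, strand = "+") {
  sA <- A[, 1]; eA <- A[, 2]; sB <- B[, 1]; eB <- B[, 2]
  nA <- length(sA); nB <- length(sB)
  if (nA == nB && all(sA == sB) && all(eA == eB)) return(character())
  iA <- if (nA > 1) cbind(eA[-nA], sA[-1]) else matrix(0L, 0, 2)
  iB <- if (nB > 1) cbind(eB[-nB], sB[-1]) else matrix(0L, 0, 2)
  out <- character()
  rec <- function(type, coords) {
    out <<- c(out, paste0(type, ":", paste(coords, collapse = "-")))
  }
  has_intron <- function(I, s, e) nrow(I) > 0 && any(I[, 1] == s & I[, 2] == e)
  has_exon <- function(S, E, s, e) any(S == s & E == e)

  if (nA >= 3) for (k in 2:(nA - 1)) {
    if (has_intron(iB, eA[k - 1], sA[k + 1])) rec("SE", c(sA[k], eA[k]))
  }
  if (nB >= 3) for (k in 2:(nB - 1)) {
    if (has_intron(iA, eB[k - 1], sB[k + 1])) rec("SE", c(sB[k], eB[k]))
  }

  if (nA > 1) for (k in 1:(nA - 1)) {
    if (has_exon(sB, eB, sA[k], eA[k + 1])) rec("RI", c(eA[k], sA[k + 1]))
  }
  if (nB > 1) for (k in 1:(nB - 1)) {
    if (has_exon(sA, eA, sB[k], eB[k + 1])) rec("RI", c(eB[k], sB[k + 1]))
  }

  if (nrow(iA) > 0 && nrow(iB) > 0) {
    for (a in seq_len(nrow(iA))) for (b in seq_len(nrow(iB))) {
      s1 <- iA[a, 1]; e1 <- iA[a, 2]; s2 <- iB[b, 1]; e2 <- iB[b, 2]
      if (e1 == e2 && s1 != s2) {
        # upstream-exon ends differ; their starts must agree
        ua <- sA[which(eA == s1)]; ub <- sB[which(eB == s2)]
        if (length(ua) == 1 && length(ub) == 1 && ua == ub) {
          rec(if (strand == "+") "A5SS" else "A3SS",
              c(e1, min(s1, s2), max(s1, s2)))
        }
      }
      if (s1 == s2 && e1 != e2) {
        da <- eA[which(sA == e1)]; db <- eB[which(sB == e2)]
        if (length(da) == 1 && length(db) == 1 && da == db) {
          rec(if (strand == "+") "A3SS" else "A5SS",
              c(s1, min(e1, e2), max(e1, e2)))
        }
      }
    }
  }

  if (nA >= 3 && nB >= 3) {
    for (k in 2:(nA - 1)) for (l in 2:(nB - 1)) {
      x_in_B <- has_exon(sB, eB, sA[k], eA[k])
      y_in_A <- has_exon(sA, eA, sB[l], eB[l])
      if (x_in_B || y_in_A) next
      if (eA[k - 1] != eB[l - 1] || sA[k + 1] != sB[l + 1]) next
      if (!(eA[k] <= sB[l] || eB[l] <= sA[k])) next
      if (sA[k] <= sB[l]) {
        rec("MXE", c(sA[k], eA[k], sB[l], eB[l]))
      } else {
        rec("MXE", c(sB[l], eB[l], sA[k], eA[k]))
      }
    }
  }

  if (nrow(iA) == nrow(iB) && (nrow(iA) == 0 || all(iA == iB))) {
    rec("AP", c(min(sA[1], sB[1]), max(sA[1], sB[1]),
                min(eA[nA], eB[nB]), max(eA[nA], eB[nB])))
  }

  if (length(out) == 0) {
    posA <- unlist(mapply(function(s, e) seq.int(s, e - 1), sA, eA,
                          SIMPLIFY = FALSE))
    posB <- unlist(mapply(function(s, e) seq.int(s, e - 1), sB, eB,
                          SIMPLIFY = FALSE))
    d <- c(setdiff(posA, posB), setdiff(posB, posA))
    rec("OTHER", c(min(d), max(d) + 1L))
  }
  unique(out)
}

# all unordered chain pairs of one gene, deduplicated anchor keys
oracle_classify <- function(chain_list, strand = "+") {
  keys <- character()
  n <- length(chain_list)
  if (n < 2) return(keys)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    keys <- c(keys, oracle_classify_pair(chain_list[[i]], chain_list[[j]],
                                         strand))
  }
  sort(unique(keys))
}

# random exon chain on a coarse grid (shared boundaries arise often)
random_chain <- function(max_exons = 5) {
  n <- sample.int(max_exons, 1)
  pos <- 0L
  m <- matrix(0L, n, 2)
  for (k in seq_len(n)) {
    pos <- pos + sample.int(3L, 1) * 10L   # gap (intron or leading)
    len <- sample.int(3L, 1) * 10L
    m[k, ] <- c(pos, pos + len)
    pos <- pos + len
  }
  m
}

# mutate a chain into a related isoform (drop/merge/shift/extend)
mutate_chain <- function(m) {
  pick <- function(v) v[sample.int(length(v), 1L)]
  n <- nrow(m)
  op <- sample(c("drop", "merge", "shift_start", "shift_end",
                 "trim_first", "extend_last"), 1)
  out <- m
  if (op == "drop" && n >= 3) {
    out <- m[-pick(2:(n - 1)), , drop = FALSE]
  } else if (op == "merge" && n >= 2) {
    k <- pick(seq_len(n - 1))
    out[k, 2] <- out[k + 1, 2]
    out <- out[-(k + 1), , drop = FALSE]
  } else if (op == "shift_start" && n >= 2) {
    k <- pick(2:n)
    gap <- out[k, 1] - out[k - 1, 2]
    if (gap > 10) out[k, 1] <- out[k, 1] - 10L
  } else if (op == "shift_end" && n >= 2) {
    k <- pick(seq_len(n - 1))
    gap <- out[k + 1, 1] - out[k, 2]
    if (gap > 10) out[k, 2] <- out[k, 2] + 10L
  } else if (op == "trim_first") {
    if (out[1, 2] - out[1, 1] > 10) out[1, 1] <- out[1, 1] + 10L
  } else if (op == "extend_last") {
    out[n, 2] <- out[n, 2] + 10L
  }
  out
}

chains_to_tibble <- function(chain_list, gene_id = "g", strand = "+") {
  dplyr::bind_rows(lapply(seq_along(chain_list), function(i) {
    tibble::tibble(gene_id = gene_id, chain_id = sprintf("c%d", i),
                   strand = strand,
                   start = chain_list[[i]][, 1], end = chain_list[[i]][, 2])
  }))
}

event_keys <- function(events) sort(unique(events$anchor))

# ---- RBH exhaustive oracle ------------------------------------------------

oracle_rbh <- function(hits, max_evalue = 1e-5) {
  h <- hits[hits$evalue_like <= max_evalue, , drop = FALSE]
  pairs <- character()
  for (q in unique(h$query)) {
    hq <- h[h$query == q, ]
    best <- hq[hq$score == max(hq$score), ]
    if (nrow(best) != 1) next
    s <- best$subject
    hs <- h[h$subject == s, ]
    bs <- hs[hs$score == max(hs$score), ]
    if (nrow(bs) != 1) next
    if (bs$query == q) pairs <- c(pairs, paste(q, s))
  }
  sort(pairs)
}

# ---- conditional NB exact test by explicit convolution --------------------

# enumerate all per-replicate count vectors with the given totals,
# conditioning on the pooled sum (tiny totals only)
oracle_nb_exact <- function(a, b, phi) {
  na <- length(a); nb <- length(b)
  total <- sum(a) + sum(b)
  size1 <- if (phi > 0) 1 / phi else Inf
  mu <- total / (na + nb)
  dens <- function(k) {
    if (is.finite(size1)) dnbinom(k, size = size1, mu = mu) else dpois(k, mu)
  }
  # probability that n iid counts sum to s, by recursive convolution
  sum_pmf <- function(n, s) {
    if (n == 1) return(dens(s))
    tot <- 0
    for (k in 0:s) tot <- tot + dens(k) * sum_pmf(n - 1, s - k)
    tot
  }
  split_prob <- vapply(0:total, function(ya) {
    sum_pmf(na, ya) * sum_pmf(nb, total - ya)
  }, numeric(1))
  split_prob <- split_prob / sum(split_prob)
  p_obs <- split_prob[sum(a) + 1]
  min(1, sum(split_prob[split_prob <= p_obs * (1 + 1e-10)]))
}
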