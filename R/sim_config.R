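#' Configuration for the synthetic reciprocal-cross cohort
#'
#' Builds a validated configuration describing the simulated study: two
#' diverged parental gene sets with one-to-one orthologs, two reciprocal
#' hybrids (`TBF3`, maternal TC; `BTF3`, maternal BSB), three tissues with
#' three biological replicates each, short reads with planted homoeolog
#' bias and between-hybrid differential expression, long reads with
#' full-length structure flags and planted alternative-splicing isoforms,
#' parental pileups for SNP discovery, and planted per-replicate outlier
#' SNP counts.
#'
#' Defaults describe the package's reference study conditions: ~9 exons
#' per gene and kilobase-scale CDS (as in the diverged cyprinid parents
#' the design emulates), a 2% fixed inter-species substitution rate in
#' exons, three tissues x three replicates per hybrid, 90% of long reads
#' full length.
#'
#' @param n_genes number of ortholog pairs to simulate.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len integer ranges (bp) for exon and intron
#'   lengths.
#' @param snp_rate per-exonic-bp probability of a fixed inter-species
#'   difference.
#' @param het_rate fraction of SNP loci where the BSB parent is
#'   heterozygous (second allele still disjoint from TC).
#' @param shared_poly_rate per-exonic-bp rate of non-diagnostic
#'   polymorphic columns (parents share an allele); these must be
#'   rejected by SNP discovery.
#' @param depth mean short reads per gene per replicate (Poisson).
#' @param read_len short-read length in transcript bp; `Inf` makes every
#'   read span the whole transcript.
#' @param tissues character vector of tissue labels.
#' @param n_replicates biological replicates per hybrid per tissue.
#' @param bias_frac fraction of genes with planted homoeolog bias.
#' @param bias_log2 planted log2(BSB/TC) ratio for biased genes.
#' @param de_frac fraction of genes differentially expressed between the
#'   hybrids (both homoeologs move together).
#' @param de_log2 planted log2 fold change (TBF3 over BTF3) for DE genes.
#' @param as_events_per_gene named integer vector of planted AS event
#'   counts per AS gene; names from `SE, RI, A5SS, A3SS, MXE, AP`.
#' @param as_gene_frac fraction of genes receiving the planted AS events
#'   (genes with enough exons are chosen).
#' @param as_shared_frac fraction of AS genes whose events are planted in
#'   both homoeologs (shared through the coordinate map).
#' @param error_rate per-base-call error rate for simulated reads.
#' @param outlier_snp_rate fraction of species-specific SNPs given an
#'   inflated read count in one random replicate.
#' @param outlier_factor fold inflation applied to outlier SNP cells.
#' @param long_read_depth mean long reads per gene per hybrid.
#' @param fl_rate probability a long read carries both primers and a
#'   poly(A) tail (full-length structure).
#' @param parent_depth mean parental pileup coverage per replicate.
#' @param intron_indel_rate fraction of introns lengthened on the TC side
#'   (creates indel columns in the coordinate map).
#' @param intron_indel_len integer range of inserted intron length (bp).
#' @param mito_reads mitochondrial read count per hybrid.
#' @param seed integer seed fixing every downstream draw.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' cfg$snp_rate
#' @export
sim_config <- function(n_genes = 150,
                       exons_per_gene = c(4L, 14L),
                       exon_len = c(80L, 300L),
                       intron_len = c(80L, 400L),
                       snp_rate = 0.02,
                       het_rate = 0.05,
                       shared_poly_rate = 0.001,
                       depth = 50,
                       read_len = 150,
                       tissues = c("gonad", "liver", "muscle"),
                       n_replicates = 3L,
                       bias_frac = 0.2,
                       bias_log2 = 1,
                       de_frac = 0.1,
                       de_log2 = 2,
                       as_events_per_gene = c(SE = 1L, RI = 1L, A5SS = 1L,
                                              A3SS = 1L, MXE = 1L, AP = 1L),
                       as_gene_frac = 0.3,
                       as_shared_frac = 0.5,
                       error_rate = 0.002,
                       outlier_snp_rate = 0,
                       outlier_factor = 10,
                       long_read_depth = 20,
                       fl_rate = 0.9,
                       parent_depth = 30,
                       intron_indel_rate = 0.1,
                       intron_indel_len = c(3L, 30L),
                       mito_reads = 1000L,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, exons_per_gene = exons_per_gene, exon_len = exon_len,
    intron_len = intron_len, snp_rate = snp_rate, het_rate = het_rate,
    shared_poly_rate = shared_poly_rate, depth = depth, read_len = read_len,
    tissues = tissues, n_replicates = n_replicates, bias_frac = bias_frac,
    bias_log2 = bias_log2, de_frac = de_frac, de_log2 = de_log2,
    as_events_per_gene = as_events_per_gene, as_gene_frac = as_gene_frac,
    as_shared_frac = as_shared_frac, error_rate = error_rate,
    outlier_snp_rate = outlier_snp_rate, outlier_factor = outlier_factor,
    long_read_depth = long_read_depth, fl_rate = fl_rate,
    parent_depth = parent_depth, intron_indel_rate = intron_indel_rate,
    intron_indel_len = intron_indel_len, mito_reads = mito_reads,
    seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
      stop_config(sprintf("'%s' must be a single integer >= %s", field, min),
                  field = field)
    }
  }
  chk_rate <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop_config(sprintf("'%s' must be a probability in [0, 1]", field),
                  field = field)
    }
  }
  chk_range <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
        x[1] < min || any(x != floor(x))) {
      stop_config(sprintf("'%s' must be a non-empty integer range c(min, max)", field),
                  field = field)
    }
  }
  chk_pos <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      stop_config(sprintf("'%s' must be a single positive number", field),
                  field = field)
    }
  }
  chk_count("n_genes"); chk_count("n_replicates", 2); chk_count("mito_reads", 0)
  chk_count("seed", 0)
  chk_range("exons_per_gene", 1); chk_range("exon_len", 10)
  chk_range("intron_len", 10); chk_range("intron_indel_len", 1)
  for (f in c("snp_rate", "het_rate", "shared_poly_rate", "bias_frac",
              "de_frac", "as_gene_frac", "as_shared_frac", "error_rate",
              "outlier_snp_rate", "fl_rate", "intron_indel_rate")) {
    chk_rate(f)
  }
  for (f in c("depth", "long_read_depth", "parent_depth", "outlier_factor")) {
    chk_pos(f)
  }
  if (!is.numeric(cfg$read_len) || length(cfg$read_len) != 1L || cfg$read_len < 20) {
    stop_config("'read_len' must be a single number >= 20 (or Inf)",
                field = "read_len")
  }
  if (!is.character(cfg$tissues) || length(cfg$tissues) < 1L ||
      anyDuplicated(cfg$tissues)) {
    stop_config("'tissues' must be distinct tissue labels", field = "tissues")
  }
  ev <- cfg$as_events_per_gene
  if (length(ev) > 0 &&
      (is.null(names(ev)) || !all(names(ev) %in% AS_TYPES_NAMED) ||
       any(ev < 0) || any(ev != floor(ev)))) {
    stop_config(
      sprintf("'as_events_per_gene' must be named counts from {%s}",
              paste(AS_TYPES_NAMED, collapse = ", ")),
      field = "as_events_per_gene"
    )
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_genes, "ortholog pairs,",
      length(x$tissues), "tissues x", x$n_replicates, "replicates, seed",
      x$seed, "\n")
  invisible(x)
}

# Event types with planted-isoform support (OTHER is a classifier catch-all).
AS_TYPES_NAMED <- c("SE", "RI", "A5SS", "A3SS", "MXE", "AP")
AS_TYPES_ALL <- c(AS_TYPES_NAMED, "OTHER")
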