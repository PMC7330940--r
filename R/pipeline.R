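# End-to-end pipeline over the synthetic cohort, with stage toggles and
# seed-stamped TSV outputs.

PIPELINE_STAGES <- c("simulate", "orthologs", "snps", "quantify", "de",
                     "as", "report")

#' Read a pipeline configuration from YAML
#'
#' The YAML may carry a `sim:` block (fields of [sim_config()]), a
#' `thresholds:` block (`fdr`, `min_count`, `fl_min_length`,
#' `assign_threshold`, `high_as_min`) and a `stages:` list.
#'
#' @param path YAML file.
#' @return list with `sim` (a `sim_config`), `thresholds`, `stages`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim %||% list())
  thresholds <- utils::modifyList(default_thresholds(),
                                  raw$thresholds %||% list())
  list(sim = sim, thresholds = thresholds,
       stages = raw$stages %||% PIPELINE_STAGES)
}

default_thresholds <- function() {
  list(fdr = 0.05, min_count = 5, fl_min_length = 300,
       assign_threshold = 0.85, high_as_min = 5)
}

#' Run the homoeolog expression and splicing pipeline
#'
#' Executes the stages in dependency order — simulate, orthologs, snps,
#' quantify, de, as, report — over a synthetic cohort, writing
#' seed-stamped TSVs into `out_dir`. Rerunning with the same
#' configuration reproduces the directory byte for byte. Requesting a
#' stage whose prerequisites have not been produced raises a dependency
#' error naming the stage.
#'
#' @param config a `sim_config`, or a list as returned by
#'   [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run (in pipeline order).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = PIPELINE_STAGES) {
  if (inherits(config, "sim_config")) {
    config <- list(sim = config, thresholds = default_thresholds())
  }
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  sim <- config$sim
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$seed
  hash <- rlang::hash(list(sim = unclass(sim), thresholds = thr))
  stamp <- function(x, name) {
    write_tsv_stamped(x, file.path(out_dir, paste0(name, ".tsv")),
                      seed = seed, config_hash = hash)
  }
  state <- list()
  t_all <- Sys.time()
  log_stage <- function(stage, t0) {
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  need <- function(stage, what) {
    if (is.null(state[[what]])) stop_dependency(stage, what)
    state[[what]]
  }

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    state$cohort <- simulate_cohort(sim)
    stamp(state$cohort$genes, "genes")
    stamp(state$cohort$snps |> select(-"bsb_hap", -"tc_hap"), "snps_truth")
    stamp(state$cohort$short_reads, "short_reads")
    stamp(state$cohort$long_reads, "long_reads")
    write_gtf(state$cohort$exons, state$cohort$genes,
              file.path(out_dir, "gene_models.gtf"))
    log_stage("simulate", t0)
  }

  if ("orthologs" %in% stages) {
    t0 <- Sys.time()
    cohort <- need("orthologs", "cohort")
    models <- filter_transcripts(cohort$genes)
    tx <- cohort$transcripts |> filter(.data$gene_id %in% models$gene_id)
    hits <- kmer_similarity_scores(
      tx |> filter(endsWith(.data$gene_id, "_bsb")),
      tx |> filter(endsWith(.data$gene_id, "_tc")),
      min_score = 0.2
    )
    state$rbh <- reciprocal_best_hits(hits, max_evalue = 0.8)
    state$structure <- structure_stats(state$rbh, cohort$genes)
    stamp(state$rbh, "ortholog_pairs")
    stamp(state$structure, "structure_stats")
    log_stage("orthologs", t0)
  }

  if ("snps" %in% stages) {
    t0 <- Sys.time()
    cohort <- need("snps", "cohort")
    state$snps <- call_species_snps(cohort$coord_maps, cohort$parent_pileups,
                                    n_replicates = sim$n_replicates)
    stamp(state$snps, "species_snps")
    log_stage("snps", t0)
  }

  if ("quantify" %in% stages) {
    t0 <- Sys.time()
    cohort <- need("quantify", "cohort")
    snps <- need("quantify", "snps")
    state$assignments <- assign_short_reads(cohort$short_read_calls, snps)
    counts <- snp_allele_counts(cohort$short_read_calls, cohort$short_reads,
                                snps, n_replicates = sim$n_replicates)
    filtered <- filter_outlier_snps(counts)
    gene_counts <- gene_homoeolog_counts(filtered,
                                         all_pairs = cohort$pairs$pair_id)
    state$normalized <- normalize_and_filter(gene_counts,
                                             min_count = thr$min_count)
    state$mito <- mito_origin_check(cohort$mito)
    stamp(gene_counts, "gene_homoeolog_counts")
    stamp(state$normalized, "gene_homoeolog_cpm")
    stamp(state$mito, "mito_origin")
    log_stage("quantify", t0)
  }

  if ("de" %in% stages) {
    t0 <- Sys.time()
    normalized <- need("de", "normalized")
    state$de <- homoeolog_de(normalized, fdr_threshold = thr$fdr)
    stamp(tidy(state$de), "homoeolog_de")
    log_stage("de", t0)
  }

  if ("as" %in% stages) {
    t0 <- Sys.time()
    cohort <- need("as", "cohort")
    snps <- need("as", "snps")
    fl <- classify_full_length(cohort$long_reads,
                               min_length = thr$fl_min_length)
    assign <- assign_long_read(cohort$long_read_calls, snps,
                               threshold = thr$assign_threshold,
                               read_ids = cohort$long_reads$read_id)
    supported <- fl |>
      inner_join(assign |> select("read_id", "call"), by = "read_id") |>
      filter(.data$full_length, .data$call != "unassigned")
    # chains supported by at least one assigned full-length read
    used <- cohort$chains |>
      semi_join(
        supported |>
          inner_join(cohort$pairs, by = "pair_id") |>
          transmute(gene_id = ifelse(.data$call == "BSB", .data$bsb_gene,
                                     .data$tc_gene),
                    chain_id = .data$chain_id),
        by = c("gene_id", "chain_id")
      )
    state$fl <- fl
    state$events <- classify_as_events(
      used |> select("gene_id", "homoeolog", "strand", "chain_id",
                     "start", "end"))
    state$shared_as <- shared_as_across_homoeologs(
      state$events |> filter(.data$homoeolog == "BSB"),
      state$events |> filter(.data$homoeolog == "TC"),
      cohort$pairs, cohort$coord_maps
    )
    stamp(state$events, "as_events")
    stamp(state$shared_as, "as_shared")
    write_event_bed(state$events, file.path(out_dir, "as_events.bed"))
    log_stage("as", t0)
  }

  if ("report" %in% stages) {
    t0 <- Sys.time()
    events <- need("report", "events")
    fl <- need("report", "fl")
    normalized <- need("report", "normalized")
    if (nrow(events) > 0) {
      summary_tbl <- as_summary_table(count_as_events(events))
      stamp(summary_tbl, "as_summary")
      writeLines(render_as_summary(summary_tbl),
                 file.path(out_dir, "as_summary.txt"))
      high <- high_as_genes(events, min_events = thr$high_as_min)
      stamp(high, "high_as_genes")
    }
    stamp(fl_summary_from_reads(fl, sample = "cohort"), "fl_summary")
    log_stage("report", t0)
  }

  message(sprintf("pipeline finished in %.1fs",
                  as.numeric(Sys.time() - t_all, units = "secs")))
  invisible(state)
}
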