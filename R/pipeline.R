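#' Build a pipeline run configuration
#'
#' All stage thresholds with their standard defaults, the root seed from
#' which every per-sample seed is derived, and the sample sheet. The
#' configuration round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed Root seed; sample i simulates with `seed + i`.
#' @param samples `data.frame`/`data.table` with columns `sample_id` and
#'   `cohort` (`"healthy"` or `"CLL"`); CLL samples are simulated with a
#'   planted dominant clone and partitioned.
#' @param germline_dir Optional directory of germline FASTA files; when
#'   `NULL` a synthetic set is generated from `germline` parameters.
#' @param germline List of generator sizes (`n_v`, `n_d`, `n_j`).
#' @param sim Named list of [sim_config()] overrides.
#' @param reads List of read-emission parameters (`error_rate`,
#'   `pcr_duplicates`, `read_length`, `const_trim`).
#' @param thresholds List of preprocessing thresholds (`min_median_phred`,
#'   `min_overlap`, `kmer`, `certainty`, `min_v_identity`,
#'   `min_j_identity`).
#' @param stats List of statistics parameters (`depth`, `n_sub`,
#'   `min_reads`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            samples = data.frame(sample_id = "sim1",
                                                 cohort = "healthy"),
                            germline_dir = NULL,
                            germline = list(n_v = 10L, n_d = 5L, n_j = 4L),
                            sim = list(),
                            reads = list(error_rate = 0.004,
                                         pcr_duplicates = 1,
                                         read_length = 210L,
                                         const_trim = 60L),
                            thresholds = list(min_median_phred = 34,
                                              min_overlap = 50L,
                                              kmer = 10L,
                                              certainty = 0.8,
                                              min_v_identity = 0.8,
                                              min_j_identity = 0.8),
                            stats = list(depth = 8000L, n_sub = 20L,
                                         min_reads = 100L)) {
  structure(list(seed = seed, samples = as.data.frame(samples),
                 germline_dir = germline_dir, germline = germline,
                 sim = sim, reads = reads, thresholds = thresholds,
                 stats = stats),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  raw$samples <- as.data.frame(raw$samples)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> emit reads -> preprocess -> annotate -> network ->
#' statistics for every sample in the configuration, writes per-sample and
#' cohort artifacts (AIRR TSV with clone ids, vertex/edge TSVs, clone
#' summaries, isotype frequencies, switch-probability tables) and a JSON
#' manifest with per-stage record counts, every threshold used, and all
#' seeds. Identical config + seed yields identical outputs.
#'
#' @param config A `pipeline_config` (or path to its YAML file).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("isoclonal")),
                   seed = config$seed,
                   thresholds = config$thresholds,
                   reads = config$reads, stats = config$stats,
                   samples = list())
  germline <- if (!is.null(config$germline_dir)) {
    if (!dir.exists(config$germline_dir))
      stop("germline FASTA directory not found: ", config$germline_dir)
    read_germline_fasta(config$germline_dir)
  } else {
    make_germline_set(config$germline$n_v, config$germline$n_d,
                      config$germline$n_j, seed = config$seed)
  }
  write_germline_fasta(germline, file.path(out_dir, "germline"))
  airr_all <- list()
  for (i in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[i]
    cohort <- config$samples$cohort[i]
    seed_i <- config$seed + i
    sim_args <- config$sim
    if (identical(cohort, "CLL") && is.null(sim_args$dominant_clone))
      sim_args$dominant_clone <- list(read_frac = 0.85, founder_mut = 12L,
                                      p_step = 0.3, p_switch = 0.02)
    sim <- simulate_repertoire(germline, do.call(sim_config, sim_args),
                               seed = seed_i)
    rd <- config$reads
    reads <- emit_reads(sim, germline, error_rate = rd$error_rate,
                        pcr_duplicates = rd$pcr_duplicates,
                        read_length = rd$read_length,
                        const_trim = rd$const_trim, seed = seed_i)
    th <- config$thresholds
    pp <- preprocess_reads(reads, germline,
                           min_median_phred = th$min_median_phred,
                           min_overlap = th$min_overlap, kmer = th$kmer,
                           certainty = th$certainty,
                           const_trim = rd$const_trim,
                           min_v_identity = th$min_v_identity,
                           min_j_identity = th$min_j_identity)
    airr <- annotate_bcrs(pp$consensus, germline, sample_id = sid,
                          min_v_identity = th$min_v_identity,
                          min_j_identity = th$min_j_identity)
    net <- build_network(airr)
    airr[, clone_id := net$vertices$cluster_id[match(sequence,
                                                     net$vertices$sequence)]]
    write_airr_tsv(airr, file.path(out_dir, paste0(sid, "_airr.tsv")))
    write_network_tsv(net, file.path(out_dir, paste0(sid, "_vertices.tsv")),
                      file.path(out_dir, paste0(sid, "_edges.tsv")))
    data.table::fwrite(clone_summaries(net),
                       file.path(out_dir, paste0(sid, "_clones.tsv")),
                       sep = "\t")
    sample_info <- list(sample_id = sid, cohort = cohort, seed = seed_i,
                        n_cells = nrow(sim$cells),
                        n_molecules = sum(sim$cells$rna_copies),
                        preprocess = pp$log,
                        error_rate_estimate = pp$error_rate$rate,
                        n_annotated = nrow(airr),
                        n_clusters = length(unique(net$vertices$cluster_id)))
    if (identical(cohort, "CLL")) {
      part <- partition_cll(airr, net)
      sample_info$partition <- list(
        n_malignant = length(part$malignant),
        n_non_malignant = length(part$non_malignant),
        n_excluded_vj_only = length(part$excluded_vj_only),
        dominant_read_fraction = part$dominant_read_fraction)
    }
    manifest$samples[[sid]] <- sample_info
    airr_all[[sid]] <- airr
  }
  airr_all <- data.table::rbindlist(airr_all)
  utab <- unique_bcr_table(airr_all)
  data.table::fwrite(isotype_frequencies(utab),
                     file.path(out_dir, "isotype_frequencies.tsv"),
                     sep = "\t")
  data.table::fwrite(sample_summaries(utab),
                     file.path(out_dir, "sample_summaries.tsv"), sep = "\t")
  sp <- tryCatch(
    switch_probabilities(utab, min_reads = config$stats$min_reads),
    error = function(e) NULL)
  if (!is.null(sp)) {
    data.table::fwrite(sp$gene, file.path(out_dir, "switch_gene.tsv"),
                       sep = "\t")
    data.table::fwrite(sp$isotype, file.path(out_dir, "switch_isotype.tsv"),
                       sep = "\t")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
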