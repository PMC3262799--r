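#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_pipeline()]'s
#'   config list (`seed`, `output_dir`, `simulate` or `inputs`,
#'   `second_cohort`, `specificity`, `correlation`, `enrichment`,
#'   `network`).
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

stage_seed <- function(seed, stage) as.integer(seed) + 100L * stage

pick <- function(lst, key, default) {
  if (!is.null(lst) && !is.null(lst[[key]])) lst[[key]] else default
}

analyse_cohort <- function(mirna, mrna, meta, predictions, scheme, cfg,
                           seed) {
  thr <- pick(cfg$specificity, "detection_threshold", 7)
  det_mi <- detection_filter(mirna, meta, scheme, thr)
  det_mr <- detection_filter(mrna, meta, scheme, thr)
  mi_f <- apply_detection_filter(mirna, det_mi)
  mr_f <- apply_detection_filter(mrna, det_mr)
  outliers <- flag_outliers_pca(mrna, pick(cfg$qc, "k_sd", 3))

  par_mi <- specificity_params(
    alpha = pick(cfg$specificity, "alpha", 0.05),
    min_fold_change = pick(cfg$specificity, "min_fold_change_mirna", 1),
    detection_threshold = thr)
  par_mr <- specificity_params(
    alpha = pick(cfg$specificity, "alpha", 0.05),
    min_fold_change = pick(cfg$specificity, "min_fold_change_mrna", 4),
    detection_threshold = thr)
  calls_mi <- call_specificity(mi_f, meta, scheme, par_mi)
  calls_mr <- call_specificity(mr_f, meta, scheme, par_mr)

  basis <- pick(cfg$correlation, "basis", "matched_samples")
  if (identical(basis, "matched_samples")) {
    z_mi <- matched_sample_profiles(mi_f, meta, scheme)
    z_mr <- matched_sample_profiles(mr_f, meta, scheme)
  } else {
    z_mi <- ztransform_profiles(mi_f, meta, scheme)
    z_mr <- ztransform_profiles(mr_f, meta, scheme)
  }
  corr <- correlate_pairs(z_mi, z_mr)
  cut <- calibrate_cutoff(
    z_mi, z_mr,
    target_fdr = pick(cfg$correlation, "target_fdr", 0.01),
    n_permutations = pick(cfg$correlation, "n_permutations", 100),
    seed = seed)

  universe <- rownames(z_mr)
  preds <- filter_confirmed_predictions(predictions)
  if (!is.na(cut$cutoff)) {
    enrich <- test_overlap(corr, cut$cutoff, preds, universe,
                           n_permutations = pick(cfg$enrichment,
                                                 "n_permutations", 100),
                           seed = seed + 1L)
    pairs <- do.call(rbind, lapply(unique(corr$mirna), function(m) {
      tl <- negcorr_target_list(corr, cut$cutoff, preds, m)
      if (nrow(tl)) data.frame(mirna = m, gene = tl$gene, r = tl$r,
                               stringsAsFactors = FALSE) else NULL
    }))
  } else {
    enrich <- NULL
    pairs <- NULL
  }
  if (is.null(pairs))
    pairs <- data.frame(mirna = character(), gene = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  list(detection = list(mirna = det_mi, mrna = det_mr),
       outliers = outliers, calls_mirna = calls_mi, calls_mrna = calls_mr,
       correlation = corr, cutoff = cut, enrichment = enrich, pairs = pairs)
}

#' Run the full inference pipeline
#'
#' Orchestrates qc -> specificity -> correlation -> overlap enrichment ->
#' (optional second cohort) -> replication -> network on either simulated
#' or file-based inputs, writes every stage output as TSV (plus SIF and
#' GraphML for the network) into `config$output_dir`, and returns the
#' manifest (also written as `manifest.json`) recording the package
#' version, seed, per-stage counts and md5 checksum of every output file.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config A list (or path handled by [read_pipeline_config()]). Keys:
#'   `seed` (integer, fans out to per-stage seeds by a fixed offset),
#'   `output_dir`, and either `simulate` (a list of [simulation_config()]
#'   overrides; `second_cohort = TRUE` adds a validation cohort) or
#'   `inputs` (paths `mirna`, `mrna`, `metadata`, `predictions`), plus
#'   optional `specificity`, `correlation`, `enrichment`, `network`
#'   parameter lists.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(pick(config, "seed", 1L))
  out_dir <- pick(config, "output_dir", NULL)
  if (is.null(out_dir)) stop("config$output_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- default_cell_scheme()
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  if (!is.null(config$inputs)) {
    need <- c("mirna", "mrna", "metadata", "predictions")
    for (key in need) {
      p <- config$inputs[[key]]
      if (is.null(p) || !file.exists(p))
        stop("input file missing before any compute: ", key, call. = FALSE)
    }
    mirna <- read_expression_matrix(config$inputs$mirna, "mirna")
    mrna <- read_expression_matrix(config$inputs$mrna, "mrna")
    meta <- read_sample_metadata(config$inputs$metadata)
    predictions <- read_prediction_table(config$inputs$predictions)
    second <- NULL
    truth <- NULL
  } else {
    sim_args <- config$simulate
    sim_args$second_cohort <- NULL
    sim_args$seed <- stage_seed(seed, 0L)
    sim <- do.call(simulation_config, sim_args %||% list())
    cohort <- simulate_cohort(sim)
    mirna <- cohort$mirna
    mrna <- cohort$mrna
    meta <- cohort$metadata
    predictions <- cohort$predictions
    truth <- cohort$truth
    emit(data.frame(transcript_id = rownames(mirna),
                    unclass(mirna), check.names = FALSE),
         "simulated_mirna.tsv")
    emit(meta, "simulated_metadata.tsv")
    emit(as.data.frame(predictions), "simulated_predictions.tsv")
    second <- if (isTRUE(pick(config$simulate, "second_cohort",
                              TRUE)))
      simulate_second_cohort(truth, seed = stage_seed(seed, 1L)) else NULL
  }

  res_a <- analyse_cohort(mirna, mrna, meta, predictions, scheme, config,
                          stage_seed(seed, 2L))
  emit(res_a$calls_mirna, "specificity_mirna_A.tsv")
  emit(res_a$calls_mrna, "specificity_mrna_A.tsv")
  emit(res_a$cutoff$fdr_curve, "cutoff_fdr_curve_A.tsv")
  if (!is.null(res_a$enrichment)) emit(res_a$enrichment, "enrichment_A.tsv")
  emit(res_a$pairs, "pairs_A.tsv")

  if (!is.null(second)) {
    res_b <- analyse_cohort(second$mirna, second$mrna, second$metadata,
                            predictions, scheme, config,
                            stage_seed(seed, 3L))
    emit(res_b$pairs, "pairs_B.tsv")
    repl <- replicated_pairs(res_a$pairs, res_b$pairs)
    # carry cohort A correlation onto replicated edges
    key <- paste(res_a$pairs$mirna, res_a$pairs$gene, sep = "\r")
    repl$r <- res_a$pairs$r[match(paste(repl$mirna, repl$gene, sep = "\r"),
                                  key)]
    calls_for_net <- res_b$calls_mirna
  } else {
    res_b <- NULL
    repl <- res_a$pairs
    calls_for_net <- res_a$calls_mirna
  }
  emit(repl, "replicated_pairs.tsv")

  net <- build_network(repl, calls_for_net,
                       filter_confirmed_predictions(predictions),
                       min_degree = pick(config$network, "min_degree", 2),
                       scheme = scheme)
  sif <- file.path(out_dir, "network.sif")
  export_network(net, sif, "sif")
  outputs[[length(outputs) + 1L]] <- sif
  gml <- file.path(out_dir, "network.graphml")
  export_network(net, gml, "graphml")
  outputs[[length(outputs) + 1L]] <- gml
  emit(rank_hubs(net), "hubs.tsv")

  outputs <- unlist(outputs)
  manifest <- list(
    package = "mircellnet",
    version = as.character(utils::packageVersion("mircellnet")),
    seed = seed,
    counts = list(
      n_mirna = nrow(mirna), n_mrna = nrow(mrna),
      n_samples = ncol(mirna),
      mirna_detected = res_a$detection$mirna$n_kept,
      mrna_detected = res_a$detection$mrna$n_kept,
      mirna_calls = nrow(res_a$calls_mirna),
      mrna_calls = nrow(res_a$calls_mrna),
      cutoff = res_a$cutoff$cutoff,
      n_pairs_a = nrow(res_a$pairs),
      n_pairs_b = if (!is.null(res_b)) nrow(res_b$pairs) else NA,
      n_replicated = nrow(repl),
      n_network_edges = nrow(net$edges),
      n_network_genes = sum(net$nodes$kind == "gene")),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
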