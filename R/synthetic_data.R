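#' Configuration for the synthetic sorted-immune-cell cohort generator
#'
#' Encodes the study design the downstream statistics assume: eight
#' analysis cell types split across the myeloid and lymphoid lineages,
#' replicate donor pools per type, log2-scale signal with a detection floor,
#' planted transcripts specifically up-/down-regulated in 1, 2 or 3 cell
#' types (3-type patterns are lineage-coherent), and planted miRNA-to-mRNA
#' repression couplings alongside expression-independent decoy predictions.
#'
#' @param lineages Named character vector, analysis cell type -> lineage.
#' @param n_pools_per_type Replicate donor pools per cell type (default 5).
#' @param n_mirna,n_mrna Number of transcripts per platform.
#' @param background_mean Log2 mean of unexpressed transcripts (default 5,
#'   below the detection floor of 7).
#' @param expressed_mean_range Log2 interval the base mean of each expressed
#'   transcript is drawn from once and shared across cell types
#'   (default `c(8, 12)`).
#' @param noise_sd Per-sample Gaussian noise on the log2 scale (default 0.5).
#' @param specificity_shift Log2 shift added (up) or subtracted (down) in
#'   the specific cell types (default 3, i.e. 8-fold).
#' @param frac_background Fraction of non-planted transcripts left at the
#'   background mean (default 0.25).
#' @param n_specific_up,n_specific_down Lists with elements `mirna` and
#'   `mrna`, each a length-3 count vector of planted transcripts specific
#'   to 1, 2 and 3 cell types.
#' @param coupling_beta Strength of the planted repression: a true target's
#'   per-cell-type mean is its base minus `coupling_beta` times the
#'   standardized cell-type profile of its miRNA (default 1).
#' @param n_coupled_mirna Number of up-specific miRNAs that receive true
#'   target links (default 6).
#' @param n_true_links_per_mirna True targets per coupled miRNA (default 20).
#' @param n_shared_targets Additional true-target genes coupled to a pair
#'   of coupled miRNAs with compatible (non-negatively correlated) planted
#'   profiles, emulating multiply-targeted hub genes (default 8).
#' @param n_decoy_predictions_per_mirna Decoy predicted targets per planted
#'   miRNA, never overlapping any true link (default 20).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    lineages = c(Neutrophils = "myeloid", Eosinophils = "myeloid",
                 Monocytes = "myeloid", mDC = "myeloid",
                 T = "lymphoid", B = "lymphoid", NK = "lymphoid",
                 pDC = "lymphoid"),
    n_pools_per_type = 5, n_mirna = 60, n_mrna = 300,
    background_mean = 5, expressed_mean_range = c(8, 12),
    noise_sd = 0.5, specificity_shift = 3, frac_background = 0.25,
    n_specific_up = list(mirna = c(4, 5, 9), mrna = c(20, 10, 5)),
    n_specific_down = list(mirna = c(2, 0, 0), mrna = c(6, 3, 2)),
    coupling_beta = 1, n_coupled_mirna = 6, n_true_links_per_mirna = 20,
    n_shared_targets = 8, n_decoy_predictions_per_mirna = 20, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  stopifnot(noise_sd > 0, n_pools_per_type >= 1,
            all(unlist(n_specific_up) >= 0),
            all(unlist(n_specific_down) >= 0),
            coupling_beta >= 0, frac_background >= 0, frac_background < 1)
  for (plat in c("mirna", "mrna")) {
    n_spec <- sum(n_specific_up[[plat]]) + sum(n_specific_down[[plat]])
    n_tot <- if (plat == "mirna") n_mirna else n_mrna
    if (n_spec > n_tot)
      stop("config requests more specific ", plat,
           " transcripts than available", call. = FALSE)
  }
  if (n_coupled_mirna > sum(n_specific_up$mirna))
    stop("n_coupled_mirna exceeds the planted up-specific miRNAs",
         call. = FALSE)
  if (n_shared_targets > 0 && n_coupled_mirna < 2)
    stop("shared targets need at least 2 coupled miRNAs", call. = FALSE)
  need <- n_coupled_mirna * n_true_links_per_mirna + n_shared_targets +
    sum(n_specific_up$mrna) + sum(n_specific_down$mrna)
  if (need > n_mrna)
    stop("config requests more planted mRNA transcripts than n_mrna",
         call. = FALSE)
  cfg
}

# Draw the cell-type set of a planted k-specific pattern. k = 3 patterns
# are lineage-coherent (all three types from one lineage).
draw_pattern <- function(k, lineages) {
  types <- names(lineages)
  if (k < 3L) return(sort(sample(types, k)))
  lin <- sample(unique(lineages), 1L)
  sort(sample(types[lineages == lin], 3L))
}

plant_patterns <- function(ids, platform, cfg) {
  rows <- list()
  i <- 0L
  for (direction in c("up", "down")) {
    counts <- if (direction == "up") cfg$n_specific_up[[platform]]
              else cfg$n_specific_down[[platform]]
    for (k in 1:3) for (rep in seq_len(counts[k])) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        transcript = ids[i], platform = platform, direction = direction,
        k = k, cell_types = paste(draw_pattern(k, cfg$lineages),
                                  collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (i == 0L)
    return(data.frame(transcript = character(), platform = character(),
                      direction = character(), k = integer(),
                      cell_types = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Noiseless per-cell-type mean profile of one transcript.
pattern_means <- function(base, pattern_row, types, shift) {
  mu <- rep(base, length(types))
  names(mu) <- types
  if (!is.null(pattern_row)) {
    cts <- intersect(strsplit(pattern_row$cell_types, ";")[[1L]], types)
    mu[cts] <- mu[cts] + if (pattern_row$direction == "up") shift else -shift
  }
  mu
}

generate_cohort <- function(plan, cfg, cell_types, cohort_label, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  types <- cell_types
  n_s <- cfg$n_pools_per_type
  sample_ids <- as.vector(vapply(types, function(ct)
    paste0(cohort_label, "_", ct, "_P", seq_len(n_s)), character(n_s)))
  lab <- rep(types, each = n_s)
  meta <- data.frame(sample_id = sample_ids, cell_type = lab,
                     donor_pool = paste0("pool", rep(seq_len(n_s),
                                                     times = length(types))),
                     cohort = cohort_label, scan_batch = "batch1",
                     stringsAsFactors = FALSE)

  make_matrix <- function(ids, platform, patterns, coupled_profiles) {
    n <- length(ids)
    is_planted <- ids %in% patterns$transcript
    is_coupled <- ids %in% colnames(coupled_profiles)
    free <- which(!is_planted & !is_coupled)
    n_bg <- round(cfg$frac_background * length(free))
    bg <- free[seq_len(n_bg)]  # deterministic tail assignment
    base <- stats::runif(n, cfg$expressed_mean_range[1L],
                         cfg$expressed_mean_range[2L])
    base[bg] <- cfg$background_mean
    mu <- matrix(rep(base, length(types)), n, length(types),
                 dimnames = list(ids, types))
    for (r in seq_len(nrow(patterns))) {
      t_id <- patterns$transcript[r]
      mu[t_id, ] <- pattern_means(base[match(t_id, ids)], patterns[r, ],
                                  types, cfg$specificity_shift)
    }
    if (ncol(coupled_profiles))
      for (g in colnames(coupled_profiles))
        mu[g, ] <- base[match(g, ids)] - cfg$coupling_beta *
          coupled_profiles[, g]
    vals <- mu[, lab, drop = FALSE] +
      matrix(stats::rnorm(n * length(lab), 0, cfg$noise_sd), n)
    colnames(vals) <- sample_ids
    list(x = expr_matrix(vals, platform), mu = mu)
  }

  pat_mi <- plan$patterns[plan$patterns$platform == "mirna", , drop = FALSE]
  pat_mr <- plan$patterns[plan$patterns$platform == "mrna", , drop = FALSE]
  none <- matrix(numeric(), length(types), 0,
                 dimnames = list(types, NULL))
  mi <- make_matrix(plan$mirna_ids, "mirna", pat_mi, none)

  # standardized noiseless miRNA cell-type profiles drive the couplings;
  # a gene linked to several miRNAs tracks their average profile
  coupled <- none
  if (nrow(plan$true_links) && cfg$coupling_beta >= 0) {
    zrow <- function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    genes <- unique(plan$true_links$gene)
    prof <- vapply(genes, function(g) {
      ms <- plan$true_links$mirna[plan$true_links$gene == g]
      zs <- vapply(ms, function(m) zrow(mi$mu[m, ]), numeric(length(types)))
      zrow(rowMeans(matrix(zs, ncol = length(ms))))
    }, numeric(length(types)))
    coupled <- matrix(prof, length(types), dimnames = list(types, genes))
  }
  mr <- make_matrix(plan$mrna_ids, "mrna", pat_mr, coupled)

  list(mirna = mi$x, mrna = mr$x, metadata = meta)
}

#' Simulate a full discovery cohort
#'
#' Generates miRNA and mRNA expression matrices, sample metadata, a
#' target-prediction table and the ground-truth tables under a
#' [simulation_config()]. Non-planted expressed transcripts share one base
#' mean across cell types; planted k-specific transcripts shift it up or
#' down in their cell types; each true link's target mRNA tracks the
#' negative of its miRNA's standardized cell-type profile; per-sample
#' Gaussian noise is added on top. The prediction table holds every true
#' link plus decoys, each with a synthetic non-overlapping seed-site
#' interval and sources targetscan + mirdb. Deterministic under the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return A list `mirna`, `mrna` ([expr_matrix()]), `metadata`,
#'   `predictions` (`prediction_table`), `truth` (list of
#'   `specific_transcripts`, `true_links`, `decoy_links`; the generator
#'   plan needed to simulate further cohorts rides along as an attribute).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(config$seed))

  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("gene-%04d", seq_len(config$n_mrna))
  pat_mi <- plant_patterns(mirna_ids, "mirna", config)
  n_spec_mrna <- sum(config$n_specific_up$mrna) +
    sum(config$n_specific_down$mrna)
  pat_mr <- plant_patterns(mrna_ids, "mrna", config)
  patterns <- rbind(pat_mi, pat_mr)

  # coupled miRNAs are chosen for overlapping specificity patterns
  # (broadest k first, then greedily by shared cell types), mirroring the
  # co-expressed miRNA clusters that drive multiply-targeted genes
  up <- pat_mi[pat_mi$direction == "up", , drop = FALSE]
  up_sets <- strsplit(up$cell_types, ";")
  ord <- order(-up$k, up$transcript)
  picked <- ord[seq_len(min(1L, config$n_coupled_mirna))]
  while (length(picked) < config$n_coupled_mirna) {
    rest <- setdiff(ord, picked)
    cover <- unique(unlist(up_sets[picked]))
    ov <- vapply(rest, function(i)
      length(intersect(up_sets[[i]], cover)), integer(1L))
    picked <- c(picked, rest[which.max(ov)])
  }
  coupled_mirnas <- up$transcript[picked]
  target_pool <- mrna_ids[(n_spec_mrna + 1L):config$n_mrna]
  true_links <- data.frame(mirna = character(), gene = character(),
                           stringsAsFactors = FALSE)
  used <- 0L
  for (m in coupled_mirnas) {
    g <- target_pool[used + seq_len(config$n_true_links_per_mirna)]
    used <- used + config$n_true_links_per_mirna
    true_links <- rbind(true_links,
                        data.frame(mirna = m, gene = g,
                                   stringsAsFactors = FALSE))
  }
  if (config$n_shared_targets > 0 && length(coupled_mirnas) >= 2L) {
    # shared targets arise between co-expressed miRNAs: the pair must share
    # at least one specific cell type so that the combined profile still
    # anti-correlates strongly with each regulator
    types <- names(config$lineages)
    sets <- lapply(coupled_mirnas, function(m)
      strsplit(pat_mi$cell_types[pat_mi$transcript == m], ";")[[1L]])
    share <- outer(seq_along(sets), seq_along(sets), Vectorize(function(i, j)
      length(intersect(sets[[i]], sets[[j]])) > 0))
    cand <- which(upper.tri(share) & share, arr.ind = TRUE)
    if (!nrow(cand)) {  # fall back to the most similar pair of patterns
      prof <- vapply(coupled_mirnas, function(m) {
        row <- pat_mi[pat_mi$transcript == m, , drop = FALSE]
        mu <- pattern_means(10, row, types, config$specificity_shift)
        (mu - mean(mu)) / stats::sd(mu)
      }, numeric(length(types)))
      pc <- stats::cor(prof)
      cand <- which(upper.tri(pc) & pc == max(pc[upper.tri(pc)]),
                    arr.ind = TRUE)
    }
    for (s in seq_len(config$n_shared_targets)) {
      g <- target_pool[used + 1L]
      used <- used + 1L
      pr <- cand[sample.int(nrow(cand), 1L), ]
      true_links <- rbind(true_links,
                          data.frame(mirna = coupled_mirnas[c(pr[1L], pr[2L])],
                                     gene = g, stringsAsFactors = FALSE))
    }
  }
  # decoys for every planted miRNA, drawn away from all true-target genes
  decoy_pool <- setdiff(target_pool, true_links$gene)
  decoy_links <- do.call(rbind, lapply(pat_mi$transcript, function(m) {
    data.frame(mirna = m,
               gene = sample(decoy_pool,
                             min(config$n_decoy_predictions_per_mirna,
                                 length(decoy_pool))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(decoy_links))
    decoy_links <- data.frame(mirna = character(), gene = character(),
                              stringsAsFactors = FALSE)

  links <- rbind(true_links, decoy_links)
  predictions <- if (nrow(links)) {
    slot <- stats::ave(seq_len(nrow(links)), links$gene, FUN = seq_along)
    prediction_table(data.frame(
      mirna_family = links$mirna, gene = links$gene,
      chrom = links$gene, start = 100L + 50L * (slot - 1L),
      end = 100L + 50L * (slot - 1L) + 7L,
      sources = "targetscan;mirdb", stringsAsFactors = FALSE))
  } else prediction_table(data.frame(
    mirna_family = character(), gene = character(), chrom = character(),
    start = integer(), end = integer(), sources = character()))

  plan <- list(mirna_ids = mirna_ids, mrna_ids = mrna_ids,
               patterns = patterns, true_links = true_links)
  cohort <- generate_cohort(plan, config, names(config$lineages), "A",
                            seed = config$seed + 17L)
  truth <- structure(list(specific_transcripts = patterns,
                          true_links = true_links,
                          decoy_links = decoy_links),
                     plan = plan, config = config)
  c(cohort, list(predictions = predictions, truth = truth))
}

#' Simulate an independent validation cohort sharing the planted truth
#'
#' Re-generates expression with fresh base means, fresh noise and fresh
#' donor pools while keeping the planted specificity patterns and
#' repression links of a prior [simulate_cohort()] run, optionally on a
#' subset of the cell types (by default the dendritic subsets mDC and pDC
#' are dropped, mirroring a smaller validation panel).
#'
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @param cell_types Analysis cell types profiled in the second cohort;
#'   must share at least one cell type with the original design.
#' @param seed Integer seed for the new cohort (defaults to the original
#'   seed + 1).
#' @return A list `mirna`, `mrna`, `metadata` (cohort label "B").
#' @export
simulate_second_cohort <- function(truth,
                                   cell_types = NULL, seed = NULL) {
  plan <- attr(truth, "plan")
  config <- attr(truth, "config")
  if (is.null(plan) || is.null(config))
    stop("`truth` must come from simulate_cohort()", call. = FALSE)
  all_types <- names(config$lineages)
  if (is.null(cell_types))
    cell_types <- setdiff(all_types, c("mDC", "pDC"))
  cell_types <- intersect(all_types, cell_types)
  if (!length(cell_types))
    stop("second cohort shares no cell type with the design", call. = FALSE)
  if (is.null(seed)) seed <- config$seed + 1L
  generate_cohort(plan, config, cell_types, "B", seed = seed + 31L)
}
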