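# Shared fixture builders: everything is generated in code at test time.

# Small expression matrix with explicit per-cell-type means.
# means: named list cell_type -> numeric vector over transcripts.
make_expr <- function(means, n_per_type = 3, noise_sd = 0, seed = 1,
                      platform = "mrna", transcripts = NULL) {
  set.seed(seed)
  types <- names(means)
  n_t <- length(means[[1L]])
  if (is.null(transcripts)) transcripts <- paste0("t", seq_len(n_t))
  cols <- list()
  ids <- character()
  for (ct in types) for (j in seq_len(n_per_type)) {
    cols[[length(cols) + 1L]] <- means[[ct]] +
      stats::rnorm(n_t, 0, noise_sd)
    ids <- c(ids, paste0(ct, "_s", j))
  }
  vals <- do.call(cbind, cols)
  dimnames(vals) <- list(transcripts, ids)
  list(x = expr_matrix(vals, platform),
       meta = data.frame(sample_id = ids,
                         cell_type = rep(types, each = n_per_type),
                         donor_pool = paste0("pool",
                                             rep(seq_len(n_per_type),
                                                 times = length(types))),
                         cohort = "A", scan_batch = "b1",
                         stringsAsFactors = FALSE))
}

# Identity scheme over arbitrary cell-type labels, alternating lineages.
make_scheme <- function(types) {
  lin <- rep(c("myeloid", "lymphoid"), length.out = length(types))
  cell_scheme(types, stats::setNames(types, types),
              stats::setNames(lin, types))
}

# A small config that keeps module tests fast.
small_config <- function(seed = 1, ...) {
  simulation_config(n_mirna = 30, n_mrna = 120,
                    n_specific_up = list(mirna = c(3, 2, 2),
                                         mrna = c(8, 4, 2)),
                    n_specific_down = list(mirna = c(1, 0, 0),
                                           mrna = c(3, 1, 1)),
                    n_coupled_mirna = 3, n_true_links_per_mirna = 10,
                    n_shared_targets = 4,
                    n_decoy_predictions_per_mirna = 10, seed = seed, ...)
}

# Compare a specificity call table against the planted truth; returns the
# fraction of planted transcripts of a platform recovered with correct
# direction, k and cell-type set.
recovery_fraction <- function(calls, truth, plat) {
  tr <- truth$specific_transcripts
  tr <- tr[tr$platform == plat, , drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    m <- calls[calls$transcript == tr$transcript[i] &
                 calls$direction == tr$direction[i], , drop = FALSE]
    nrow(m) == 1L && m$k == tr$k[i] &&
      identical(sort(strsplit(m$specific_cell_types, ";")[[1L]]),
                sort(strsplit(tr$cell_types[i], ";")[[1L]]))
  }, logical(1L))
  mean(hit)
}

# Run both platforms of a cohort through detection + specificity.
call_cohort <- function(cohort, scheme = default_cell_scheme(),
                        alpha = 0.05) {
  mi <- apply_detection_filter(
    cohort$mirna, detection_filter(cohort$mirna, cohort$metadata, scheme))
  mr <- apply_detection_filter(
    cohort$mrna, detection_filter(cohort$mrna, cohort$metadata, scheme))
  list(mirna = call_specificity(mi, cohort$metadata, scheme,
         specificity_params(alpha = alpha, min_fold_change = 1)),
       mrna = call_specificity(mr, cohort$metadata, scheme,
         specificity_params(alpha = alpha, min_fold_change = 4)))
}
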