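#' Test over-representation of predicted targets among anti-correlated mRNAs
#'
#' For each miRNA, compares the observed overlap between (i) the mRNAs
#' whose correlation with the miRNA falls below the negative cutoff and
#' (ii) its predicted target genes, against a fixed-size randomisation
#' null: in each permutation the number of predicted targets is held fixed
#' while their identities are drawn uniformly from the profiled gene
#' universe. That sampling scheme makes the null overlap hypergeometric, so
#' the empirical p-value converges to the exact hypergeometric upper tail.
#' Add-one smoothing keeps p above 1/(n_permutations + 1); BH adjustment is
#' applied across miRNAs and each miRNA is assigned a significance tier at
#' FDR 1%, 5% or none.
#'
#' @param corr A `correlation_table` from [correlate_pairs()].
#' @param cutoff Negative correlation threshold (pairs with
#'   \code{r < cutoff} count as anti-correlated); non-negative values are
#'   rejected.
#' @param predictions A `prediction_table`, already passed through
#'   [filter_confirmed_predictions()].
#' @param universe Character vector of all profiled genes (the draw space
#'   of the randomisation).
#' @param n_permutations Number of random draws per miRNA (default 100).
#' @param seed Integer seed.
#' @return Data.frame of class `enrichment_results`: one row per miRNA in
#'   `corr` with `n_predicted`, `n_negcorr`, `observed_overlap`,
#'   `expected_overlap_null`, `empirical_p`, `p_adj`, `significant_at`.
#' @export
test_overlap <- function(corr, cutoff, predictions, universe,
                         n_permutations = 100, seed = 1L) {
  if (!is.numeric(cutoff) || cutoff >= 0)
    stop("cutoff must be negative (anti-correlation contract)",
         call. = FALSE)
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)

  mirnas <- unique(corr$mirna)
  pred_by_mirna <- split(predictions$gene, predictions$mirna_family)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  rows <- lapply(mirnas, function(m) {
    sub <- corr[corr$mirna == m & !is.na(corr$r), , drop = FALSE]
    Nm <- intersect(sub$mrna[sub$r < cutoff], universe)
    Tm <- intersect(unique(pred_by_mirna[[m]]), universe)
    O <- length(intersect(Nm, Tm))
    if (length(Tm)) {
      null_ov <- vapply(seq_len(n_permutations), function(b)
        sum(sample(universe, length(Tm)) %in% Nm), numeric(1L))
    } else null_ov <- numeric(n_permutations)
    data.frame(mirna = m, n_predicted = length(Tm), n_negcorr = length(Nm),
               observed_overlap = O, expected_overlap_null = mean(null_ov),
               empirical_p = (1 + sum(null_ov >= O)) / (1 + n_permutations),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$empirical_p, "BH")
  out$significant_at <- ifelse(out$p_adj <= 0.01, "0.01",
                        ifelse(out$p_adj <= 0.05, "0.05", "none"))
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Anti-correlated predicted targets of one miRNA
#'
#' Returns the intersection of a miRNA's predicted target genes with the
#' genes anti-correlated with it below the cutoff, sorted by ascending
#' correlation (strongest repression signal first). This list feeds the
#' per-miRNA reporting tables and the regulatory-network builder.
#'
#' @inheritParams test_overlap
#' @param mirna The miRNA identifier (must appear in `corr`).
#' @return Data.frame with columns `gene`, `r`, ascending in `r`.
#' @export
negcorr_target_list <- function(corr, cutoff, predictions, mirna) {
  if (!mirna %in% corr$mirna)
    stop("unknown miRNA: ", mirna, call. = FALSE)
  sub <- corr[corr$mirna == mirna & !is.na(corr$r), , drop = FALSE]
  neg <- sub[sub$r < cutoff, , drop = FALSE]
  targets <- unique(predictions$gene[predictions$mirna_family == mirna])
  hit <- neg[neg$mrna %in% targets, , drop = FALSE]
  out <- data.frame(gene = hit$mrna, r = hit$r, stringsAsFactors = FALSE)
  out <- out[order(out$r, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
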