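#' Cross-cohort agreement of two identifier sets
#'
#' Jaccard coefficient (intersection over union) plus the hypergeometric
#' upper-tail probability of seeing at least the observed overlap when one
#' set is drawn at random from the universe. The Jaccard does not depend on
#' the universe; the p-value does, and the universe size must therefore be
#' supplied explicitly.
#'
#' @param set_a,set_b Character vectors (identifier sets).
#' @param universe_size Size of the common identifier universe; must be at
#'   least the size of the union.
#' @return A list of class `overlap_stats` with `n_a`, `n_b`, `n_common`,
#'   `jaccard`, `hypergeom_p`, `universe_size`.
#' @export
overlap_stats <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  overlap_stats_counts(length(set_a), length(set_b),
                       length(intersect(set_a, set_b)), universe_size)
}

#' @rdname overlap_stats
#' @param n_a,n_b,n_common Set sizes and overlap count.
#' @export
overlap_stats_counts <- function(n_a, n_b, n_common, universe_size) {
  n_union <- n_a + n_b - n_common
  if (universe_size < n_union)
    stop("universe smaller than the union of the two sets", call. = FALSE)
  if (n_common > min(n_a, n_b))
    stop("overlap exceeds the smaller set", call. = FALSE)
  jac <- if (n_union == 0) 1 else n_common / n_union
  p <- stats::phyper(n_common - 1, n_a, universe_size - n_a, n_b,
                     lower.tail = FALSE)
  structure(list(n_a = n_a, n_b = n_b, n_common = n_common, jaccard = jac,
                 hypergeom_p = p, universe_size = universe_size),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("<overlap_stats> |A|=%d |B|=%d common=%d Jaccard=%.2f p=%.3g\n",
              x$n_a, x$n_b, x$n_common, x$jaccard, x$hypergeom_p))
  invisible(x)
}

#' Pairs replicated across two cohorts
#'
#' Exact intersection of two (miRNA, gene) pair sets, e.g. the significant
#' repression pairs of a discovery and an independent validation cohort.
#'
#' @param pairs_a,pairs_b Data.frames with columns `mirna` and `gene`.
#' @return Data.frame of the common pairs (columns `mirna`, `gene`).
#' @export
replicated_pairs <- function(pairs_a, pairs_b) {
  key_a <- paste(pairs_a$mirna, pairs_a$gene, sep = "\r")
  key_b <- paste(pairs_b$mirna, pairs_b$gene, sep = "\r")
  keep <- !duplicated(key_a) & key_a %in% key_b
  out <- data.frame(mirna = pairs_a$mirna[keep], gene = pairs_a$gene[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate candidate targets against knockout fold changes
#'
#' When a miRNA is knocked out, genuine targets should be de-repressed
#' (linear fold change above 1). The statistic is the fraction of candidate
#' genes whose fold change exceeds the primary threshold (first element of
#' `thresholds`, default 1.3); its significance is assessed by drawing
#' same-size gene sets from the background of all predicted targets with
#' fold-change data and counting draws whose fraction reaches the observed
#' one, with add-one smoothing.
#'
#' @param candidates Character vector of candidate target genes (a subset
#'   of `background`).
#' @param fc Fold-change table (columns `gene`, `linear_fc`); genes without
#'   fold-change data are dropped from both sets with a warning.
#' @param background Character vector: all predicted targets eligible for
#'   random draws.
#' @param thresholds Linear fold-change thresholds, primary first
#'   (default `c(1.3, 1.5)`).
#' @param n_permutations Number of random draws (default 1000).
#' @param seed Integer seed.
#' @param statistic `"fraction"` (default) or `"mean_fc"`.
#' @return A list of class `knockout_validation` with per-threshold counts,
#'   `fraction_above_primary`, `permutation_p`, the gene sets used and the
#'   dropped genes.
#' @export
validate_against_knockout <- function(candidates, fc, background,
                                      thresholds = c(1.3, 1.5),
                                      n_permutations = 1000, seed = 1L,
                                      statistic = c("fraction", "mean_fc")) {
  statistic <- match.arg(statistic)
  candidates <- unique(candidates)
  background <- unique(background)
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background", call. = FALSE)
  fcv <- stats::setNames(fc$linear_fc, fc$gene)
  dropped <- setdiff(background, names(fcv))
  if (length(dropped))
    warning(length(dropped), " gene(s) without fold-change data dropped")
  background <- intersect(background, names(fcv))
  candidates <- intersect(candidates, background)
  if (!length(candidates))
    stop("no candidate gene has fold-change data", call. = FALSE)

  cand_fc <- fcv[candidates]
  counts <- vapply(thresholds, function(th) sum(cand_fc > th), integer(1L))
  names(counts) <- paste0("fc_gt_", thresholds)
  primary <- thresholds[1L]
  obs <- if (statistic == "fraction") mean(cand_fc > primary) else
    mean(cand_fc)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  null_stat <- vapply(seq_len(n_permutations), function(b) {
    draw <- fcv[sample(background, length(candidates))]
    if (statistic == "fraction") mean(draw > primary) else mean(draw)
  }, numeric(1L))
  p <- (1 + sum(null_stat >= obs)) / (1 + n_permutations)

  structure(list(candidate_genes = candidates, background_genes = background,
                 fc_thresholds = thresholds, counts_above = counts,
                 fraction_above_primary = mean(cand_fc > primary),
                 observed_statistic = obs, statistic = statistic,
                 permutation_p = p, n_permutations = n_permutations,
                 seed = as.integer(seed), dropped_genes = dropped),
            class = "knockout_validation")
}

#' @export
print.knockout_validation <- function(x, ...) {
  cat(sprintf(
    "<knockout_validation> %d/%d candidates (%.1f%%) above FC %.2g; p = %.3g\n",
    x$counts_above[1L], length(x$candidate_genes),
    100 * x$fraction_above_primary, x$fc_thresholds[1L], x$permutation_p))
  invisible(x)
}

#' Generic over-representation test on user-supplied gene sets
#'
#' Hypergeometric upper-tail test of each annotation term's gene set
#' against a query set, BH-adjusted across terms. A stand-in for
#' ontology-based enrichment when no live annotation database is in scope:
#' terms are whatever gene groupings the caller supplies.
#'
#' @param gene_set Character vector: the query genes (subset of universe).
#' @param annotation Named list of character vectors, term -> gene set.
#' @param universe Character vector of all eligible genes.
#' @return Data.frame with `term`, `n_term`, `overlap`, `p`, `p_adj`,
#'   ordered by increasing p.
#' @export
over_representation <- function(gene_set, annotation, universe) {
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  if (!all(unlist(annotation) %in% universe))
    stop("annotation gene sets must be subsets of the universe",
         call. = FALSE)
  empty <- vapply(annotation, function(g) length(g) == 0L, logical(1L))
  if (any(empty)) {
    warning("skipping term(s) with empty gene set: ",
            paste(names(annotation)[empty], collapse = ", "))
    annotation <- annotation[!empty]
  }
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(unique(annotation[[term]]), universe)
    ov <- length(intersect(tg, gene_set))
    p <- stats::phyper(ov - 1, length(tg), length(universe) - length(tg),
                       length(gene_set), lower.tail = FALSE)
    data.frame(term = term, n_term = length(tg), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
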