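#' Per-cell-type mean expression
#'
#' Collapses a sample-level matrix to per-analysis-cell-type mean log2
#' expression, the basis of the detection filter, the specificity caller
#' and the correlation profiles.
#'
#' @param x An [expr_matrix()].
#' @param meta Sample metadata (one row per column of `x`).
#' @param scheme A [cell_scheme()].
#' @return Numeric matrix, transcripts x analysis cell types (scheme order,
#'   restricted to cell types present in the data).
#' @export
cell_type_means <- function(x, meta, scheme = default_cell_scheme()) {
  meta <- check_metadata(x, meta)
  lab <- analysis_labels(meta, scheme)
  types <- scheme$cell_types[scheme$cell_types %in% lab]
  out <- vapply(types, function(ct)
    rowMeans(x[, lab == ct, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, 1L, dimnames = list(rownames(x), types))
  out
}

#' Detection filter at a log2 expression floor
#'
#' Keeps transcripts whose mean log2 expression reaches the detection
#' threshold (default 7, inclusive) in at least one analysis cell type;
#' everything below the floor in every cell type is treated as unexpressed
#' background. Idempotent: re-filtering the kept set changes nothing.
#'
#' @inheritParams cell_type_means
#' @param threshold Log2 detection floor (default 7).
#' @return A list of class `detection_filter` with `kept_transcripts`,
#'   `threshold`, `basis` (the per-cell-type mean matrix), `n_total`,
#'   `n_kept`.
#' @export
detection_filter <- function(x, meta, scheme = default_cell_scheme(),
                             threshold = 7) {
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("empty expression matrix", call. = FALSE)
  m <- cell_type_means(x, meta, scheme)
  keep <- apply(m, 1L, max) >= threshold
  structure(list(kept_transcripts = rownames(x)[keep], threshold = threshold,
                 basis = m, n_total = nrow(x), n_kept = sum(keep)),
            class = "detection_filter")
}

#' @export
print.detection_filter <- function(x, ...) {
  cat(sprintf("<detection_filter> %d / %d transcripts >= %.3g in >= 1 cell type\n",
              x$n_kept, x$n_total, x$threshold))
  invisible(x)
}

#' Apply a detection filter to an expression matrix
#'
#' @param x An [expr_matrix()].
#' @param filter A `detection_filter`.
#' @return The row-subset `expr_matrix`.
#' @export
apply_detection_filter <- function(x, filter) {
  expr_matrix(unclass(x)[filter$kept_transcripts, , drop = FALSE],
              platform(x))
}

#' Flag outlying samples on the first two principal components
#'
#' Centers each transcript, computes sample scores on PC1/PC2, and flags
#' samples whose absolute score exceeds `k_sd` standard deviations of the
#' scores on either component. The flags are advisory: callers decide
#' whether to drop the samples.
#'
#' @param x An [expr_matrix()] with at least 3 samples.
#' @param k_sd Flagging multiplier (default 3; `Inf` flags nothing).
#' @return A list of class `outlier_report` with `flagged_samples` (a
#'   data.frame of sample, PC1, PC2), `k_sd` and the full `scores` matrix.
#' @export
flag_outliers_pca <- function(x, k_sd = 3) {
  if (ncol(x) < 3L)
    stop("PCA outlier flagging needs >= 3 samples", call. = FALSE)
  pc <- stats::prcomp(t(unclass(x)), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  sds <- apply(scores, 2L, stats::sd)
  bad <- rep(FALSE, nrow(scores))
  for (j in seq_len(ncol(scores)))
    if (is.finite(k_sd) && sds[j] > 0)
      bad <- bad | abs(scores[, j]) > k_sd * sds[j]
  flagged <- data.frame(sample = rownames(scores)[bad],
                        scores[bad, , drop = FALSE], row.names = NULL)
  structure(list(flagged_samples = flagged, k_sd = k_sd, scores = scores),
            class = "outlier_report")
}

#' Z-score cell-type expression profiles
#'
#' Collapses to per-cell-type means, then centers and scales each
#' transcript's profile to zero mean and unit variance across cell types
#' (sample standard deviation, n-1 denominator). Constant profiles cannot
#' be scaled; they map to all-zero rows and are flagged in the
#' `"degenerate"` attribute so correlation steps can exclude them.
#'
#' @inheritParams cell_type_means
#' @return Numeric matrix transcripts x cell types with attribute
#'   `degenerate` (logical per transcript).
#' @export
ztransform_profiles <- function(x, meta, scheme = default_cell_scheme()) {
  m <- cell_type_means(x, meta, scheme)
  if (ncol(m) < 2L)
    stop("z-transform needs >= 2 analysis cell types", call. = FALSE)
  zscore_rows(m)
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  degen <- s == 0
  z <- (m - mu) / ifelse(degen, 1, s)
  z[degen, ] <- 0
  attr(z, "degenerate") <- stats::setNames(degen, rownames(m))
  z
}

#' Z-score sample-level profiles on a matched sample axis
#'
#' Alternative correlation basis to the per-cell-type means of
#' [ztransform_profiles()]: each transcript's profile is its z-scored
#' vector of per-sample values, with samples ordered by (analysis cell
#' type, donor pool) and relabelled by that composite key so that miRNA
#' and mRNA matrices assayed on the same donor pools share an identical
#' profile axis even when their platform sample identifiers differ. With
#' ~40 samples the permutation null of a Pearson correlation is far
#' tighter than with 8 cell-type means, which is what makes a stringent
#' permutation FDR attainable.
#'
#' @inheritParams cell_type_means
#' @return Numeric matrix transcripts x matched samples (columns named
#'   `cellType.pool`), with a `degenerate` attribute as in
#'   [ztransform_profiles()].
#' @export
matched_sample_profiles <- function(x, meta, scheme = default_cell_scheme()) {
  meta <- check_metadata(x, meta)
  lab <- analysis_labels(meta, scheme)
  key <- paste(lab, meta$donor_pool, sep = ".")
  if (anyDuplicated(key))
    stop("duplicate (cell type, donor pool) combination: ",
         key[duplicated(key)][1L], call. = FALSE)
  ord <- order(match(lab, scheme$cell_types), meta$donor_pool)
  m <- unclass(x)[, ord, drop = FALSE]
  colnames(m) <- key[ord]
  zscore_rows(m)
}
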