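#' Pearson correlation of every miRNA x mRNA profile pair
#'
#' Takes two z-scored cell-type-profile matrices sharing the same ordered
#' cell-type axis (see [ztransform_profiles()]) and returns the full
#' cross-product of Pearson correlations. Degenerate (constant) profiles
#' have no defined correlation; their pairs are recorded with \code{r = NA}
#' and are excluded by every downstream consumer.
#'
#' @param mirna_profiles,mrna_profiles Matrices transcripts x cell types,
#'   identical column order.
#' @return Data.frame of class `correlation_table` with columns `mirna`,
#'   `mrna`, `r`.
#' @export
correlate_pairs <- function(mirna_profiles, mrna_profiles) {
  if (!identical(colnames(mirna_profiles), colnames(mrna_profiles)))
    stop("profile matrices must share the same ordered cell-type axis",
         call. = FALSE)
  r <- pair_cor_matrix(mirna_profiles, mrna_profiles)
  out <- data.frame(
    mirna = rep(rownames(mirna_profiles), times = nrow(mrna_profiles)),
    mrna = rep(rownames(mrna_profiles), each = nrow(mirna_profiles)),
    r = as.vector(r), stringsAsFactors = FALSE)
  class(out) <- c("correlation_table", "data.frame")
  out
}

# rows(A) x rows(B) Pearson correlation; constant rows give NA.
pair_cor_matrix <- function(A, B) {
  suppressWarnings(stats::cor(t(A), t(B)))
}

#' Calibrate the negative-correlation cutoff by permutation
#'
#' Estimates, for a grid of candidate negative cutoffs, the false discovery
#' rate of calling a pair "repressive" at that cutoff: in each permutation
#' round the cell-type axis of the entire mRNA profile matrix is permuted
#' once (preserving the mRNA-mRNA correlation structure), all pairwise
#' correlations are recomputed, and FDR(c) is the mean permutation count of
#' pairs below c divided by the observed count (floored at 1). The chosen
#' cutoff is the most lenient candidate (closest to zero) whose estimated
#' FDR is at or below `target_fdr`; if none qualifies the cutoff is `NA`
#' and the caller decides using the returned FDR curve.
#'
#' @inheritParams correlate_pairs
#' @param target_fdr Target false discovery rate (default 0.01).
#' @param n_permutations Number of permutation rounds (default 100).
#' @param grid Candidate cutoffs, negative (default -0.05 to -0.95 by 0.05).
#' @param seed Integer seed making the permutations reproducible.
#' @return A list of class `cutoff_result`: `cutoff`, `target_fdr`,
#'   `n_permutations`, `fdr_curve` (data.frame cutoff / n_observed /
#'   mean_null / fdr), `seed`.
#' @export
calibrate_cutoff <- function(mirna_profiles, mrna_profiles,
                             target_fdr = 0.01, n_permutations = 100,
                             grid = seq(-0.05, -0.95, by = -0.05),
                             seed = 1L) {
  if (ncol(mirna_profiles) < 4L)
    stop("cutoff calibration needs >= 4 profile points", call. = FALSE)
  if (any(grid >= 0)) stop("candidate cutoffs must be negative", call. = FALSE)
  grid <- sort(grid, decreasing = TRUE)

  r_obs <- as.vector(pair_cor_matrix(mirna_profiles, mrna_profiles))
  r_obs <- r_obs[!is.na(r_obs)]
  n_obs <- vapply(grid, function(c) sum(r_obs < c), numeric(1L))

  C <- ncol(mrna_profiles)
  null_counts <- matrix(0, n_permutations, length(grid))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(C)
    r_p <- as.vector(pair_cor_matrix(mirna_profiles,
                                     mrna_profiles[, perm, drop = FALSE]))
    r_p <- r_p[!is.na(r_p)]
    null_counts[b, ] <- vapply(grid, function(c) sum(r_p < c), numeric(1L))
  }
  mean_null <- colMeans(null_counts)
  fdr <- mean_null / pmax(1, n_obs)
  ok <- which(fdr <= target_fdr)
  cutoff <- if (length(ok)) grid[ok[1L]] else NA_real_
  structure(list(cutoff = cutoff, target_fdr = target_fdr,
                 n_permutations = n_permutations,
                 fdr_curve = data.frame(cutoff = grid, n_observed = n_obs,
                                        mean_null = mean_null, fdr = fdr),
                 seed = as.integer(seed)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> cutoff = %s at FDR <= %g (%d permutations)\n",
              ifelse(is.na(x$cutoff), "undefined", format(x$cutoff)),
              x$target_fdr, x$n_permutations))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}
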