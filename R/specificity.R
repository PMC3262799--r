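#' Parameters for the cell-type specificity caller
#'
#' @param alpha Significance level for all gates (default 0.05).
#' @param min_fold_change Linear fold-change gate between the k-th and
#'   (k+1)-th ranked cell type. `NULL` resolves at call time to 4 for mRNA
#'   and 1 (disabled) for miRNA, matching the asymmetric design: mRNA calls
#'   require at least a 4-fold separation, miRNA calls impose no fold gate.
#' @param detection_threshold Log2 floor (default 7): up-calls require all
#'   specific cell types at or above it, down-calls require all
#'   non-specific cell types at or above it.
#' @param max_k Largest specificity order considered (default 3).
#' @param require_overall_anova If `TRUE` (default) a transcript must first
#'   pass a one-way ANOVA across all analysis cell types at BH-adjusted
#'   p < alpha (adjusted across transcripts).
#' @param homogeneity_gate If `TRUE` (default) a k >= 2 call additionally
#'   requires the top-k (or bottom-k) cell types to be statistically
#'   homogeneous: their restricted one-way ANOVA must have unadjusted
#'   p >= alpha.
#' @param boundary_test `"welch"` (default) or `"pooled"`: the two-group
#'   contrast between the k-th and (k+1)-th ranked cell types.
#' @return A list of class `specificity_params`.
#' @export
specificity_params <- function(alpha = 0.05, min_fold_change = NULL,
                               detection_threshold = 7, max_k = 3,
                               require_overall_anova = TRUE,
                               homogeneity_gate = TRUE,
                               boundary_test = c("welch", "pooled")) {
  stopifnot(alpha > 0, alpha < 1, is.null(min_fold_change) ||
              min_fold_change >= 1, max_k >= 1)
  structure(list(alpha = alpha, min_fold_change = min_fold_change,
                 detection_threshold = detection_threshold, max_k = max_k,
                 require_overall_anova = require_overall_anova,
                 homogeneity_gate = homogeneity_gate,
                 boundary_test = match.arg(boundary_test)),
            class = "specificity_params")
}

# One-way ANOVA p-values from per-group sufficient statistics.
# m, v: transcripts x groups matrices of means and sample variances;
# n: per-group sample sizes. Equivalent to anova(lm(y ~ group)).
anova_from_stats <- function(m, v, n) {
  N <- sum(n)
  C <- length(n)
  grand <- as.vector(m %*% n) / N
  ssb <- as.vector(((m - grand)^2) %*% n)
  ssw <- as.vector(v %*% (n - 1))
  f <- (ssb / (C - 1)) / (ssw / (N - C))
  p <- stats::pf(f, C - 1, N - C, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1  # totally constant data carries no signal
  p
}

# Two-sided two-sample t p-value from sufficient statistics (vectorised).
two_group_p <- function(m1, v1, n1, m2, v2, n2, pooled = FALSE) {
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    a <- v1 / n1
    b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  p
}

#' Call transcripts specifically up- or down-regulated in 1..max_k cell types
#'
#' The hierarchical rank-and-test classifier. Per transcript: cell types are
#' ranked by mean log2 expression (descending for up-calls, ascending for
#' down-calls; ties broken by cell-type name). For k = 1, 2, ..., `max_k`
#' in order, a call at k requires (a) detection -- every specific cell type
#' (up) or every non-specific cell type (down) at or above the log2 floor;
#' (b) homogeneity within the candidate top/bottom group (vacuous at k = 1);
#' (c) a significant boundary contrast between the k-th and (k+1)-th ranked
#' cell types at BH-adjusted p < alpha, adjusted across all transcripts'
#' boundary tests of that direction and k; and (d) the linear fold change
#' across the boundary at or above the platform's gate. The smallest k that
#' satisfies all gates wins; a transcript carries at most one up and one
#' down call.
#'
#' @inheritParams cell_type_means
#' @param params A [specificity_params()].
#' @return A data.frame of class `specificity_calls` with columns
#'   `transcript`, `platform`, `direction`, `k`, `specific_cell_types`
#'   (semicolon-joined, rank order), `fold_change` (linear, boundary),
#'   `p` (raw boundary p), `p_adj` (the BH-adjusted p*), `mean_expr`
#'   (semicolon-joined log2 means over the specific cell types).
#' @export
call_specificity <- function(x, meta, scheme = default_cell_scheme(),
                             params = specificity_params()) {
  meta <- check_metadata(x, meta)
  lab <- analysis_labels(meta, scheme)
  types <- scheme$cell_types[scheme$cell_types %in% lab]
  n <- vapply(types, function(ct) sum(lab == ct), integer(1L))
  small <- names(n)[n < 2L]
  if (length(small))
    stop("cell type with < 2 samples: ", small[1L], call. = FALSE)
  plat <- platform(x)
  min_fc <- params$min_fold_change
  if (is.null(min_fc)) min_fc <- if (identical(plat, "mrna")) 4 else 1

  vals <- unclass(x)
  C <- length(types)
  Tn <- nrow(vals)
  M <- vapply(types, function(ct)
    rowMeans(vals[, lab == ct, drop = FALSE]), numeric(Tn))
  V <- vapply(types, function(ct)
    apply(vals[, lab == ct, drop = FALSE], 1L, stats::var), numeric(Tn))
  if (Tn == 1L) {
    M <- matrix(M, 1L, C, dimnames = list(rownames(vals), types))
    V <- matrix(V, 1L, C, dimnames = list(rownames(vals), types))
  }

  p_overall <- anova_from_stats(M, V, n)
  pass0 <- if (params$require_overall_anova)
    stats::p.adjust(p_overall, "BH") < params$alpha else rep(TRUE, Tn)

  max_k <- min(params$max_k, C - 1L)
  calls <- list()

  for (direction in c("up", "down")) {
    ord <- t(apply(M, 1L, function(m)
      if (direction == "up") order(-m, types) else order(m, types)))
    if (Tn == 1L) ord <- matrix(ord, 1L)
    done <- rep(FALSE, Tn)
    # gates (a),(b),(d) and raw boundary p for every k, then BH per k
    for (k in seq_len(max_k)) {
      ik <- ord[, k]
      inext <- ord[, k + 1L]
      pick <- function(mat, idx) mat[cbind(seq_len(Tn), idx)]
      m_k <- pick(M, ik);    v_k <- pick(V, ik);    n_k <- n[ik]
      m_n <- pick(M, inext); v_n <- pick(V, inext); n_n <- n[inext]

      p_raw <- two_group_p(m_k, v_k, n_k, m_n, v_n, n_n,
                           pooled = params$boundary_test == "pooled")
      p_adj <- rep(NA_real_, Tn)
      p_adj[pass0] <- stats::p.adjust(p_raw[pass0], "BH")

      if (direction == "up") {
        detect <- m_k >= params$detection_threshold
        fold <- 2^(m_k - m_n)
      } else {
        detect <- m_n >= params$detection_threshold  # ranked ascending:
        # the (k+1)-th is the lowest of the non-specific types
        fold <- 2^(m_n - m_k)
      }
      if (k >= 2L && params$homogeneity_gate) {
        homog <- vapply(seq_len(Tn), function(t) {
          idx <- ord[t, seq_len(k)]
          anova_from_stats(M[t, idx, drop = FALSE],
                           V[t, idx, drop = FALSE], n[idx])
        }, numeric(1L)) >= params$alpha
      } else homog <- rep(TRUE, Tn)

      hit <- !done & pass0 & detect & homog & fold >= min_fc &
        !is.na(p_adj) & p_adj < params$alpha
      if (any(hit)) {
        for (t in which(hit)) {
          idx <- ord[t, seq_len(k)]
          calls[[length(calls) + 1L]] <- data.frame(
            transcript = rownames(vals)[t], platform = plat,
            direction = direction, k = k,
            specific_cell_types = paste(types[idx], collapse = ";"),
            fold_change = fold[t], p = p_raw[t], p_adj = p_adj[t],
            mean_expr = paste(sprintf("%.4g", M[t, idx]), collapse = ";"),
            stringsAsFactors = FALSE)
        }
        done <- done | hit
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(transcript = character(), platform = character(),
               direction = character(), k = integer(),
               specific_cell_types = character(), fold_change = numeric(),
               p = numeric(), p_adj = numeric(), mean_expr = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$direction, out$k, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("specificity_calls", "data.frame")
  out
}

#' Tabulate specificity calls
#'
#' Builds the two summary contingency tables of a specificity analysis:
#' counts of up-/down-regulated transcripts by specificity order k (with
#' row and column totals) and, for single-cell-type calls, counts by cell
#' type and direction.
#'
#' @param calls A `specificity_calls` data.frame.
#' @param cell_types Optional character vector fixing the cell-type rows of
#'   the second table (defaults to the cell types observed in the calls).
#' @return A list with data.frames `by_k` and `by_cell_type`.
#' @export
summarize_calls <- function(calls, cell_types = NULL) {
  ks <- 1:3
  up <- vapply(ks, function(k)
    sum(calls$direction == "up" & calls$k == k), integer(1L))
  dn <- vapply(ks, function(k)
    sum(calls$direction == "down" & calls$k == k), integer(1L))
  by_k <- data.frame(k = c(ks, NA), n_up = c(up, sum(up)),
                     n_down = c(dn, sum(dn)),
                     n_total = c(up + dn, sum(up) + sum(dn)))
  one <- calls[calls$k == 1L, , drop = FALSE]
  cts <- if (is.null(cell_types)) sort(unique(one$specific_cell_types))
         else cell_types
  by_ct <- data.frame(
    cell_type = cts,
    n_up = vapply(cts, function(ct) sum(one$direction == "up" &
      one$specific_cell_types == ct), integer(1L)),
    n_down = vapply(cts, function(ct) sum(one$direction == "down" &
      one$specific_cell_types == ct), integer(1L)),
    row.names = NULL)
  list(by_k = by_k, by_cell_type = by_ct)
}
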