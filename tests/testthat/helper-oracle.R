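# Independent oracle: re-evaluates the rank-and-test rules with stats::lm /
# stats::t.test loops on small instances, sharing no code with the
# vectorised implementation.
oracle_calls <- function(x, meta, scheme, alpha = 0.05, min_fc = 1,
                         thr = 7, max_k = 3, homogeneity = TRUE) {
  vals <- unclass(x)
  lab <- meta$cell_type
  types <- scheme$cell_types
  C <- length(types)
  p_over <- apply(vals, 1, function(v)
    stats::anova(stats::lm(v ~ factor(lab)))[["Pr(>F)"]][1])
  pass0 <- stats::p.adjust(p_over, "BH") < alpha
  out <- list()
  for (direction in c("up", "down")) {
    claimed <- rep(FALSE, nrow(vals))
    for (k in seq_len(min(max_k, C - 1))) {
      info <- lapply(seq_len(nrow(vals)), function(t) {
        m <- vapply(types, function(ct) mean(vals[t, lab == ct]),
                    numeric(1))
        ord <- if (direction == "up") order(-m, types) else order(m, types)
        top <- types[ord[seq_len(k)]]
        nxt <- types[ord[k + 1]]
        p_b <- stats::t.test(vals[t, lab == types[ord[k]]],
                             vals[t, lab == nxt])$p.value
        detect <- if (direction == "up") all(m[top] >= thr) else
          all(m[types[ord[(k + 1):C]]] >= thr)
        homog <- if (k == 1 || !homogeneity) TRUE else {
          sel <- lab %in% top
          stats::anova(stats::lm(vals[t, sel] ~
                                   factor(lab[sel])))[["Pr(>F)"]][1] >= alpha
        }
        fold <- if (direction == "up") 2^(m[types[ord[k]]] - m[nxt]) else
          2^(m[nxt] - m[types[ord[k]]])
        list(top = top, p_b = p_b, detect = detect, homog = homog,
             fold = fold)
      })
      p_adj <- rep(NA_real_, nrow(vals))
      p_adj[pass0] <- stats::p.adjust(
        vapply(info, `[[`, numeric(1), "p_b")[pass0], "BH")
      for (t in seq_len(nrow(vals))) {
        i <- info[[t]]
        if (!claimed[t] && pass0[t] && i$detect && i$homog &&
            i$fold >= min_fc && !is.na(p_adj[t]) && p_adj[t] < alpha) {
          claimed[t] <- TRUE
          out[[length(out) + 1]] <- data.frame(
            transcript = rownames(vals)[t], direction = direction, k = k,
            specific_cell_types = paste(i$top, collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(transcript = character(), direction = character(),
               k = integer(), specific_cell_types = character())
}
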