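# Independent, naively-written oracles used to cross-check the production
# implementations. Each one follows the definition directly, with no code
# shared with the package internals.

# Mann-Whitney AUC by explicit pair counting: concordant pairs plus half the
# ties, over all (positive, negative) pairs.
oracle_mw_auc <- function(scores, labels) {
  pos <- scores[labels == "morf"]
  neg <- scores[labels == "non_morf"]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp) / (length(pos) * length(neg))
}

# FPR at a TPR target by exhaustive scan over every candidate threshold
# (all distinct scores), calling positive at score >= t.
oracle_fpr_at_tpr <- function(scores, labels, target) {
  n_pos <- sum(labels == "morf")
  n_neg <- sum(labels == "non_morf")
  best <- Inf
  for (t in unique(scores)) {
    tpr <- sum(scores >= t & labels == "morf") / n_pos
    fpr <- sum(scores >= t & labels == "non_morf") / n_neg
    if (tpr >= target && fpr < best) best <- fpr
  }
  best
}

# Per-residue re-statement of the two mcs scenarios, written as literal
# loops over each residue's centered (truncated) windows.
oracle_mcs <- function(ics, dis, p = morffuse::mcs_params()) {
  L <- length(ics)
  out <- numeric(L)
  h1 <- (p$disorder_window - 1) / 2
  h2 <- (p$structured_window - 1) / 2
  for (r in seq_len(L)) {
    w1 <- max(1, r - h1):min(L, r + h1)
    w2 <- max(1, r - h2):min(L, r + h2)
    conserved <- w1[ics[w1] > p$ics_conserved]
    k <- length(conserved)
    if (mean(dis[w1]) > p$disorder_hi && k >= p$min_conserved) {
      m <- mean(ics[conserved])
      extra <- k - p$min_conserved
      if (p$root_per_extra) {
        for (j in seq_len(2 * extra)) m <- sqrt(m)
      } else if (extra > 0) {
        m <- sqrt(sqrt(m))
      }
      out[r] <- m
    } else if (mean(dis[w2]) < p$disorder_lo && all(ics[w2] <= p$ics_cap)) {
      out[r] <- ics[r] * mean(dis[w2])
    } else {
      out[r] <- ics[r]
    }
  }
  out
}

# Run extraction by a literal scan.
oracle_runs <- function(score, cutoff) {
  above <- score >= cutoff
  runs <- list()
  start <- NA
  for (i in seq_along(above)) {
    if (above[i] && is.na(start)) start <- i
    if (!above[i] && !is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(above))
  if (length(runs) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}
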