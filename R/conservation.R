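# Conservation scoring: the initial conservation propensity score (ics) from
# the three PSSM features, and the MoRF conservation propensity score (mcs)
# that smooths ics with two window-based scenarios so that the high
# conservation of binding residues is extended across putative MoRFs.

#' Parameters of the MoRF-conservation smoothing rules
#'
#' Window sizes and thresholds of the two mcs scenarios, exposed with the
#' method's published values as defaults:
#'
#' * Scenario 1 (disordered, conserved window): a residue at the center of a
#'   `disorder_window` (7) whose average normalized disorder exceeds
#'   `disorder_hi` (0.45) and which contains at least `min_conserved` (3)
#'   residues with ics above `ics_conserved` (0.45) gets the mean ics of
#'   those conserved residues; for every conserved residue beyond
#'   `min_conserved`, a square root is applied twice more, i.e. the mean is
#'   raised to the power `(1/4)^(k - min_conserved)`, which pushes the score
#'   toward 1.
#' * Scenario 2 (structured, unconserved window): a residue at the center of
#'   a `structured_window` (15) whose average normalized disorder is below
#'   `disorder_lo` (0.45) and in which no residue has ics above `ics_cap`
#'   (0.60) gets its ics multiplied by the window's average disorder.
#' * All other residues keep their ics unchanged.
#'
#' `root_per_extra = FALSE` selects the alternative reading of the boost in
#' which the square root is applied twice in total whenever the window holds
#' more than `min_conserved` conserved residues, regardless of how many.
#'
#' @param disorder_window,structured_window Odd window sizes (residues).
#' @param disorder_hi,disorder_lo Disorder-average thresholds in (0, 1).
#' @param ics_conserved,ics_cap ics thresholds in (0, 1).
#' @param min_conserved Minimum conserved residues for scenario 1.
#' @param root_per_extra Apply the double square root once per extra
#'   conserved residue (default) or once in total?
#' @return An `mcs_params` object (a validated list).
#' @export
mcs_params <- function(disorder_window = 7L, structured_window = 15L,
                       disorder_hi = 0.45, ics_conserved = 0.45,
                       min_conserved = 3L, ics_cap = 0.60,
                       disorder_lo = 0.45, root_per_extra = TRUE) {
  p <- list(
    disorder_window = as.integer(disorder_window),
    structured_window = as.integer(structured_window),
    disorder_hi = disorder_hi, ics_conserved = ics_conserved,
    min_conserved = as.integer(min_conserved), ics_cap = ics_cap,
    disorder_lo = disorder_lo, root_per_extra = isTRUE(root_per_extra)
  )
  for (w in c(p$disorder_window, p$structured_window)) {
    if (w < 3L || w %% 2L == 0L) abort("Window sizes must be odd and >= 3.")
  }
  for (th in c(p$disorder_hi, p$ics_conserved, p$ics_cap, p$disorder_lo)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) abort("Thresholds must lie in (0, 1).")
  }
  if (p$min_conserved < 1L) abort("`min_conserved` must be >= 1.")
  structure(p, class = "mcs_params")
}

#' @export
print.mcs_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<mcs_params>\n",
      "  scenario 1: window %d, mean disorder > %.2f, >= %d residues with ics > %.2f (%s)\n",
      "  scenario 2: window %d, mean disorder < %.2f, all ics <= %.2f\n"
    ),
    x$disorder_window, x$disorder_hi, x$min_conserved, x$ics_conserved,
    if (x$root_per_extra) "double sqrt per extra conserved residue" else "double sqrt once if any extra",
    x$structured_window, x$disorder_lo, x$ics_cap
  ))
  invisible(x)
}

# Rolling window statistics with windows truncated at the sequence ends (the
# center residue is always included; averages run over the residues actually
# present). mean() is used per window — not a running-sum shortcut — so that
# threshold comparisons at values like 0.45 are the exact comparisons of the
# rule definitions, free of cumulative rounding drift.
win_mean <- function(x, w) {
  zoo::rollapply(x, width = w, FUN = mean, partial = TRUE, align = "center")
}

win_max <- function(x, w) {
  zoo::rollapply(x, width = w, FUN = max, partial = TRUE, align = "center")
}

#' Initial conservation propensity score
#'
#' Bayes-combines the three normalized PSSM conservation tracks —
#' information per position, the *complemented* relative weight (see
#' [complement_track()]), and the query-residue weighted observed
#' percentage — into the initial conservation score ics. When `map` is
#' supplied (an ics normalization map fitted on training data), the combined
#' score is re-normalized so that the downstream mcs thresholds 0.45/0.60
#' act on the quantile-meaningful (0, 1) scale; without a map the raw
#' combination is returned.
#'
#' @param ipp_n,rwgrmp_n,wop_n Normalized tracks for the three features;
#'   `rwgrmp_n` must already be complemented.
#' @param map Optional `norm_map` for the combined ics score.
#' @return A residue track named `"ics"` (normalized when `map` is given,
#'   raw otherwise).
#' @export
compute_ics <- function(ipp_n, rwgrmp_n, wop_n, map = NULL) {
  combined <- bayes_combine(list(ipp_n, rwgrmp_n, wop_n), feature = "ics")
  if (is.null(map)) {
    return(combined)
  }
  apply_map(map, combined, check_feature = FALSE)
}

# The square-root boost is applied as literal repeated sqrt() calls (not as
# a single power), so the arithmetic is exactly the iterated operation the
# rule describes.
boost_root <- function(m, extra, per_extra) {
  times <- if (per_extra) 2L * extra else if (extra > 0L) 2L else 0L
  for (i in seq_len(times)) m <- sqrt(m)
  m
}

mcs_vector <- function(ics, dis, p) {
  L <- length(ics)
  avg_d_small <- win_mean(dis, p$disorder_window)
  avg_d_big <- win_mean(dis, p$structured_window)
  conserved <- ics > p$ics_conserved
  max_big <- win_max(ics, p$structured_window)
  h1 <- (p$disorder_window - 1L) %/% 2L

  out <- ics
  scen1_possible <- avg_d_small > p$disorder_hi
  for (r in which(scen1_possible)) {
    w <- max(1L, r - h1):min(L, r + h1)
    cons <- w[conserved[w]]
    k <- length(cons)
    if (k >= p$min_conserved) {
      out[r] <- boost_root(mean(ics[cons]), k - p$min_conserved, p$root_per_extra)
    } else {
      scen1_possible[r] <- FALSE
    }
  }
  scen2 <- !scen1_possible & avg_d_big < p$disorder_lo & max_big <= p$ics_cap
  out[scen2] <- ics[scen2] * avg_d_big[scen2]
  out
}

#' MoRF conservation propensity score
#'
#' Smooths the ics track with the two window-based scenarios of
#' [mcs_params()], per sequence. Scenario 1 (conserved residues inside a
#' disordered window) is evaluated first and wins when both scenarios could
#' apply; residues matching neither keep their ics. Windows are truncated at
#' sequence ends. Both threshold comparisons are strict, so a disorder track
#' constant at exactly 0.45 fires neither scenario.
#'
#' @param ics Normalized ics track (from [compute_ics()] with a map).
#' @param disorder_n Normalized disorder track for the same sequences.
#' @param params An [mcs_params()] object.
#' @return A normalized residue track named `"mcs"`.
#' @export
compute_mcs <- function(ics, disorder_n, params = mcs_params()) {
  stopifnot(inherits(params, "mcs_params"))
  assert_track(ics, space = "normalized", single_feature = TRUE, arg = "ics")
  assert_track(disorder_n, space = "normalized", single_feature = TRUE, arg = "disorder_n")
  ics <- dplyr::arrange(ics, .data$seq_id, .data$pos)
  disorder_n <- dplyr::arrange(disorder_n, .data$seq_id, .data$pos)
  check_same_grid(list(ics, disorder_n))
  out <- ics |>
    dplyr::mutate(.dis = disorder_n$score) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::mutate(score = mcs_vector(.data$score, .data$.dis, params)) |>
    dplyr::ungroup() |>
    dplyr::select(-".dis") |>
    dplyr::mutate(feature = "mcs", space = "normalized")
  assert_track(out, space = "normalized")
  out
}
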