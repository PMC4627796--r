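# Bayes-rule fusion of normalized propensity tracks. Each normalized score
# is treated as an independent class-conditional probability; with equal
# priors the two-class posterior is prod(p) / (prod(p) + prod(1 - p)).
# Computation runs in log-odds space so long products cannot underflow.

#' Log-odds transform of a normalized track
#'
#' Elementwise `ln(p / (1 - p))`. This is the numerically stable carrier for
#' Bayes products: [bayes_combine()] sums log-odds and applies the logistic
#' inverse. Scores at exactly 0 or 1 are errors (the normalization clip bound
#' excludes them).
#'
#' @param track A normalized-space residue track.
#' @return The track with log-odds scores, declared raw space.
#' @export
log_odds <- function(track) {
  assert_track(track, space = "normalized", arg = "track")
  dplyr::mutate(track, score = qlogis(.data$score), space = "raw")
}

#' Combine normalized tracks with Bayes rule
#'
#' Per residue, the equal-prior two-class posterior
#' `prod(p_i) / (prod(p_i) + prod(1 - p_i))` over all input tracks,
#' computed as the logistic inverse of the summed log-odds. A single track is
#' returned unchanged (one-element product). The result is declared **raw**:
#' in the prediction hierarchy every combined score is re-normalized under
#' its own map before entering the next fusion level, which is what keeps
#' extreme values from dominating subsequent combinations.
#'
#' All tracks must be in normalized space, with values strictly inside
#' (0, 1), and cover exactly the same sequences and positions.
#'
#' @param tracks A list of residue tracks, or one tibble holding several
#'   features in long form.
#' @param feature Feature name given to the combined track.
#' @return A raw-space residue track of the combined scores.
#' @examples
#' a <- residue_track("s", 1:2, c(0.8, 0.5), "a", "normalized")
#' b <- residue_track("s", 1:2, c(0.8, 0.5), "b", "normalized")
#' bayes_combine(list(a, b))$score # 0.9411765, 0.5
#' @export
bayes_combine <- function(tracks, feature = "combined") {
  tracks <- split_tracks(tracks)
  for (t in tracks) {
    assert_track(t, space = "normalized", arg = t$feature[[1]])
  }
  check_same_grid(tracks)
  ref <- tracks[[1]]
  lo <- Reduce(`+`, lapply(tracks, function(t) qlogis(t$score)))
  out <- residue_track(ref$seq_id, ref$pos, plogis(lo),
    feature = feature, space = "raw",
    aa = if ("aa" %in% names(ref)) ref$aa else NULL
  )
  out
}
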