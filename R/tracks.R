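#' Per-residue score tracks
#'
#' The package's central data structure is the *residue track*: a tibble with
#' one row per residue of one or more protein sequences and the columns
#'
#' * `feature`  — name of the scored feature (`"ipp"`, `"disorder"`, ...),
#' * `seq_id`   — sequence identifier,
#' * `pos`      — 1-based residue position,
#' * `score`    — real-valued propensity score,
#' * `space`    — `"raw"` (the feature's native scale) or `"normalized"`
#'   (the Gaussian N(0.5, 0.01) scale produced by [apply_map()]; values are
#'   then strictly inside (0, 1)).
#'
#' An optional `aa` column carries the residue letter so tracks can be
#' cross-checked against the FASTA they belong to. All track-consuming
#' functions in the package accept and return this shape, so results chain
#' with the pipe and ordinary dplyr verbs.
#'
#' @param seq_id Character vector of sequence identifiers (recycled).
#' @param pos Integer vector of 1-based positions.
#' @param score Numeric scores.
#' @param feature Single feature name.
#' @param space `"raw"` or `"normalized"`.
#' @param aa Optional character vector of residue letters.
#' @return A tibble with the track columns described above.
#' @examples
#' residue_track("s1", 1:3, c(0.1, 0.2, 0.3), feature = "ipp", space = "raw")
#' @export
residue_track <- function(seq_id, pos, score, feature, space = c("raw", "normalized"),
                          aa = NULL) {
  space <- match.arg(space)
  out <- tibble(
    feature = as.character(feature),
    seq_id = as.character(seq_id),
    pos = as.integer(pos),
    score = as.numeric(score),
    space = space
  )
  if (!is.null(aa)) out$aa <- as.character(aa)
  assert_track(out)
  out
}

#' Validate a residue track
#'
#' Checks that `x` has the track columns, optionally that it is declared in a
#' given score space, carries a single feature, and (for normalized tracks)
#' that scores lie strictly in (0, 1).
#'
#' @param x A data frame.
#' @param space If non-NULL, required declared space.
#' @param single_feature Require exactly one feature?
#' @param arg Name used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
assert_track <- function(x, space = NULL, single_feature = FALSE,
                         arg = deparse(substitute(x))) {
  need <- c("feature", "seq_id", "pos", "score", "space")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf(
      "`%s` is not a residue track: required columns are %s.",
      arg, paste0("`", need, "`", collapse = ", ")
    ))
  }
  if (nrow(x) == 0) abort(sprintf("`%s` is an empty track.", arg))
  sp <- unique(x$space)
  if (length(sp) != 1) abort(sprintf("`%s` mixes score spaces: %s.", arg, toString(sp)))
  if (!sp %in% c("raw", "normalized")) {
    abort(sprintf("`%s` has unknown score space '%s'.", arg, sp))
  }
  if (!is.null(space) && sp != space) {
    abort(sprintf("`%s` must be in %s space, but is declared %s.", arg, space, sp))
  }
  if (single_feature && length(unique(x$feature)) != 1) {
    abort(sprintf("`%s` must carry a single feature.", arg))
  }
  if (anyNA(x$score) || any(!is.finite(x$score))) {
    abort(sprintf("`%s` contains non-finite scores.", arg))
  }
  if (sp == "normalized" && (any(x$score <= 0) || any(x$score >= 1))) {
    abort(sprintf("`%s` is declared normalized but has scores outside (0, 1).", arg))
  }
  invisible(x)
}

#' Declared score space of a track
#' @param x A residue track.
#' @return `"raw"` or `"normalized"`.
#' @export
track_space <- function(x) {
  assert_track(x, arg = "x")
  unique(x$space)
}

# Split a track input (single multi-feature tibble or list of tracks) into a
# named list of single-feature tracks.
split_tracks <- function(tracks) {
  if (is.data.frame(tracks)) {
    assert_track(tracks, arg = "tracks")
    tracks <- split(tracks, tracks$feature)
  }
  if (!is.list(tracks) || length(tracks) == 0) {
    abort("`tracks` must be a residue track or a non-empty list of residue tracks.")
  }
  tracks <- lapply(tracks, function(t) {
    assert_track(t, single_feature = TRUE, arg = "tracks")
    dplyr::arrange(t, .data$seq_id, .data$pos)
  })
  names(tracks) <- vapply(tracks, function(t) t$feature[[1]], character(1))
  tracks
}

# Check that every track in a list covers exactly the same (seq_id, pos) grid.
check_same_grid <- function(tracks) {
  ref <- tracks[[1]][c("seq_id", "pos")]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref)) {
      abort(sprintf(
        "Track '%s' has %d residues but '%s' has %d: lengths must match.",
        t$feature[[1]], nrow(t), tracks[[1]]$feature[[1]], nrow(ref)
      ))
    }
    if (!identical(t$seq_id, ref$seq_id) || !identical(t$pos, ref$pos)) {
      abort(sprintf(
        "Tracks '%s' and '%s' cover different sequences/positions.",
        tracks[[1]]$feature[[1]], t$feature[[1]]
      ))
    }
  }
  invisible(tracks)
}
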