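# End-to-end assembly of the prediction hierarchy:
#   PSSM features --normalize--> ics --smooth--> mcs --+
#                                                      |--> MoRF_DC --+
#   disorder --normalize----------------------------- -+              |--> final
#   local-sequence (chibi) --normalize--------------------------------+
# with Bayes-rule combination at every junction and re-normalization of each
# combined score before it enters the next level.

#' Disorder–conservation intermediate score
#'
#' Bayes-combines the normalized mcs and disorder tracks into the
#' intermediate disorder+conservation predictor (MoRF_DC); when `map` is
#' given the combination is re-normalized under it.
#'
#' @param mcs_n,disorder_n Normalized tracks.
#' @param map Optional `norm_map` for the combined score.
#' @return A residue track named `"morf_dc"`.
#' @export
compute_morf_dc <- function(mcs_n, disorder_n, map = NULL) {
  combined <- bayes_combine(list(mcs_n, disorder_n), feature = "morf_dc")
  if (is.null(map)) {
    return(combined)
  }
  apply_map(map, combined, check_feature = FALSE)
}

#' Final fused MoRF propensity
#'
#' Bayes-combines the normalized disorder+conservation intermediate with the
#' normalized local-sequence (chibi) track. The result lies in (0, 1) and is
#' the score the calling cutoff (default 0.66) applies to; it is not
#' re-normalized.
#'
#' @param morf_dc_n,chibi_n Normalized tracks.
#' @return A residue track named `"final"` with scores in (0, 1).
#' @export
compute_final <- function(morf_dc_n, chibi_n) {
  bayes_combine(list(morf_dc_n, chibi_n), feature = "final")
}

resolve_pssms <- function(pssms, seq_ids) {
  if (is.character(pssms) && length(pssms) == 1) {
    dir <- pssms
    paths <- file.path(dir, paste0(seq_ids, ".pssm"))
    present <- file.exists(paths)
    profiles <- lapply(which(present), function(i) parse_ascii_pssm(paths[[i]], seq_id = seq_ids[[i]]))
    names(profiles) <- seq_ids[present]
    return(profiles)
  }
  if (is.list(pssms)) {
    if (is.null(names(pssms)) || !all(nzchar(names(pssms)))) {
      names(pssms) <- vapply(pssms, `[[`, character(1), "seq_id")
    }
    return(pssms)
  }
  abort("`pssms` must be a directory path or a (named) list of pssm_profile objects.")
}

# One raw track per PSSM feature, pooled over all profiles, in seq_ids order.
pssm_feature_tracks <- function(profiles, seq_ids) {
  list(
    ipp = dplyr::bind_rows(lapply(seq_ids, function(s) extract_ipp(profiles[[s]]))),
    rwgrmp = dplyr::bind_rows(lapply(seq_ids, function(s) extract_rwgrmp(profiles[[s]]))),
    wop = dplyr::bind_rows(lapply(seq_ids, function(s) extract_wop(profiles[[s]])))
  )
}

check_component_coverage <- function(sequences, profiles, disorder, chibi) {
  ids <- sequences$seq_id
  miss <- list(
    PSSM = setdiff(ids, names(profiles)),
    disorder = setdiff(ids, unique(disorder$seq_id)),
    chibi = setdiff(ids, unique(chibi$seq_id))
  )
  miss <- miss[lengths(miss) > 0]
  if (length(miss) > 0) {
    abort(paste0(
      "Missing component input(s): ",
      paste(vapply(names(miss), function(k) {
        sprintf("%s for sequence(s) %s", k, toString(miss[[k]]))
      }, character(1)), collapse = "; "), "."
    ))
  }
  invisible(TRUE)
}

subset_track <- function(track, seq_ids) {
  out <- track |>
    dplyr::filter(.data$seq_id %in% seq_ids) |>
    dplyr::arrange(match(.data$seq_id, seq_ids), .data$pos)
  out
}

#' Fit all normalization maps from a training dataset
#'
#' Training walks the hierarchy once on a score population: it fits the five
#' input-feature maps (three PSSM conservation features, disorder, chibi) on
#' the pooled raw scores, then fits a map for each combined score in turn
#' (ics, mcs, and the disorder+conservation intermediate) on the combined
#' values the pipeline itself produces. Fitting uses only the score
#' populations — the mapping is a rank transform, so MoRF annotations play
#' no role here and are only needed later for evaluation. Maps are fitted
#' once on training data and never refitted on query data.
#'
#' @param sequences Sequence tibble from [read_fasta()].
#' @param pssms Directory of `<seq_id>.pssm` files or a named list of
#'   `pssm_profile` objects covering every sequence.
#' @param disorder,chibi Raw residue tracks for every sequence.
#' @param params [mcs_params()] used during training and stored in the
#'   bundle for prediction.
#' @param epsilon Optional clip bound passed to every [fit_map()] call.
#' @return A `morf_maps` bundle: named list of `norm_map`s (`ipp`, `rwgrmp`,
#'   `wop`, `disorder`, `chibi`, `ics`, `mcs`, `morf_dc`) plus the params.
#' @export
morf_train <- function(sequences, pssms, disorder, chibi,
                       params = mcs_params(), epsilon = NULL) {
  stopifnot(inherits(params, "mcs_params"))
  profiles <- resolve_pssms(pssms, sequences$seq_id)
  check_component_coverage(sequences, profiles, disorder, chibi)
  ids <- sequences$seq_id
  feats <- pssm_feature_tracks(profiles, ids)
  disorder <- subset_track(disorder, ids)
  chibi <- subset_track(chibi, ids)

  maps <- list(
    ipp = fit_map(feats$ipp$score, "ipp", epsilon),
    rwgrmp = fit_map(feats$rwgrmp$score, "rwgrmp", epsilon),
    wop = fit_map(feats$wop$score, "wop", epsilon),
    disorder = fit_map(disorder$score, "disorder", epsilon),
    chibi = fit_map(chibi$score, "chibi", epsilon)
  )
  ipp_n <- apply_map(maps$ipp, feats$ipp)
  rwgrmp_n <- complement_track(apply_map(maps$rwgrmp, feats$rwgrmp))
  wop_n <- apply_map(maps$wop, feats$wop)
  disorder_n <- apply_map(maps$disorder, disorder, check_feature = FALSE)

  ics_raw <- compute_ics(ipp_n, rwgrmp_n, wop_n)
  maps$ics <- fit_map(ics_raw$score, "ics", epsilon)
  ics_n <- apply_map(maps$ics, ics_raw, check_feature = FALSE)

  mcs_n <- compute_mcs(ics_n, disorder_n, params)
  maps$mcs <- fit_map(mcs_n$score, "mcs", epsilon)
  mcs_nn <- apply_map(maps$mcs, mcs_n)

  dc_raw <- compute_morf_dc(mcs_nn, disorder_n)
  maps$morf_dc <- fit_map(dc_raw$score, "morf_dc", epsilon)

  structure(list(maps = maps, params = params), class = "morf_maps")
}

#' @export
print.morf_maps <- function(x, ...) {
  cat(sprintf(
    "<morf_maps> normalization bundle with maps for: %s\n",
    toString(names(x$maps))
  ))
  invisible(x)
}

#' Save / load a normalization-map bundle
#'
#' One text file holding every fitted map plus the mcs parameters, in the
#' same versioned format as [save_map()].
#'
#' @param bundle A `morf_maps` object.
#' @param path File path.
#' @return `save_maps` returns `path` invisibly; `load_maps` the bundle.
#' @export
save_maps <- function(bundle, path) {
  stopifnot(inherits(bundle, "morf_maps"))
  p <- bundle$params
  par_lines <- c(
    "morffuse_mcs_params\t1",
    paste("disorder_window", p$disorder_window, sep = "\t"),
    paste("structured_window", p$structured_window, sep = "\t"),
    paste("disorder_hi", fmt_num(p$disorder_hi), sep = "\t"),
    paste("ics_conserved", fmt_num(p$ics_conserved), sep = "\t"),
    paste("min_conserved", p$min_conserved, sep = "\t"),
    paste("ics_cap", fmt_num(p$ics_cap), sep = "\t"),
    paste("disorder_lo", fmt_num(p$disorder_lo), sep = "\t"),
    paste("root_per_extra", as.integer(p$root_per_extra), sep = "\t")
  )
  blocks <- c(
    list(par_lines),
    lapply(bundle$maps, map_to_lines)
  )
  writeLines(unlist(lapply(blocks, function(b) c(b, "%%"))), path)
  invisible(path)
}

#' @rdname save_maps
#' @export
load_maps <- function(path) {
  if (!file.exists(path)) abort(sprintf("Bundle file '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  idx <- cumsum(c(TRUE, head(lines, -1) == "%%"))
  blocks <- split(lines, idx)
  blocks <- lapply(blocks, function(b) b[b != "%%" & nzchar(b)])
  blocks <- blocks[lengths(blocks) > 0]
  if (length(blocks) < 2 || !startsWith(blocks[[1]][[1]], "morffuse_mcs_params")) {
    abort(sprintf("Bundle file '%s' is not a morffuse map bundle.", path))
  }
  kv <- strsplit(blocks[[1]][-1], "\t")
  fields <- setNames(
    lapply(kv, `[[`, 2),
    vapply(kv, `[[`, character(1), 1)
  )
  params <- mcs_params(
    disorder_window = as.integer(fields$disorder_window),
    structured_window = as.integer(fields$structured_window),
    disorder_hi = as.numeric(fields$disorder_hi),
    ics_conserved = as.numeric(fields$ics_conserved),
    min_conserved = as.integer(fields$min_conserved),
    ics_cap = as.numeric(fields$ics_cap),
    disorder_lo = as.numeric(fields$disorder_lo),
    root_per_extra = as.integer(fields$root_per_extra) == 1L
  )
  maps <- lapply(blocks[-1], map_from_lines, label = sprintf("Bundle file '%s'", path))
  names(maps) <- vapply(maps, `[[`, character(1), "feature")
  need <- c("ipp", "rwgrmp", "wop", "disorder", "chibi", "ics", "mcs", "morf_dc")
  miss <- setdiff(need, names(maps))
  if (length(miss) > 0) {
    abort(sprintf("Bundle file '%s' is missing map(s): %s.", path, toString(miss)))
  }
  structure(list(maps = maps[need], params = params), class = "morf_maps")
}

#' Predict MoRF propensities for a set of sequences
#'
#' Runs the full hierarchy with a fitted map bundle: normalizes the three
#' PSSM conservation features (complementing the relative-weight feature),
#' the disorder track and the chibi track; combines conservation into ics;
#' smooths ics into mcs; fuses mcs with disorder into the intermediate
#' disorder+conservation score; and fuses that with chibi into the final
#' MoRF propensity. The run is deterministic: identical inputs give
#' bit-identical results.
#'
#' @param sequences Sequence tibble from [read_fasta()].
#' @param pssms Directory of `<seq_id>.pssm` files or named list of
#'   `pssm_profile`s.
#' @param disorder,chibi Raw residue tracks covering every sequence.
#' @param maps A `morf_maps` bundle from [morf_train()] or [load_maps()].
#' @param cutoff Calling cutoff in (0, 1) applied to the final score
#'   (default 0.66).
#' @return A `morf_prediction`: a tibble with one row per residue and
#'   columns `seq_id`, `pos`, `aa`, the normalized component tracks
#'   (`ipp_n`, `rwgrmp_n` (complemented), `wop_n`, `disorder_n`, `chibi_n`),
#'   the intermediate scores (`ics`, `mcs`, `morf_dc`) and `final`; called
#'   intervals are available via [call_morfs()] and stored in
#'   `attr(x, "calls")`.
#' @export
morf_predict <- function(sequences, pssms, disorder, chibi, maps, cutoff = 0.66) {
  stopifnot(inherits(maps, "morf_maps"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie in (0, 1).")
  }
  profiles <- resolve_pssms(pssms, sequences$seq_id)
  check_component_coverage(sequences, profiles, disorder, chibi)
  ids <- sequences$seq_id
  feats <- pssm_feature_tracks(profiles, ids)
  disorder <- subset_track(disorder, ids)
  chibi <- subset_track(chibi, ids)
  m <- maps$maps

  ipp_n <- apply_map(m$ipp, feats$ipp)
  rwgrmp_n <- complement_track(apply_map(m$rwgrmp, feats$rwgrmp))
  wop_n <- apply_map(m$wop, feats$wop)
  disorder_n <- apply_map(m$disorder, disorder, check_feature = FALSE)
  chibi_n <- apply_map(m$chibi, chibi, check_feature = FALSE)

  ics_n <- compute_ics(ipp_n, rwgrmp_n, wop_n, map = m$ics)
  mcs_n <- apply_map(m$mcs, compute_mcs(ics_n, disorder_n, maps$params))
  morf_dc_n <- compute_morf_dc(mcs_n, disorder_n, map = m$morf_dc)
  final <- compute_final(morf_dc_n, chibi_n)

  wide <- feats$ipp[c("seq_id", "pos", "aa")]
  wide$ipp_n <- ipp_n$score
  wide$rwgrmp_n <- rwgrmp_n$score
  wide$wop_n <- wop_n$score
  wide$disorder_n <- disorder_n$score
  wide$chibi_n <- chibi_n$score
  wide$ics <- ics_n$score
  wide$mcs <- mcs_n$score
  wide$morf_dc <- morf_dc_n$score
  wide$final <- final$score

  out <- tibble::new_tibble(wide, class = "morf_prediction")
  attr(out, "cutoff") <- cutoff
  attr(out, "calls") <- call_morfs(out, cutoff)
  out
}

#' Extract a single component as a residue track
#'
#' @param prediction A `morf_prediction`.
#' @param feature Column name of the component (`"final"`, `"ics"`, ...).
#' @param space Declared space of the extracted track.
#' @return A residue track tibble.
#' @export
prediction_track <- function(prediction, feature = "final",
                             space = c("normalized", "raw")) {
  space <- match.arg(space)
  stopifnot(is.data.frame(prediction), feature %in% names(prediction))
  residue_track(prediction$seq_id, prediction$pos, prediction[[feature]],
    feature = feature, space = space, aa = prediction$aa
  )
}

#' Call MoRF intervals at a score cutoff
#'
#' Maximal runs of residues whose final score is greater than or equal to
#' the cutoff, as 1-based inclusive intervals.
#'
#' @param x A `morf_prediction` (uses the `final` column) or any residue
#'   track (uses `score`).
#' @param cutoff Calling cutoff in (0, 1).
#' @return A tibble with columns `seq_id`, `start`, `end`.
#' @export
call_morfs <- function(x, cutoff = 0.66) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie in (0, 1).")
  }
  if ("final" %in% names(x)) {
    df <- tibble(seq_id = x$seq_id, pos = x$pos, score = x$final)
  } else {
    assert_track(x, arg = "x")
    df <- x[c("seq_id", "pos", "score")]
  }
  df |>
    dplyr::arrange(.data$seq_id, .data$pos) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::reframe({
      p <- .data$pos
      r <- rle(.data$score >= cutoff)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      tibble(start = p[starts[keep]], end = p[ends[keep]])
    }) |>
    as_tibble()
}

#' Write prediction output files
#'
#' Writes `<prefix>_residues.tsv` (all per-residue tracks) and
#' `<prefix>_calls.tsv` (called intervals at the prediction's cutoff).
#'
#' @param prediction A `morf_prediction`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_prediction <- function(prediction, prefix) {
  stopifnot(inherits(prediction, "morf_prediction"))
  res_path <- paste0(prefix, "_residues.tsv")
  call_path <- paste0(prefix, "_calls.tsv")
  readr::write_tsv(as_tibble(prediction), res_path, progress = FALSE)
  readr::write_tsv(attr(prediction, "calls"), call_path, progress = FALSE)
  invisible(c(residues = res_path, calls = call_path))
}

#' @export
tidy.morf_prediction <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = -c("seq_id", "pos", "aa"),
      names_to = "feature", values_to = "score"
    )
}

#' @export
glance.morf_prediction <- function(x, ...) {
  calls <- attr(x, "calls")
  as_tibble(x) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(
      length = dplyr::n(),
      mean_final = mean(.data$final),
      max_final = max(.data$final),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      calls |> dplyr::count(.data$seq_id, name = "n_called"),
      by = "seq_id"
    ) |>
    dplyr::mutate(n_called = dplyr::coalesce(.data$n_called, 0L))
}
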