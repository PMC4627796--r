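# Readers/writers for sequences, per-residue score tracks and MoRF
# annotations. All file coordinates are 1-based inclusive.

AA_VALID <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
  "R", "S", "T", "V", "W", "Y", "X", "B", "Z", "U"
)

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20 amino-acid letters
#' plus the ambiguity codes X/B/Z/U. Gap characters and duplicate identifiers
#' are errors. The identifier is the FASTA header up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id`, `seq` and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file '%s' does not exist.", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("Cannot parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) abort(sprintf("FASTA file '%s' contains no sequences.", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) abort(sprintf("FASTA file '%s' has a record with an empty id.", path))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("FASTA file '%s' has duplicate ids: %s.", path, toString(dup)))
  }
  seqs <- toupper(as.character(set))
  bad <- vapply(
    strsplit(seqs, ""),
    function(ch) !all(ch %in% AA_VALID),
    logical(1)
  )
  if (any(bad)) {
    abort(sprintf(
      "FASTA record(s) %s contain characters outside the amino-acid alphabet (gaps are not allowed).",
      toString(ids[bad])
    ))
  }
  if (any(nchar(seqs) < 1)) {
    abort(sprintf("FASTA record(s) %s are empty.", toString(ids[nchar(seqs) < 1])))
  }
  tibble(seq_id = unname(ids), seq = unname(seqs), length = nchar(unname(seqs)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Tibble with `seq_id` and `seq` columns (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences), all(c("seq_id", "seq") %in% names(sequences)))
  set <- Biostrings::BStringSet(setNames(sequences$seq, sequences$seq_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a per-residue score track from TSV
#'
#' The file format is tab-separated with a header line and columns
#' `seq_id`, `pos`, `aa`, `score`. Positions must be contiguous from 1 for
#' every sequence. The redundant residue letter enables cross-validation
#' against the FASTA: when `sequences` is supplied, any mismatch in length or
#' residue letter is an error.
#'
#' @param path Path to the track TSV.
#' @param feature Feature name stored in the `feature` column; defaults to
#'   the file stem.
#' @param space Declared score space of the file (`"raw"` by default).
#' @param sequences Optional sequence tibble from [read_fasta()] for
#'   cross-validation.
#' @return A residue track tibble (see [residue_track()]) with an `aa` column.
#' @export
read_track <- function(path, feature = NULL, space = c("raw", "normalized"),
                       sequences = NULL) {
  space <- match.arg(space)
  if (is.null(feature)) feature <- tools::file_path_sans_ext(basename(path))
  if (!file.exists(path)) abort(sprintf("Track file '%s' does not exist.", path))
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      seq_id = readr::col_character(),
      pos = readr::col_integer(),
      aa = readr::col_character(),
      score = readr::col_character()
    ),
    progress = FALSE
  )
  if (!all(c("seq_id", "pos", "aa", "score") %in% names(df))) {
    abort(sprintf("Track file '%s' must have columns seq_id, pos, aa, score.", path))
  }
  if (nrow(df) == 0) abort(sprintf("Track file '%s' is empty.", path))
  # correctly rounded string -> double conversion (full precision round trip)
  df$score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(df$score) || anyNA(df$pos)) {
    bad <- which(is.na(df$score) | is.na(df$pos))[[1]]
    abort(sprintf("Track file '%s': unparseable value at data row %d.", path, bad))
  }
  out <- df |>
    dplyr::mutate(feature = feature, space = space) |>
    dplyr::select("feature", "seq_id", "pos", "score", "space", "aa")
  # contiguity 1..L per sequence, in file order
  for (sid in unique(out$seq_id)) {
    p <- out$pos[out$seq_id == sid]
    if (!identical(as.integer(p), seq_len(length(p)))) {
      gap <- which(as.integer(p) != seq_len(length(p)))[[1]]
      abort(sprintf(
        "Track file '%s': position gap for sequence '%s' near position %s (expected %d).",
        path, sid, p[gap], gap
      ))
    }
  }
  if (!is.null(sequences)) check_track_against_sequences(out, sequences, path)
  assert_track(out, space = space)
  out
}

check_track_against_sequences <- function(track, sequences, label = "track") {
  missing <- setdiff(unique(track$seq_id), sequences$seq_id)
  if (length(missing) > 0) {
    abort(sprintf("%s: sequences %s not present in FASTA.", label, toString(missing)))
  }
  by_seq <- split(track, track$seq_id)
  for (sid in names(by_seq)) {
    t <- by_seq[[sid]]
    s <- sequences$seq[sequences$seq_id == sid]
    if (nrow(t) != nchar(s)) {
      abort(sprintf(
        "%s: sequence '%s' has %d residues but the track has %d.",
        label, sid, nchar(s), nrow(t)
      ))
    }
    if ("aa" %in% names(t)) {
      letters_fa <- strsplit(s, "")[[1]]
      mism <- which(t$aa != letters_fa)
      if (length(mism) > 0) {
        abort(sprintf(
          "%s: residue mismatch for '%s' at position %d ('%s' in track vs '%s' in FASTA).",
          label, sid, t$pos[mism[[1]]], t$aa[mism[[1]]], letters_fa[mism[[1]]]
        ))
      }
    }
  }
  invisible(track)
}

#' Write a per-residue score track to TSV
#'
#' Inverse of [read_track()]. Scores are written with full double precision
#' so that a read/write round trip preserves them.
#'
#' @param track A residue track with an `aa` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  assert_track(track, arg = "track")
  if (!"aa" %in% names(track)) {
    abort("`track` must carry an `aa` column to be written (the file format is seq_id, pos, aa, score).")
  }
  out <- track[c("seq_id", "pos", "aa", "score")]
  out$score <- sprintf("%.17g", out$score) # survives a write/read round trip bitwise
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read MoRF annotations from TSV
#'
#' The file is tab-separated with a header and columns `seq_id`, `start`,
#' `end`, `label`, with 1-based inclusive coordinates and labels `morf` or
#' `masked`. Residues outside all intervals are implicitly non-MoRF.
#' Overlapping intervals, inverted intervals, and (when `sequences` is given)
#' out-of-range intervals are errors.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Optional sequence tibble from [read_fasta()].
#' @return A tibble with columns `seq_id`, `start`, `end`, `label`.
#' @export
read_annotations <- function(path, sequences = NULL) {
  if (!file.exists(path)) abort(sprintf("Annotation file '%s' does not exist.", path))
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      seq_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      label = readr::col_character()
    ),
    progress = FALSE
  )
  validate_annotations(df, sequences, label = sprintf("Annotation file '%s'", path))
  as_tibble(df)
}

validate_annotations <- function(ann, sequences = NULL, label = "annotations") {
  if (!all(c("seq_id", "start", "end", "label") %in% names(ann))) {
    abort(sprintf("%s must have columns seq_id, start, end, label.", label))
  }
  bad_lab <- setdiff(unique(ann$label), c("morf", "masked"))
  if (length(bad_lab) > 0) {
    abort(sprintf("%s: unknown labels %s (allowed: morf, masked).", label, toString(bad_lab)))
  }
  if (any(ann$start < 1) || any(ann$end < ann$start)) {
    i <- which(ann$start < 1 | ann$end < ann$start)[[1]]
    abort(sprintf(
      "%s: invalid interval %d-%d for sequence '%s'.",
      label, ann$start[i], ann$end[i], ann$seq_id[i]
    ))
  }
  for (sid in unique(ann$seq_id)) {
    iv <- ann[ann$seq_id == sid, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      abort(sprintf("%s: overlapping intervals for sequence '%s'.", label, sid))
    }
    if (!is.null(sequences)) {
      if (!sid %in% sequences$seq_id) {
        abort(sprintf("%s: sequence '%s' not present in FASTA.", label, sid))
      }
      L <- sequences$length[sequences$seq_id == sid]
      if (any(iv$end > L)) {
        abort(sprintf(
          "%s: interval ending at %d exceeds length %d of sequence '%s'.",
          label, max(iv$end), L, sid
        ))
      }
    }
  }
  invisible(ann)
}

#' Write MoRF annotations to TSV
#' @param annotations Annotation tibble (`seq_id`, `start`, `end`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_tsv(annotations[c("seq_id", "start", "end", "label")], path, progress = FALSE)
  invisible(path)
}

#' Expand interval annotations to per-residue labels
#'
#' @param annotations Annotation tibble.
#' @param sequences Sequence tibble from [read_fasta()] (gives lengths).
#' @return A tibble with columns `seq_id`, `pos`, `label` where `label` is
#'   `"morf"`, `"masked"` or `"non_morf"` for every residue of every sequence.
#' @export
morf_labels <- function(annotations, sequences) {
  validate_annotations(annotations, sequences)
  out <- purrr::map_dfr(seq_len(nrow(sequences)), function(i) {
    sid <- sequences$seq_id[[i]]
    L <- sequences$length[[i]]
    lab <- rep("non_morf", L)
    iv <- annotations[annotations$seq_id == sid, ]
    for (j in seq_len(nrow(iv))) {
      lab[iv$start[[j]]:iv$end[[j]]] <- iv$label[[j]]
    }
    tibble(seq_id = sid, pos = seq_len(L), label = lab)
  })
  out
}
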