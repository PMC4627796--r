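# PSI-BLAST ASCII PSSM parsing and extraction of the three conservation
# features used for MoRF prediction: IPP (information per position), WOP
# (weighted observed percentage of the query residue) and RWGRMP (relative
# weight of gapless real matches to pseudocounts).

# Column order of the 20 standard residues in PSI-BLAST ASCII PSSM files.
PSSM_AA <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

new_pssm_profile <- function(seq_id, residues, log_odds, wop, ipp, rwgrmp) {
  L <- length(residues)
  stopifnot(
    nrow(log_odds) == L, ncol(log_odds) == 20,
    nrow(wop) == L, ncol(wop) == 20,
    length(ipp) == L, length(rwgrmp) == L
  )
  colnames(log_odds) <- PSSM_AA
  colnames(wop) <- PSSM_AA
  structure(
    list(
      seq_id = seq_id, residues = residues,
      log_odds = log_odds, wop = wop,
      ipp = as.numeric(ipp), rwgrmp = as.numeric(rwgrmp)
    ),
    class = "pssm_profile"
  )
}

validate_pssm_profile <- function(p) {
  if (any(p$wop < 0) || any(p$wop > 100)) {
    abort(sprintf("PSSM '%s': weighted observed percentages must lie in [0, 100].", p$seq_id))
  }
  if (any(p$ipp < 0)) abort(sprintf("PSSM '%s': information per position must be >= 0.", p$seq_id))
  if (any(p$rwgrmp < 0)) abort(sprintf("PSSM '%s': relative weight must be >= 0.", p$seq_id))
  invisible(p)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the 44-column ASCII dialect: per position, the position index, the
#' query residue, 20 log-odds integers, 20 weighted-observed-percentage
#' integers, the information-per-position value and the relative weight of
#' gapless real matches to pseudocounts. The K/lambda footer is ignored.
#' Binary and XML PSSM outputs are not supported.
#'
#' @param path Path to the PSSM file.
#' @param seq_id Sequence identifier; defaults to the file stem.
#' @return A `pssm_profile` object: a list with elements `seq_id`,
#'   `residues` (character vector), `log_odds` and `wop` (L x 20 integer
#'   matrices with residue column names), `ipp` and `rwgrmp` (length-L
#'   numeric vectors).
#' @export
parse_ascii_pssm <- function(path, seq_id = NULL) {
  if (!file.exists(path)) abort(sprintf("PSSM file '%s' does not exist.", path))
  if (is.null(seq_id)) seq_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)

  row_start <- grepl("^\\s*[0-9]+\\s+[A-Za-z](\\s|$)", lines)
  rows <- list()
  expected <- 1L
  in_data <- FALSE
  for (i in seq_along(lines)) {
    if (!row_start[[i]]) {
      if (in_data) break # footer reached
      next
    }
    in_data <- TRUE
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    pos <- suppressWarnings(as.integer(f[[1]]))
    if (is.na(pos) || pos != expected) {
      abort(sprintf(
        "PSSM file '%s', line %d: position index %s out of order (expected %d).",
        path, i, f[[1]], expected
      ))
    }
    if (length(f) != 44) {
      abort(sprintf(
        "PSSM file '%s', line %d: expected 44 fields per position row, found %d.",
        path, i, length(f)
      ))
    }
    nums <- suppressWarnings(as.numeric(f[3:44]))
    if (anyNA(nums)) {
      abort(sprintf("PSSM file '%s', line %d: unreadable numeric field.", path, i))
    }
    rows[[expected]] <- list(aa = toupper(f[[2]]), nums = nums)
    expected <- expected + 1L
  }
  if (length(rows) == 0) {
    abort(sprintf("PSSM file '%s' contains no position rows.", path))
  }
  mat <- do.call(rbind, lapply(rows, `[[`, "nums"))
  p <- new_pssm_profile(
    seq_id = seq_id,
    residues = vapply(rows, `[[`, character(1), "aa"),
    log_odds = matrix(as.integer(mat[, 1:20]), ncol = 20),
    wop = matrix(as.integer(mat[, 21:40]), ncol = 20),
    ipp = mat[, 41],
    rwgrmp = mat[, 42]
  )
  validate_pssm_profile(p)
  p
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf(
    "<pssm_profile> %s: %d positions, IPP range [%.2f, %.2f], RWGRMP range [%.2f, %.2f]\n",
    x$seq_id, length(x$residues), min(x$ipp), max(x$ipp), min(x$rwgrmp), max(x$rwgrmp)
  ))
  invisible(x)
}

#' @export
tidy.pssm_profile <- function(x, ...) {
  tibble(
    seq_id = x$seq_id,
    pos = seq_along(x$residues),
    aa = x$residues,
    ipp = x$ipp,
    rwgrmp = x$rwgrmp,
    wop_query = wop_query_values(x)
  )
}

wop_query_values <- function(profile) {
  idx <- match(profile$residues, PSSM_AA)
  unknown <- which(is.na(idx))
  v <- numeric(length(idx))
  known <- which(!is.na(idx))
  v[known] <- profile$wop[cbind(known, idx[known])]
  if (length(unknown) > 0) {
    inform(sprintf(
      "PSSM '%s': residues without a dedicated column (%s) at position(s) %s; WOP set to 0.",
      profile$seq_id,
      toString(unique(profile$residues[unknown])),
      toString(unknown)
    ))
  }
  v
}

#' Extract conservation feature tracks from a PSSM profile
#'
#' `extract_ipp()` returns the information-per-position column,
#' `extract_rwgrmp()` the relative-weight column, and `extract_wop()` the
#' weighted observed percentage of the query residue at each position (the
#' integer printed in the file; positions whose query residue has no PSSM
#' column, i.e. X/B/Z/U, get WOP 0 and are reported via a message). All
#' three return raw-space residue tracks.
#'
#' @param profile A `pssm_profile` from [parse_ascii_pssm()].
#' @return A raw-space residue track tibble.
#' @export
extract_ipp <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  residue_track(profile$seq_id, seq_along(profile$ipp), profile$ipp,
    feature = "ipp", space = "raw", aa = profile$residues
  )
}

#' @rdname extract_ipp
#' @export
extract_rwgrmp <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  residue_track(profile$seq_id, seq_along(profile$rwgrmp), profile$rwgrmp,
    feature = "rwgrmp", space = "raw", aa = profile$residues
  )
}

#' @rdname extract_ipp
#' @export
extract_wop <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  residue_track(profile$seq_id, seq_along(profile$residues), wop_query_values(profile),
    feature = "wop", space = "raw", aa = profile$residues
  )
}

#' Complement a normalized track
#'
#' Replaces every score v by 1 - v. Used for features that are
#' anti-correlated with MoRFs (the relative-weight feature RWGRMP): on the
#' normalized (0, 1) scale the complement mirrors the score about the
#' Gaussian mean 0.5, so a ROC area a becomes 1 - a. Raw-space input is an
#' error: raw feature scales are unbounded and have no meaningful complement.
#'
#' @param track A normalized-space residue track.
#' @return The complemented normalized track.
#' @export
complement_track <- function(track) {
  assert_track(track, space = "normalized", arg = "track")
  dplyr::mutate(track, score = 1 - .data$score)
}
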