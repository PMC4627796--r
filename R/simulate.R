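# Seeded synthetic-data generator. Emulates the statistical structure the
# fusion method assumes: each sequence carries one MoRF embedded in a longer
# intrinsically disordered region; the disorder track is elevated over the
# whole IDR and does not dip at the MoRF; the local-sequence (chibi) track
# and the three PSSM conservation features are drawn from MoRF-class
# distributions inside the MoRF and background distributions elsewhere
# (the relative-weight feature is anti-correlated with MoRFs). Every
# generator is pure given (spec, seed).

default_sim_dists <- function(separation = c("moderate", "strong")) {
  separation <- match.arg(separation)
  if (separation == "strong") {
    sep <- list(hi = c(8, 2), lo = c(2, 8))
    return(list(
      disorder = list(idr = sep$hi, other = sep$lo),
      chibi = list(morf = sep$hi, other = sep$lo),
      ipp = list(morf = sep$hi, other = sep$lo, scale = 2),
      wop = list(morf = sep$hi, other = sep$lo, scale = 100),
      rwgrmp = list(morf = sep$lo, other = sep$hi, scale = 1.5)
    ))
  }
  # Moderate overlap: Beta pairs chosen so that single-feature residue-level
  # ROC areas land in the realistic 0.65-0.75 range.
  list(
    disorder = list(idr = c(5, 3), other = c(3, 5)),
    chibi = list(morf = c(4, 3), other = c(3, 4)),
    ipp = list(morf = c(3.5, 3), other = c(2.5, 3.5), scale = 2),
    wop = list(morf = c(4, 3), other = c(3, 4), scale = 100),
    rwgrmp = list(morf = c(3, 4), other = c(4, 3), scale = 1.5)
  )
}

#' Specify a synthetic MoRF dataset
#'
#' Describes a simulated study: number and length of sequences, the MoRF
#' length regime (`"short"`: 5–25 residues, `"long"`: 31–45, `"mixed"`:
#' either with equal probability), the flank lengths by which the enclosing
#' IDR extends past the MoRF, and the per-class Beta score distributions of
#' every feature. `separation = "strong"` switches all class distributions
#' to the well-separated Beta(8, 2) / Beta(2, 8) pair; `correlation` mixes a
#' shared per-residue percentile into all features, probing the fusion
#' model's independence assumption.
#'
#' @param n_sequences Number of sequences.
#' @param length_range Sequence length range (inclusive).
#' @param morf_mode `"short"`, `"long"` or `"mixed"`.
#' @param flank_range Range of IDR flank lengths on each side of the MoRF.
#' @param separation `"moderate"` (default) or `"strong"`.
#' @param correlation Probability in \[0, 1) that a residue's features share
#'   one latent percentile instead of being drawn independently.
#' @param seed Integer seed; the same spec and seed give identical output.
#' @param dists Optional list overriding the per-feature class
#'   distributions (see `default_sim_dists`).
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n_sequences = 100L, length_range = c(80L, 300L),
                     morf_mode = c("short", "long", "mixed"),
                     flank_range = c(15L, 40L),
                     separation = c("moderate", "strong"),
                     correlation = 0, seed = 1L, dists = NULL) {
  morf_mode <- match.arg(morf_mode)
  separation <- match.arg(separation)
  if (is.null(dists)) dists <- default_sim_dists(separation)
  if (n_sequences < 1) abort("`n_sequences` must be >= 1.")
  if (length_range[[1]] < 10 || length_range[[2]] < length_range[[1]]) {
    abort("`length_range` must be an increasing pair with minimum >= 10.")
  }
  if (correlation < 0 || correlation >= 1) abort("`correlation` must lie in [0, 1).")
  max_morf <- if (morf_mode == "short") 25L else 45L
  if (max_morf + 2L > length_range[[1]]) {
    abort(sprintf(
      "MoRFs of up to %d residues do not fit in sequences of length %d.",
      max_morf, length_range[[1]]
    ))
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      length_range = as.integer(length_range),
      morf_mode = morf_mode,
      flank_range = as.integer(flank_range),
      separation = separation,
      correlation = correlation,
      seed = as.integer(seed),
      dists = dists
    ),
    class = "sim_spec"
  )
}

# Draw one residue-class score vector from the spec'd Beta family, with the
# optional shared-percentile correlation knob.
draw_scores <- function(n, shape, shared_u, correlation) {
  u <- runif(n)
  if (correlation > 0) {
    take <- runif(n) < correlation
    u[take] <- shared_u[take]
  }
  stats::qbeta(u, shape[[1]], shape[[2]])
}

#' Simulate a complete synthetic MoRF dataset
#'
#' Generates sequences, MoRF annotations, raw disorder and chibi tracks and
#' synthetic PSSM profiles according to a [sim_spec()]. Each sequence gets
#' one MoRF placed uniformly inside an IDR that extends it by random flanks;
#' disorder scores are drawn from the IDR-class distribution over the whole
#' IDR (MoRF included, so the track does not dip there) and from the
#' background class elsewhere. PSSM-borne feature values are quantized the
#' way the ASCII format stores them (integers for the weighted observed
#' percentage, two decimals for information and relative weight), so writing
#' profiles with [write_synthetic_pssm()] and re-parsing recovers them
#' exactly.
#'
#' @param spec A [sim_spec()].
#' @return A list with elements `sequences` (tibble), `annotations`
#'   (tibble), `disorder` and `chibi` (raw residue tracks) and `pssms`
#'   (named list of `pssm_profile`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, simulate_dataset_impl(spec))
}

simulate_dataset_impl <- function(spec) {
  d <- spec$dists
  seqs <- vector("list", spec$n_sequences)
  anns <- vector("list", spec$n_sequences)
  dis <- vector("list", spec$n_sequences)
  chi <- vector("list", spec$n_sequences)
  pssms <- vector("list", spec$n_sequences)
  ids <- sprintf("syn%04d", seq_len(spec$n_sequences))

  for (i in seq_len(spec$n_sequences)) {
    L <- sample(seq.int(spec$length_range[[1]], spec$length_range[[2]]), 1L)
    mode <- if (spec$morf_mode == "mixed") sample(c("short", "long"), 1L) else spec$morf_mode
    mlen <- if (mode == "short") sample(5:25, 1L) else sample(31:45, 1L)
    if (mlen > L) abort(sprintf("MoRF of %d residues does not fit in a %d-residue sequence.", mlen, L))
    start <- sample.int(L - mlen + 1L, 1L)
    end <- start + mlen - 1L
    f1 <- sample(seq.int(spec$flank_range[[1]], spec$flank_range[[2]]), 1L)
    f2 <- sample(seq.int(spec$flank_range[[1]], spec$flank_range[[2]]), 1L)
    idr <- c(max(1L, start - f1), min(L, end + f2))

    residues <- sample(PSSM_AA, L, replace = TRUE)
    in_morf <- seq_len(L) >= start & seq_len(L) <= end
    in_idr <- seq_len(L) >= idr[[1]] & seq_len(L) <= idr[[2]]
    shared_u <- runif(L)

    dis_score <- numeric(L)
    dis_score[in_idr] <- draw_scores(sum(in_idr), d$disorder$idr, shared_u[in_idr], spec$correlation)
    dis_score[!in_idr] <- draw_scores(sum(!in_idr), d$disorder$other, shared_u[!in_idr], spec$correlation)

    class_scores <- function(fd) {
      v <- numeric(L)
      v[in_morf] <- draw_scores(sum(in_morf), fd$morf, shared_u[in_morf], spec$correlation)
      v[!in_morf] <- draw_scores(sum(!in_morf), fd$other, shared_u[!in_morf], spec$correlation)
      v
    }
    chi_score <- class_scores(d$chibi)
    ipp <- round(class_scores(d$ipp) * d$ipp$scale, 2)
    wop_q <- as.integer(round(class_scores(d$wop) * d$wop$scale))
    rwgrmp <- round(class_scores(d$rwgrmp) * d$rwgrmp$scale, 2)

    seqs[[i]] <- tibble(seq_id = ids[[i]], seq = paste(residues, collapse = ""), length = L)
    anns[[i]] <- tibble(seq_id = ids[[i]], start = start, end = end, label = "morf")
    dis[[i]] <- residue_track(ids[[i]], seq_len(L), dis_score,
      feature = "disorder", space = "raw", aa = residues
    )
    chi[[i]] <- residue_track(ids[[i]], seq_len(L), chi_score,
      feature = "chibi", space = "raw", aa = residues
    )
    pssms[[i]] <- make_pssm_profile(ids[[i]], residues, ipp = ipp, wop_query = wop_q, rwgrmp = rwgrmp)
  }

  list(
    sequences = dplyr::bind_rows(seqs),
    annotations = dplyr::bind_rows(anns),
    disorder = dplyr::bind_rows(dis),
    chibi = dplyr::bind_rows(chi),
    pssms = setNames(pssms, ids)
  )
}

#' Build a synthetic PSSM profile with planted feature values
#'
#' Constructs a `pssm_profile` whose information-per-position, relative
#' weight and query-residue weighted-observed-percentage values equal the
#' planted vectors. The remaining weighted-observed percentages and the
#' log-odds block are filled with plausible values drawn from the current
#' RNG state.
#'
#' @param seq_id Sequence identifier.
#' @param residues Character vector of residue letters.
#' @param ipp Non-negative information values (will be stored at two
#'   decimals in the ASCII file).
#' @param wop_query Integer weighted observed percentages in \[0, 100\] for
#'   the query residue at each position.
#' @param rwgrmp Non-negative relative weights (two decimals in the file).
#' @return A `pssm_profile`.
#' @export
make_pssm_profile <- function(seq_id, residues, ipp, wop_query, rwgrmp) {
  L <- length(residues)
  if (L == 0) abort("Cannot build a zero-length PSSM profile.")
  stopifnot(length(ipp) == L, length(wop_query) == L, length(rwgrmp) == L)
  if (any(wop_query < 0) || any(wop_query > 100)) {
    abort("Planted weighted observed percentages must lie in [0, 100].")
  }
  log_odds <- matrix(sample(-5:9, L * 20L, replace = TRUE), nrow = L)
  wop <- matrix(sample(0:15, L * 20L, replace = TRUE), nrow = L)
  idx <- match(residues, PSSM_AA)
  for (i in seq_len(L)) {
    if (!is.na(idx[[i]])) wop[i, idx[[i]]] <- wop_query[[i]]
  }
  validate_pssm_profile(
    new_pssm_profile(seq_id, residues, log_odds, wop, round(ipp, 2), round(rwgrmp, 2))
  )
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Produces a file that [parse_ascii_pssm()] reads back with exact recovery
#' of the stored log-odds, weighted observed percentages, information and
#' relative-weight values (information and relative weight are printed at
#' two decimals, as PSI-BLAST does).
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  validate_pssm_profile(profile)
  L <- length(profile$residues)
  if (L == 0) abort("Cannot write a zero-length PSSM profile.")
  header <- paste0(
    "           ",
    paste(sprintf("%3s", PSSM_AA), collapse = ""), "  ",
    paste(sprintf("%3s", PSSM_AA), collapse = "")
  )
  rows <- vapply(seq_len(L), function(i) {
    paste0(
      sprintf("%5d %s ", i, profile$residues[[i]]),
      paste(sprintf("%3d", profile$log_odds[i, ]), collapse = ""), " ",
      paste(sprintf("%4d", profile$wop[i, ]), collapse = ""),
      sprintf("  %5.2f %9.2f", profile$ipp[[i]], profile$rwgrmp[[i]])
    )
  }, character(1))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weight ratio of pseudocounts, and information per position",
    header,
    rows,
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3179",
    "Standard Gapped      0.0410     0.2670",
    "PSI Ungapped         0.1347     0.3179",
    "PSI Gapped           0.0410     0.2670"
  ), path)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Materializes a [simulate_dataset()] result as the package's file formats:
#' `sequences.fasta`, `annotations.tsv`, `disorder.tsv`, `chibi.tsv` and one
#' `<seq_id>.pssm` per sequence under `pssm/`. Writing is deterministic:
#' the same dataset gives byte-identical files.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  write_track(dataset$disorder, file.path(dir, "disorder.tsv"))
  write_track(dataset$chibi, file.path(dir, "chibi.tsv"))
  for (sid in names(dataset$pssms)) {
    write_synthetic_pssm(dataset$pssms[[sid]], file.path(dir, "pssm", paste0(sid, ".pssm")))
  }
  invisible(dir)
}
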