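test_that("FASTA parsing validates records and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "MKV"), f)
  seqs <- read_fasta(f)
  expect_equal(seqs$seq_id, "s1")
  expect_equal(seqs$seq, "MKV")
  expect_equal(seqs$length, 3L)

  writeLines(c(">p53", "MKV", ">p53", "ALA"), f)
  expect_error(read_fasta(f), "duplicate ids.*p53")

  writeLines(c(">s1", "MK-V"), f)
  expect_error(read_fasta(f), "amino-acid alphabet")

  writeLines(c(">s1", "mkqv"), f)
  expect_equal(read_fasta(f)$seq, "MKQV") # lowercase input is uppercased

  # 50-record synthetic round trip
  set.seed(31)
  many <- tibble::tibble(
    seq_id = sprintf("rt%02d", 1:50),
    seq = vapply(1:50, function(i) {
      paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
        sample(20:200, 1),
        replace = TRUE
      ), collapse = "")
    }, character(1))
  )
  many$length <- nchar(many$seq)
  write_fasta(many, f)
  expect_equal(read_fasta(f), many)
})

test_that("track TSV reading enforces contiguity and cross-checks the FASTA", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "seq_id\tpos\taa\tscore",
    "s1\t1\tM\t0.5", "s1\t2\tK\t0.25", "s1\t3\tV\t0.125"
  ), f)
  tr <- read_track(f, feature = "disorder")
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$score, c(0.5, 0.25, 0.125))
  expect_equal(track_space(tr), "raw")

  writeLines(c(
    "seq_id\tpos\taa\tscore",
    "s1\t1\tM\t0.5", "s1\t2\tK\t0.25", "s1\t4\tV\t0.125"
  ), f)
  expect_error(read_track(f), "position gap")

  writeLines(c(
    "seq_id\tpos\taa\tscore",
    "s1\t1\tM\t0.5", "s1\t2\tK\tnot_a_number"
  ), f)
  expect_error(suppressWarnings(read_track(f)), "unparseable")

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MKV"), fa)
  seqs <- read_fasta(fa)
  writeLines(c(
    "seq_id\tpos\taa\tscore",
    "s1\t1\tM\t0.5", "s1\t2\tQ\t0.25", "s1\t3\tV\t0.125"
  ), f)
  expect_error(read_track(f, sequences = seqs), "mismatch.*position 2")
})

test_that("track write/read round trip preserves scores to full precision", {
  set.seed(77)
  tr <- residue_track("s1", 1:1000, rexp(1000) * 1e3 + pi,
    feature = "t", space = "raw", aa = sample(LETTERS[1:20], 1000, TRUE)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, f)
  back <- read_track(f, feature = "t")
  expect_identical(back$score, tr$score) # bitwise, i.e. >= 12 significant digits
  expect_identical(back$aa, tr$aa)
})

test_that("annotation parsing validates intervals", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", strrep("A", 50)), fa)
  seqs <- read_fasta(fa)
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("seq_id\tstart\tend\tlabel", "s1\t10\t20\tmorf"), f)
  ann <- read_annotations(f, seqs)
  expect_equal(ann$end - ann$start + 1L, 11L) # 11 MoRF residues

  writeLines(c("seq_id\tstart\tend\tlabel", "s1\t10\t20\tmorf", "s1\t15\t30\tmorf"), f)
  expect_error(read_annotations(f, seqs), "overlapping")

  writeLines(c("seq_id\tstart\tend\tlabel", "s1\t40\t60\tmorf"), f)
  expect_error(read_annotations(f, seqs), "exceeds length")

  writeLines(c("seq_id\tstart\tend\tlabel", "s1\t20\t10\tmorf"), f)
  expect_error(read_annotations(f), "invalid interval")
})

test_that("per-residue labels count exactly the annotated morf residues", {
  set.seed(5)
  ds <- small_dataset(n = 8)
  labs <- morf_labels(ds$annotations, ds$sequences)
  expect_equal(nrow(labs), sum(ds$sequences$length))
  n_morf_expected <- sum(ds$annotations$end - ds$annotations$start + 1L)
  expect_equal(sum(labs$label == "morf"), n_morf_expected)
  # track/sequence length agreement for every simulated pair
  len_by_track <- dplyr::count(ds$disorder, seq_id)
  expect_equal(
    len_by_track$n[match(ds$sequences$seq_id, len_by_track$seq_id)],
    ds$sequences$length
  )
})
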