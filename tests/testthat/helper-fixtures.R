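# Small in-code fixtures shared across test files.

rand_norm_track <- function(n = 50, seq_id = "s1", feature = "f", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  residue_track(seq_id, seq_len(n), runif(n, 0.01, 0.99),
    feature = feature, space = "normalized"
  )
}

# A tiny deterministic PSSM profile with planted feature values.
tiny_profile <- function(seq_id = "s1", residues = c("M", "K", "V", "A", "L"),
                         ipp = c(0.12, 1.25, 0.3, 2.01, 0),
                         wop_query = c(37L, 0L, 100L, 12L, 5L),
                         rwgrmp = c(0.05, 1.1, 0, 0.42, 2.5)) {
  set.seed(4242)
  make_pssm_profile(seq_id, residues, ipp = ipp, wop_query = wop_query, rwgrmp = rwgrmp)
}

scored_labels <- function(scores, labels) {
  tibble::new_tibble(
    tibble::tibble(seq_id = "s", pos = seq_along(scores), score = scores, label = labels),
    class = "labeled_scores"
  )
}

extract_many <- function(pssms, fun) {
  dplyr::bind_rows(lapply(pssms, fun))
}

small_dataset <- function(n = 12, seed = 7, ...) {
  simulate_dataset(sim_spec(n_sequences = n, length_range = c(60L, 120L), seed = seed, ...))
}
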