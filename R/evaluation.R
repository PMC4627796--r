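# Per-residue ROC analysis of MoRF predictions: residues are pooled across
# sequences (micro-averaging), positives are MoRF residues, negatives are
# all unmasked non-MoRF residues. TPR = TP / N_morf, FPR = FP / N_non_morf;
# a residue is called positive at a threshold t when its score >= t.

#' Pool per-residue scores with labels, applying region masking
#'
#' Joins a score table with interval annotations and removes masked
#' residues. `mask_mode` implements length-based masking of MoRF regions:
#' `"short_only"` masks (removes from evaluation entirely) MoRF intervals
#' longer than `long_cutoff` residues; `"long_only"` masks MoRF intervals of
#' up to `long_cutoff` residues; `"all"` keeps every MoRF. Masked residues
#' count toward neither the positive nor the negative class. Every scored
#' sequence must appear in the annotations.
#'
#' @param scores A `morf_prediction` (its `final` column is used) or a
#'   tibble with `seq_id`, `pos`, `score`.
#' @param annotations Annotation tibble (`seq_id`, `start`, `end`, `label`).
#' @param mask_mode `"all"`, `"short_only"` or `"long_only"`.
#' @param long_cutoff MoRF-length boundary between short and long (30).
#' @return A `labeled_scores` tibble with columns `seq_id`, `pos`, `score`,
#'   `label` (`"morf"` / `"non_morf"`).
#' @export
pool_scores <- function(scores, annotations,
                        mask_mode = c("all", "short_only", "long_only"),
                        long_cutoff = 30L) {
  mask_mode <- match.arg(mask_mode)
  if (inherits(scores, "morf_prediction") || "final" %in% names(scores)) {
    scores <- tibble(seq_id = scores$seq_id, pos = scores$pos, score = scores$final)
  }
  stopifnot(all(c("seq_id", "pos", "score") %in% names(scores)))
  validate_annotations(annotations)
  unann <- setdiff(unique(scores$seq_id), unique(annotations$seq_id))
  if (length(unann) > 0) {
    abort(sprintf("Sequence(s) scored but not annotated: %s.", toString(unann)))
  }
  ann <- annotations |>
    dplyr::mutate(
      len = .data$end - .data$start + 1L,
      label = dplyr::case_when(
        .data$label == "masked" ~ "masked",
        mask_mode == "short_only" & .data$len > long_cutoff ~ "masked",
        mask_mode == "long_only" & .data$len <= long_cutoff ~ "masked",
        .default = "morf"
      )
    )
  res <- purrr::pmap_dfr(
    ann[c("seq_id", "start", "end", "label")],
    function(seq_id, start, end, label) {
      tibble(seq_id = seq_id, pos = seq.int(start, end), label = label)
    }
  )
  out <- scores |>
    dplyr::left_join(res, by = c("seq_id", "pos"), relationship = "one-to-one") |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, "non_morf")) |>
    dplyr::filter(.data$label != "masked")
  tibble::new_tibble(out, class = "labeled_scores")
}

assert_labeled <- function(ls, arg = "ls") {
  if (!is.data.frame(ls) || !all(c("score", "label") %in% names(ls))) {
    abort(sprintf("`%s` must have `score` and `label` columns (see pool_scores()).", arg))
  }
  invisible(ls)
}

# Cumulative TP/FP counts at every distinct threshold, descending; ties at a
# threshold are all called positive together.
roc_points <- function(ls) {
  assert_labeled(ls)
  classes <- unique(ls$label)
  if (!all(c("morf", "non_morf") %in% classes)) {
    abort("ROC analysis needs at least one residue of each class (morf and non_morf).")
  }
  n_pos <- sum(ls$label == "morf")
  n_neg <- sum(ls$label == "non_morf")
  o <- order(ls$score, decreasing = TRUE)
  s <- ls$score[o]
  is_pos <- ls$label[o] == "morf"
  tp <- cumsum(is_pos)
  fp <- cumsum(!is_pos)
  last <- which(!duplicated(s, fromLast = TRUE)) # last index per distinct score
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
}

#' ROC curve over pooled residue scores
#'
#' One point per distinct score threshold (calling positive every residue
#' with score >= threshold), from (0, 0) to (1, 1), monotone in both
#' coordinates.
#'
#' @param ls A `labeled_scores` tibble from [pool_scores()].
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(ls) {
  roc_points(ls)
}

#' Area under the residue-level ROC curve
#'
#' Trapezoidal area under [roc_curve()]; equal to the Mann–Whitney
#' probability that a random MoRF residue outscores a random non-MoRF
#' residue, with ties counted half.
#'
#' @param ls A `labeled_scores` tibble.
#' @return A number in \[0, 1\].
#' @export
auc_morf <- function(ls) {
  r <- roc_points(ls)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' False positive rate at fixed true positive rates
#'
#' For each target TPR, the smallest achievable FPR among thresholds whose
#' TPR is at least the target (discrete score sets rarely reach a target
#' exactly, so the minimal-FPR threshold at or above it is reported).
#'
#' @param ls A `labeled_scores` tibble.
#' @param tpr_targets Numeric targets in (0, 1].
#' @return A tibble with columns `tpr_target`, `fpr`, `threshold`.
#' @export
fpr_at_tpr <- function(ls, tpr_targets = c(0.2, 0.3, 0.4, 0.5)) {
  if (any(tpr_targets <= 0) || any(tpr_targets > 1)) {
    abort("`tpr_targets` must lie in (0, 1].")
  }
  r <- roc_points(ls)
  purrr::map_dfr(tpr_targets, function(tgt) {
    ok <- which(r$tpr >= tgt)
    if (length(ok) == 0) {
      abort(sprintf("TPR target %.3f is unreachable.", tgt))
    }
    i <- ok[which.min(r$fpr[ok])]
    tibble(tpr_target = tgt, fpr = r$fpr[[i]], threshold = r$threshold[[i]])
  })
}

#' Sensitivity and specificity at a score cutoff
#'
#' Sensitivity is the TPR and specificity is 1 - FPR when every residue with
#' score >= cutoff is called a MoRF residue.
#'
#' @param ls A `labeled_scores` tibble.
#' @param cutoff Cutoff in (0, 1).
#' @return A one-row tibble with `cutoff`, `sensitivity`, `specificity`.
#' @export
sens_spec_at_cutoff <- function(ls, cutoff = 0.66) {
  assert_labeled(ls)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie in (0, 1).")
  }
  pos <- ls$score >= cutoff
  tibble(
    cutoff = cutoff,
    sensitivity = sum(pos & ls$label == "morf") / sum(ls$label == "morf"),
    specificity = 1 - sum(pos & ls$label == "non_morf") / sum(ls$label == "non_morf")
  )
}

#' Plot one or several ROC curves
#'
#' @param ls A `labeled_scores` tibble, or a named list of them (one curve
#'   per element, labelled in the legend).
#' @return A ggplot object.
#' @export
plot_roc <- function(ls) {
  if (is.data.frame(ls)) ls <- list(scores = ls)
  curves <- purrr::imap_dfr(ls, function(l, nm) {
    dplyr::mutate(roc_points(l), predictor = sprintf("%s (%.3f)", nm, auc_morf(l)))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$predictor)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      colour = "Predictor (AUC)"
    ) +
    ggplot2::theme_minimal()
}
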