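# Per-sequence track plots, in the style of per-component propensity curves
# along a protein.

#' Plot prediction tracks along a sequence
#'
#' Draws the final fused MoRF propensity together with selected component
#' tracks along one or more sequences, with the calling cutoff as a
#' horizontal reference and called intervals shaded.
#'
#' @param object A `morf_prediction`.
#' @param seq_ids Sequences to plot (default: the first one).
#' @param features Score columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morf_prediction <- function(object, seq_ids = NULL,
                                     features = c("final", "morf_dc", "chibi_n", "disorder_n", "mcs"),
                                     ...) {
  stopifnot(inherits(object, "morf_prediction"))
  if (is.null(seq_ids)) seq_ids <- object$seq_id[[1]]
  cutoff <- attr(object, "cutoff")
  calls <- attr(object, "calls")
  df <- as_tibble(object) |>
    dplyr::filter(.data$seq_id %in% seq_ids) |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature", values_to = "score") |>
    dplyr::mutate(feature = factor(.data$feature, levels = features))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$score, colour = .data$feature))
  if (!is.null(calls) && nrow(calls) > 0) {
    shade <- calls |> dplyr::filter(.data$seq_id %in% seq_ids)
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
        inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
      )
    }
  }
  p +
    ggplot2::geom_line() +
    {
      if (!is.null(cutoff)) {
        ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted", colour = "grey40")
      }
    } +
    ggplot2::facet_wrap(~seq_id, ncol = 1) +
    ggplot2::labs(x = "Residue position", y = "Propensity", colour = "Track") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
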