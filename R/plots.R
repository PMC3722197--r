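#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_abline
#'   labs autoplot scale_y_log10 coord_flip theme_minimal
NULL

#' Training-trace plot for a boosting model
#'
#' Plots the per-round training error and the multiplicative bound given by
#' the cumulative product of the round normalisers.
#'
#' @param object A `boost_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boost_model
#' @export
autoplot.boost_model <- function(object, ...) {
  tr <- object$trace |>
    mutate(bound = cumprod(.data$z)) |>
    tidyr::pivot_longer(c("train_error", "bound"),
                        names_to = "series", values_to = "value")
  ggplot(tr, aes(x = .data$round, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(x = "boosting round", y = NULL, colour = NULL,
         title = "Training error and normaliser bound") +
    theme_minimal()
}

#' Consensus TF significance plot
#'
#' Dot plot of consensus TFs by mean ablation significance, annotated with
#' run support.
#'
#' @param object A `consensus_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_report
#' @export
autoplot.consensus_report <- function(object, ...) {
  d <- mutate(object$tfs, tf = stats::reorder(.data$tf, .data$mean_score))
  ggplot(d, aes(x = .data$mean_score, y = .data$tf)) +
    geom_point(aes(size = .data$support)) +
    labs(x = "mean ablation significance", y = NULL, size = "runs",
         title = "Consensus transcription factors") +
    theme_minimal()
}

#' Bar chart of top enriched terms
#'
#' @param enrichment Result of [enrich_terms()].
#' @param n_terms Number of terms to show, default 15.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, n_terms = 15) {
  d <- enrichment |>
    slice_head(n = n_terms) |>
    mutate(term = stats::reorder(.data$term, -log10(.data$p)))
  ggplot(d, aes(x = -log10(.data$p), y = .data$term, fill = .data$direction)) +
    geom_col() +
    labs(x = expression(-log[10] * "(p)"), y = NULL, fill = NULL,
         title = "Term over/under-representation") +
    theme_minimal()
}

#' Dose-response scatter of per-gene fold changes
#'
#' High- versus low-dose fold changes with the identity line; genes above the
#' line respond more strongly at the higher dose.
#'
#' @param records Tibble with `gene`, `fc_high`, `fc_low`.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(records) {
  ggplot(records, aes(x = .data$fc_low, y = .data$fc_high)) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    scale_y_log10() +
    ggplot2::scale_x_log10() +
    labs(x = "low-dose fold change", y = "high-dose fold change",
         title = "Dose-response relationship") +
    theme_minimal()
}

#' @export
ggplot2::autoplot
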