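# ggplot2 views of the main result types.

#' @describeIn mismatch_combination_table Plot the top combinations of a
#'   landscape as an ordered bar chart.
#' @param object A `combination_table`.
#' @param top_n Number of combinations to show.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.combination_table <- function(object, top_n = 20, ...) {
  tbl <- head(object, top_n)
  lab <- if (isTRUE(attr(object, "ordered"))) {
    paste(tbl$donor_allele, tbl$patient_allele, sep = " → ")
  } else {
    paste(tbl$allele_1, tbl$allele_2, sep = " – ")
  }
  df <- tibble(combination = factor(lab, rev(lab)), freq = tbl$freq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$combination)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = sprintf("Frequency among %s-mismatched pairs (n = %d)",
                  attr(object, "locus"), attr(object, "denominator")),
      y = NULL,
      title = sprintf("Mismatch landscape at HLA-%s%s", attr(object, "locus"),
                      if (!is.null(attr(object, "stratum"))) {
                        paste0(" (", attr(object, "stratum"), " pairs)")
                      } else "")
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_time_to_transplant Plot group medians and
#'   interquartile ranges by era and matching status.
#' @param object A `tx_time_comparison`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.tx_time_comparison <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(
    g,
    ggplot2::aes(x = .data$era, y = .data$median, colour = .data$matching)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::scale_colour_manual(values = c("10/10" = "black",
                                            "<10/10" = "grey55")) +
    ggplot2::labs(x = "Transplant era",
                  y = "Months from diagnosis to transplant",
                  colour = "Matching") +
    ggplot2::theme_minimal()
}

#' Era-stratified matching trends
#'
#' Line plot of 10/10, 12/12 and DPB1 matching proportions across eras.
#'
#' @param summary A `cohort_summary` (or the `era_matching` tibble).
#' @return A ggplot.
#' @export
plot_era_matching <- function(summary) {
  tbl <- if (inherits(summary, "cohort_summary")) summary$era_matching else summary
  long <- tbl |>
    select("era", "pct_10of10", "pct_12of12", "pct_dpb1_matched") |>
    tidyr::pivot_longer(-"era", names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$era, y = .data$pct,
                                     group = .data$metric,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Transplant era", y = "% of pairs", colour = NULL) +
    ggplot2::theme_minimal()
}
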