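#' Volcano plot of a moderated-test result
#'
#' @param x A `moderated_fit`, `bfa_contrasts` element, or tidy contrast
#'   tibble with `l2fc` and `adj_p` columns.
#' @param alpha Significance level drawn as a horizontal guide.
#' @param annotations Optional annotation tibble used to colour points by
#'   signal-peptide status.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, alpha = 0.05, annotations = NULL) {
  if (inherits(x, "moderated_fit")) x <- tidy(x)
  dat <- mutate(x, neglog_p = -log10(pmax(.data$adj_p, 1e-300)))
  if (!is.null(annotations)) {
    dat <- dat |>
      left_join(select(annotations, "accession", "has_signal_peptide"),
                by = c(group_id = "accession")) |>
      mutate(has_signal_peptide = dplyr::coalesce(.data$has_signal_peptide, FALSE))
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$l2fc, .data$neglog_p,
                                           colour = .data$has_signal_peptide))
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$l2fc, .data$neglog_p))
  }
  p +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (treatment vs control)",
                  y = "-log10 adjusted p", colour = "Signal peptide") +
    ggplot2::theme_minimal()
}

#' Bar chart of the signal-peptide percentage per M/L bin
#'
#' @param bins A [bin_signal_peptide_fraction()] result.
#' @return A ggplot object.
#' @export
plot_sp_bins <- function(bins) {
  dat <- mutate(bins, bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(dat, ggplot2::aes(.data$bin, .data$sp_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "M/L ratio bin", y = "% proteins with signal peptide") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a `moderated_fit` draws the volcano plot; on a
#' `ratio_table` it draws the distribution of log2 summary M/L coloured by
#' signal-peptide status.
#'
#' @param object The fitted or ratio object.
#' @param ... Passed on to the underlying plot function.
#' @return A ggplot object.
#' @export
autoplot.moderated_fit <- function(object, ...) plot_volcano(object, ...)

#' @rdname autoplot.moderated_fit
#' @param condition Which condition's summary M/L to plot.
#' @export
autoplot.ratio_table <- function(object, condition = NULL, ...) {
  condition <- condition %||% attr(object, "conditions")[1] %||% "ctrl"
  col <- paste0("log2_ml_", condition)
  dat <- filter(object, .data$detection_status == "both",
                is.finite(.data[[col]]))
  ggplot2::ggplot(dat, ggplot2::aes(.data[[col]],
                                    fill = .data$has_signal_peptide)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::labs(x = sprintf("log2 M/L (%s)", condition), y = "proteins",
                  fill = "Signal peptide") +
    ggplot2::theme_minimal()
}
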