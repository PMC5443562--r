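# ggplot2 views of the main result types.

#' Plot a cofitness profile
#'
#' Histogram of the focal gene's corrected cofitness with every other gene,
#' with predicted targets (if given) marked by vertical lines — the visual
#' behind the rank-based test: validated TFs have a target in the extreme
#' tail of their own cofitness distribution.
#'
#' @param object A [corrected_cofitness_profile()].
#' @param targets Optional locus ids to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cofitness_profile <- function(object, targets = NULL, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$corrected))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$corrected)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", color = "grey40") +
    ggplot2::labs(x = "corrected cofitness", y = "genes",
                  title = sprintf("Cofitness profile of %s", attr(object, "focal"))) +
    ggplot2::theme_minimal()
  if (!is.null(targets)) {
    tdf <- df |> filter(.data$partner %in% targets)
    p <- p + ggplot2::geom_vline(data = tdf,
                                 ggplot2::aes(xintercept = .data$corrected),
                                 color = "firebrick", linewidth = 0.6)
  }
  p
}

#' Plot a validation run
#'
#' One point per tested TF: top cofitness (positive side) or top
#' anti-cofitness (negative side) against the combined p-value of that
#' side, colored by the sign call.
#'
#' @param object A `tf_validation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_validation <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.01
  df <- as_tibble(object) |>
    filter(.data$tested) |>
    mutate(
      r_top = ifelse(.data$p_activator <= .data$p_repressor, .data$r_max, .data$r_min),
      p_top = pmin(.data$p_activator, .data$p_repressor)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_top, y = -log10(.data$p_top),
                                   color = .data$sign)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "top target cofitness (most significant side)",
                  y = expression(-log[10](p)), color = "sign call") +
    ggplot2::theme_minimal()
}

#' Plot the polar-effect comparison
#'
#' Validation-rate difference (polar-flagged minus other predictions) with
#' its 95% CI, per direction. Polar effects predict an excess only in the
#' positive-cofitness direction.
#'
#' @param object A `polar_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.polar_comparison <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$direction, y = .data$diff)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$diff - .data$ci95,
                                          ymax = .data$diff + .data$ci95)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "validation-rate difference (polar - other)") +
    ggplot2::theme_minimal()
}
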