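# ggplot2 autoplot methods for the main result types

#' Plot a library-screen result
#'
#' Variants in screening order against their normalized response, with the
#' 2-sigma threshold as a horizontal line; hits highlighted, the mock level
#' dashed.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- object$variants |> mutate(rank = row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$normalized_rlu)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_hit), size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, colour = "red") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red3"), guide = "none"
    ) +
    ggplot2::labs(
      x = "OR variant", y = "normalized response (RLU)",
      title = sprintf("2σ threshold = %.3g; %d hit(s)",
        object$threshold, length(object$hits))
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$mock_rlu)) {
    p <- p + ggplot2::geom_hline(yintercept = object$mock_rlu,
      linetype = "dashed", colour = "grey60")
  }
  p
}

#' Plot a concentration-response curve
#'
#' Responses on a log10 concentration axis; when a fit is supplied its
#' Hill function is overlaid.
#'
#' @param object A `dose_response_curve` from [build_curve()].
#' @param fit Optional `hill_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response_curve
#' @export
autoplot.dose_response_curve <- function(object, fit = NULL, ...) {
  df <- as_tibble(object) |> filter(.data$conc_umolL > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_umolL, y = .data$response)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate))) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (µmol/L)", y = "normalized response",
      shape = "replicate",
      title = paste(df$variant_id[1], "/", df$odorant[1])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble(
      conc_umolL = 10^seq(log10(min(df$conc_umolL)), log10(max(df$conc_umolL)),
        length.out = 200)
    ) |>
      mutate(response = hill_function(.data$conc_umolL, fit$min, fit$max,
        fit$ec50_umolL, fit$hillslope))
    p <- p + ggplot2::geom_line(data = grid, colour = "red3")
  }
  p
}
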