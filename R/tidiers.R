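# broom-style tidiers for the package's result objects

#' Tidy a screen result
#'
#' @param x A `screen_result` from [call_hits()].
#' @param ... Unused.
#' @return One row per screened variant: `variant_id`, `normalized_rlu`,
#'   `is_hit`, `is_false_positive`.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  x$variants
}

#' Glance at a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A one-row tibble: `screen_mean`, `screen_sd`, `threshold`,
#'   `n_variants`, `n_hits`, `fp_fraction`, `mock_rlu`.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    screen_mean = x$screen_mean, screen_sd = x$screen_sd,
    threshold = x$threshold, n_variants = x$n_variants,
    n_hits = length(x$hits), fp_fraction = x$fp_fraction,
    mock_rlu = x$mock_rlu
  )
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c("min", "max", "ec50_umolL", "hillslope"),
    estimate = c(x$min, x$max, x$ec50_umolL, x$hillslope)
  )
}

#' Glance at a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `converged`, `residual_ss`, `n`.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(converged = x$converged, residual_ss = x$residual_ss, n = x$n)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> ", x$variant_id, " / ", x$odorant,
    " (replicate ", x$replicate, ")\n", sep = "")
  cat(sprintf("  EC50 %.4g umol/L, Hillslope %.3g, min %.3g, max %.3g\n",
    x$ec50_umolL, x$hillslope, x$min, x$max))
  cat(sprintf("  converged: %s, residual SS %.3g (n = %d)\n",
    x$converged, x$residual_ss, x$n))
  invisible(x)
}
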