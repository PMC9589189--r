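# Internal-standard quantification of aldehyde emissions and the strain
# fold-ratio statistic.

#' Internal-standard quantification of analyte amounts
#'
#' Single-point internal-standard quantification with a unit response
#' factor: `amount = is_ng * area(analyte) / area(internal standard)`.
#' The response factor is a configurable constant (no per-analyte
#' calibration curve is modelled).
#'
#' @param samples Headspace tibble in the [gen_headspace()] schema.
#' @param analyte `"z4_9al"` or `"z4_11al"` (matching the
#'   `area_<analyte>` column).
#' @param response_factor Analyte/IS response factor (default 1).
#' @return The input with an added `ng_<analyte>` column.
#' @export
#' @examples
#' hs <- gen_headspace(headspace_preset("zimbabwe", seed = 1))
#' quantify(hs, "z4_11al")
quantify <- function(samples, analyte = c("z4_9al", "z4_11al"),
                     response_factor = 1) {
  analyte <- match.arg(analyte)
  area_col <- paste0("area_", analyte)
  if (!area_col %in% names(samples)) {
    abort_data(paste0("analyte column not present: ", area_col))
  }
  if (any(samples$area_is <= 0)) {
    abort(paste0("zero or negative internal-standard area in sample(s): ",
      paste(samples$sample_id[samples$area_is <= 0], collapse = ", ")),
      class = "orscreen_degenerate_sample")
  }
  samples[[paste0("ng_", analyte)]] <-
    samples$is_ng * samples[[area_col]] / (samples$area_is * response_factor)
  samples
}

#' Per-sample Z4-9Al / Z4-11Al fold ratio
#'
#' Quantifies both aldehydes against the internal standard and returns the
#' arithmetic mean and sample SD of the per-sample ratio (mean of ratios,
#' not ratio of means). The ratio is invariant to the internal-standard
#' area and amount, which cancel.
#'
#' @param samples Headspace tibble in the [gen_headspace()] schema.
#' @return A one-row tibble `mean_ratio`, `sd_ratio`, `n`, with the
#'   per-sample table (including `ratio`) as attribute `"samples"`.
#' @export
#' @examples
#' fold_ratio(gen_headspace(headspace_preset("zimbabwe", seed = 1)))
fold_ratio <- function(samples) {
  q <- samples |>
    quantify("z4_9al") |>
    quantify("z4_11al")
  zero <- q$sample_id[q$ng_z4_11al <= 0]
  if (length(zero) > 0) {
    abort(paste0("Z4-11Al amount is zero in sample(s): ",
      paste(zero, collapse = ", ")), class = "orscreen_undefined_ratio")
  }
  q <- q |> mutate(ratio = .data$ng_z4_9al / .data$ng_z4_11al)
  structure(
    tibble(
      mean_ratio = mean(q$ratio),
      sd_ratio = if (nrow(q) > 1) sd(q$ratio) else 0,
      n = nrow(q)
    ),
    samples = q
  )
}
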