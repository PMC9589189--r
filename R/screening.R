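# Library-screen analysis: well summarization, reference normalization,
# duplicate averaging, 2-sigma hit calling, false-positive classification.

#' Basal-subtracted well signals
#'
#' Averages the three basal and the three post-stimulus reads of every well
#' and subtracts the basal average from the post average. The result may be
#' negative; negative signals are retained throughout.
#'
#' @param wells A plate tibble in the [gen_screen()] schema.
#' @return The input with an added `signal` column (LU).
#' @export
#' @examples
#' wells <- gen_screen(screen_config(n_variants = 10, seed = 1))
#' summarize_wells(wells)
summarize_wells <- function(wells) {
  req <- c(paste0("basal_", 1:3), paste0("post_", 1:3))
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0("malformed well record: missing ", paste(missing_cols, collapse = ", ")),
      class = "orscreen_malformed_record")
  }
  reads <- wells[, req]
  if (anyNA(reads)) {
    abort("malformed well record: NA reads", class = "orscreen_malformed_record")
  }
  wells |>
    mutate(signal = (.data$post_1 + .data$post_2 + .data$post_3) / 3 -
      (.data$basal_1 + .data$basal_2 + .data$basal_3) / 3)
}

#' Normalize a screen to the per-plate positive control
#'
#' Divides every well's basal-subtracted signal by the summarized signal of
#' that plate's OR1A1 + R-(-)-carvone positive-control wells, then averages
#' duplicate wells per variant (normalization before averaging). Mock wells
#' are normalized identically and reported alongside with role `"mock"`.
#'
#' @param wells A plate tibble ([gen_screen()] schema), one or more plates.
#' @return A tibble of per-variant averaged normalized values
#'   (`variant_id`, `role`, `normalized_rlu`, `n_wells`), with the per-well
#'   normalized table attached as attribute `"wells"`.
#' @export
normalize_screen <- function(wells) {
  ws <- summarize_wells(wells)

  ref <- ws |>
    filter(.data$role == "positive") |>
    group_by(.data$plate_id) |>
    summarise(ref_signal = mean(.data$signal), .groups = "drop")
  missing_ref <- setdiff(unique(ws$plate_id), ref$plate_id)
  if (length(missing_ref) > 0) {
    abort(paste0("no positive-control well on plate(s): ",
      paste(missing_ref, collapse = ", ")), class = "orscreen_degenerate_reference")
  }
  bad <- ref |> filter(.data$ref_signal <= 0)
  if (nrow(bad) > 0) {
    abort(paste0("non-positive positive-control signal on plate(s): ",
      paste(bad$plate_id, collapse = ", ")), class = "orscreen_degenerate_reference")
  }

  per_well <- ws |>
    left_join(ref, by = "plate_id") |>
    mutate(normalized = .data$signal / .data$ref_signal) |>
    select("plate_id", "well_id", "variant_id", "role", "normalized")

  per_variant <- per_well |>
    group_by(.data$variant_id, .data$role) |>
    summarise(
      normalized_rlu = mean(.data$normalized), n_wells = dplyr::n(),
      .groups = "drop"
    )

  singletons <- per_variant |>
    filter(.data$role == "test", .data$n_wells == 1L)
  if (nrow(singletons) > 0 && any(per_variant$n_wells > 1L)) {
    warn(paste0("unpaired singleton well(s) for: ",
      paste(utils::head(singletons$variant_id, 5), collapse = ", ")))
  }

  structure(per_variant, wells = per_well)
}

#' Call screen hits above a 2-sigma threshold
#'
#' Computes the screen-wide mean and standard deviation of normalized test
#' signals (mock and positive-control wells excluded) and flags variants
#' whose duplicate-averaged normalized value strictly exceeds
#' `mean + 2 * SD`.
#'
#' The dispersion can be taken over per-well normalized signals
#' (`stat_level = "wells"`, the default when per-well data are available)
#' or over the per-variant duplicate averages (`"variants"`). Well-level
#' dispersion uses the replicate wells' technical variation and keeps the
#' null exceedance rate of duplicate averages well below 2%; it is the
#' package default for full screens (see the methods vignette). A bare
#' per-variant table falls back to variant-level statistics.
#'
#' @param normalized Output of [normalize_screen()], or any tibble with
#'   `variant_id` and `normalized_rlu` columns (an optional `role` column
#'   restricts statistics to `"test"` rows).
#' @param sd_convention `"sample"` (n - 1, default) or `"population"`.
#' @param stat_level `"auto"`, `"wells"` or `"variants"`.
#' @return A `screen_result` object; see [tidy.screen_result()] and
#'   [glance.screen_result()].
#' @export
#' @examples
#' wells <- gen_screen(screen_config(n_variants = 50, seed = 1))
#' res <- call_hits(normalize_screen(wells))
#' glance(res)
call_hits <- function(normalized,
                      sd_convention = c("sample", "population"),
                      stat_level = c("auto", "wells", "variants")) {
  sd_convention <- match.arg(sd_convention)
  stat_level <- match.arg(stat_level)
  per_well <- attr(normalized, "wells")
  if (stat_level == "auto") {
    stat_level <- if (is.null(per_well)) "variants" else "wells"
  }
  if (stat_level == "wells" && is.null(per_well)) {
    abort_data("stat_level = 'wells' needs per-well data from normalize_screen()")
  }

  tab <- as_tibble(normalized)
  if (!"role" %in% names(tab)) tab$role <- "test"
  test <- tab |> filter(.data$role == "test")
  if (nrow(test) < 2) {
    abort("need >= 2 test variants to define a screen SD",
      class = "orscreen_insufficient_data")
  }

  stat_values <- if (stat_level == "wells") {
    per_well$normalized[per_well$role == "test"]
  } else {
    test$normalized_rlu
  }
  screen_mean <- mean(stat_values)
  screen_sd <- sd_by_convention(stat_values, sd_convention)
  threshold <- screen_mean + 2 * screen_sd

  variants <- test |>
    mutate(
      is_hit = .data$normalized_rlu > threshold,
      is_false_positive = NA
    ) |>
    select("variant_id", "normalized_rlu", "is_hit", "is_false_positive")

  mock_rlu <- if (any(tab$role == "mock")) {
    mean(tab$normalized_rlu[tab$role == "mock"])
  } else {
    NA_real_
  }

  structure(
    list(
      variants = variants,
      screen_mean = screen_mean, screen_sd = screen_sd,
      threshold = threshold,
      sd_convention = sd_convention, stat_level = stat_level,
      mock_rlu = mock_rlu,
      n_variants = nrow(variants),
      hits = variants$variant_id[variants$is_hit],
      false_positives = character(0),
      fp_fraction = NA_real_
    ),
    class = "screen_result"
  )
}

#' Classify screen hits as validated or false positive
#'
#' False positives are hits that did not show concentration-dependent
#' activation in follow-up experiments. The false-positive fraction is the
#' number of unvalidated hits divided by the number of screened variants.
#'
#' @param result A `screen_result` from [call_hits()].
#' @param validations Named logical vector (or tibble with `variant_id`,
#'   `validated`) covering every hit; `TRUE` means the hit showed
#'   concentration-dependent activation.
#' @return The updated `screen_result` with `false_positives` and
#'   `fp_fraction` populated.
#' @export
classify_false_positives <- function(result, validations) {
  stopifnot(inherits(result, "screen_result"))
  if (is.data.frame(validations)) {
    validations <- setNames(validations$validated, validations$variant_id)
  }
  hits <- result$hits
  missing_v <- setdiff(hits, names(validations))
  if (length(missing_v) > 0) {
    abort(paste0("missing validation for hit(s): ",
      paste(missing_v, collapse = ", ")), class = "orscreen_incomplete_validation")
  }
  fp <- if (length(hits) == 0) character(0) else hits[!validations[hits]]
  result$false_positives <- fp
  result$fp_fraction <- length(fp) / result$n_variants
  result$variants <- result$variants |>
    mutate(is_false_positive = if_else(.data$is_hit,
      .data$variant_id %in% fp, NA))
  result
}

#' Run the full screen analysis on a plate table
#'
#' Convenience wrapper: [summarize_wells()] then [normalize_screen()] then
#' [call_hits()].
#'
#' @inheritParams call_hits
#' @param wells A plate tibble in the [gen_screen()] schema.
#' @return A `screen_result`.
#' @export
run_screen <- function(wells, sd_convention = c("sample", "population"),
                       stat_level = c("auto", "wells", "variants")) {
  call_hits(normalize_screen(wells),
    sd_convention = sd_convention, stat_level = stat_level)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", x$n_variants, " variants; threshold ",
    signif(x$threshold, 4), " (mean ", signif(x$screen_mean, 3), " + 2 x SD ",
    signif(x$screen_sd, 3), ", ", x$sd_convention, " SD, ", x$stat_level,
    "-level)\n", sep = "")
  cat("hits: ", if (length(x$hits)) paste(x$hits, collapse = ", ") else "none",
    "\n", sep = "")
  if (!is.na(x$fp_fraction)) {
    cat("false positives: ", length(x$false_positives), " (",
      signif(100 * x$fp_fraction, 3), "% of variants)\n", sep = "")
  }
  invisible(x)
}
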