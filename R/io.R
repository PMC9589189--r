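# Plain-CSV readers/writers for the pipeline's table schemas, plus JSON
# summaries. All readers validate the header columns.

check_schema <- function(tab, required, what) {
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort_data(paste0(what, " table is missing column(s): ",
      paste(missing_cols, collapse = ", ")))
  }
  tab
}

plate_schema <- c("plate_id", "well_id", "variant_id", "role", "odorant",
  "conc_umolL", paste0("basal_", 1:3), paste0("post_", 1:3))

#' Read and write plate CSV tables
#'
#' Plate tables use the schema
#' `plate_id,well_id,variant_id,role,odorant,conc_umolL,basal_1..3,post_1..3`
#' with `role` one of `test`, `mock`, `positive`.
#'
#' @param file Path to a CSV file.
#' @return A validated tibble of wells.
#' @export
read_plate_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE) |>
    check_schema(plate_schema, "plate")
}

#' @rdname read_plate_csv
#' @param wells A plate tibble.
#' @export
write_plate_csv <- function(wells, file) {
  readr::write_csv(check_schema(wells, plate_schema, "plate"), file)
  invisible(file)
}

#' Read a panel CSV table
#'
#' Schema:
#' `panelist_id,or10a6_diplotype,or2w1_diplotype,trial_id,odorant,amount_ng,correct`.
#'
#' @param file Path to a CSV file.
#' @return A validated tibble.
#' @export
read_panel_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE) |>
    check_schema(c("panelist_id", "or10a6_diplotype", "or2w1_diplotype",
      "trial_id", "odorant", "amount_ng", "correct"), "panel")
}

#' Read a headspace CSV table
#'
#' Schema: `sample_id,strain,area_z4_9al,area_z4_11al,area_is,is_ng`.
#'
#' @param file Path to a CSV file.
#' @return A validated tibble.
#' @export
read_headspace_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE) |>
    check_schema(c("sample_id", "strain", "area_z4_9al", "area_z4_11al",
      "area_is", "is_ng"), "headspace")
}

#' Read a genotype-calls CSV table
#'
#' Schema: `panelist_id,site,allele1,allele2`.
#'
#' @param file Path to a CSV file.
#' @return A validated tibble.
#' @export
read_genotype_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE) |>
    check_schema(c("panelist_id", "site", "allele1", "allele2"), "genotype")
}

#' Write a screen result to CSV + JSON
#'
#' Writes `variant_id,normalized_rlu,is_hit,is_false_positive` to
#' `<stem>.csv` and the screen summary (mean, SD, threshold, hit count,
#' false-positive fraction) to `<stem>.json`.
#'
#' @param result A `screen_result`.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_screen_result <- function(result, stem) {
  stopifnot(inherits(result, "screen_result"))
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  readr::write_csv(tidy(result), csv)
  jsonlite::write_json(as.list(glance(result)), json, auto_unbox = TRUE,
    digits = NA)
  invisible(c(csv, json))
}
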