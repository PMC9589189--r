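#' Reference EC50 table for OR10A6 and OR2W1 haplotypes
#'
#' Published concentration-response summaries (mean EC50 and its SD over
#' n = 3 transfection replicates, micromol/L) for the OR10A6 and OR2W1
#' haplotypes against the three monounsaturated aldehydes Z4-9Al, Z4-11Al
#' and Z6-11Al. `NA` rows are nonresponders ("ND": no response detected up
#' to 1000 micromol/L). The `amplitude` and `hillslope` columns are
#' generator defaults (fraction of the positive-control amplitude and Hill
#' coefficient); the source assay reports neither, so these are package
#' defaults chosen from the relative screen amplitudes (see the methods
#' vignette) and are only used to parameterize synthetic curves.
#'
#' @return A tibble with columns `variant_id`, `odorant`,
#'   `ec50_umolL`, `ec50_sd`, `amplitude`, `hillslope`, `responder`.
#' @export
#' @examples
#' or_ec50_reference()
or_ec50_reference <- function() {
  tab <- tibble::tribble(
    ~variant_id,                       ~odorant,   ~ec50_umolL, ~ec50_sd, ~amplitude,
    "OR10A6 ref",                      "Z4-9Al",   NA,          NA,       0,
    "OR10A6 ref",                      "Z4-11Al",  NA,          NA,       0,
    "OR10A6 ref",                      "Z6-11Al",  NA,          NA,       0,
    "OR10A6 L287P",                    "Z4-9Al",   41.15,       14.24,    0.9,
    "OR10A6 L287P",                    "Z4-11Al",  28.21,       12.65,    1.0,
    "OR10A6 L287P",                    "Z6-11Al",  34.78,       9.21,     0.8,
    "OR10A6 A117V/V140G/L287P",        "Z4-9Al",   NA,          NA,       0,
    "OR10A6 A117V/V140G/L287P",        "Z4-11Al",  NA,          NA,       0,
    "OR10A6 A117V/V140G/L287P",        "Z6-11Al",  NA,          NA,       0,
    "OR2W1 ref",                       "Z4-9Al",   119.31,      23.09,    0.8,
    "OR2W1 ref",                       "Z4-11Al",  65.11,       35.75,    0.2,
    "OR2W1 ref",                       "Z6-11Al",  103.73,      27.01,    0.4,
    "OR2W1 M81V",                      "Z4-9Al",   142.09,      92.38,    0.5,
    "OR2W1 M81V",                      "Z4-11Al",  NA,          NA,       0,
    "OR2W1 M81V",                      "Z6-11Al",  NA,          NA,       0,
    "OR2W1 D296N",                     "Z4-9Al",   91.82,       46.19,    0.8,
    "OR2W1 D296N",                     "Z4-11Al",  40.42,       11.98,    0.3,
    "OR2W1 D296N",                     "Z6-11Al",  137.89,      54.98,    0.4
  )
  tab$hillslope <- 1.2
  tab$responder <- !is.na(tab$ec50_umolL)
  tab
}

#' Haplotype definitions and population frequencies for OR10A6 and OR2W1
#'
#' Reads the versioned haplotype-definition table shipped with the package:
#' haplotype labels, their constituent variant sites (rs identifiers),
#' population frequencies from two human-genome-database sources (minor
#' allele frequency, `maf_pct`, and haplotype frequency, `freq_pct`), and a
#' functional flag (whether the haplotype responds to Z4-11Al in the
#' heterologous assay; for OR10A6 only L287P is functional).
#'
#' @param file Path to an alternative definitions CSV (same schema).
#' @return A tibble with columns `gene`, `haplotype_label`, `variant_sites`
#'   (semicolon-separated rs ids, empty for the reference haplotype),
#'   `accession_or_rsid`, `maf_pct`, `freq_pct`, `functional`.
#' @export
#' @examples
#' or_haplotype_defs()
or_haplotype_defs <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "or_haplotype_defs.csv", package = "orscreen")
  }
  readr::read_csv(
    file,
    col_types = readr::cols(
      gene = readr::col_character(),
      haplotype_label = readr::col_character(),
      variant_sites = readr::col_character(),
      accession_or_rsid = readr::col_character(),
      maf_pct = readr::col_double(),
      freq_pct = readr::col_double(),
      functional = readr::col_logical()
    )
  ) |>
    dplyr::mutate(variant_sites = dplyr::coalesce(.data$variant_sites, ""))
}

# standard atomic weights (IUPAC 2021 conventional values)
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, F = 18.998, Cl = 35.45
)

#' Describe an odorant by molecular formula
#'
#' Builds an odorant specification whose molar mass is derived from the
#' molecular formula using standard atomic weights.
#'
#' @param name Odorant label, e.g. `"Z4-11Al"`.
#' @param formula Molecular formula string, e.g. `"C11H20O"`.
#' @return A tibble row with `name`, `formula`, `molar_mass_g_per_mol`.
#' @export
#' @examples
#' odorant_spec("Z4-11Al", "C11H20O")
odorant_spec <- function(name, formula) {
  tibble(
    name = name, formula = formula,
    molar_mass_g_per_mol = molar_mass(formula)
  )
}

#' Molar mass from a molecular formula
#'
#' @param formula Formula string such as `"C11H20O"`.
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' molar_mass("C11H20O")
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) abort_config("empty molecular formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    abort_config(paste0("cannot parse molecular formula: ", formula))
  }
  elements <- gsub("[0-9]", "", tokens)
  counts <- as.integer(ifelse(gsub("[A-Za-z]", "", tokens) == "", "1",
    gsub("[A-Za-z]", "", tokens)
  ))
  unknown <- setdiff(elements, names(.atomic_weights))
  if (length(unknown) > 0) {
    abort_config(paste0("no atomic weight for element(s): ",
      paste(unknown, collapse = ", ")))
  }
  sum(.atomic_weights[elements] * counts)
}

#' Built-in odorant specifications
#'
#' The three fly-derived monounsaturated aldehydes and the decanal internal
#' standard, with formula-derived molar masses.
#'
#' @return A tibble of odorant specs.
#' @export
or_odorants <- function() {
  dplyr::bind_rows(
    odorant_spec("Z4-11Al", "C11H20O"),
    odorant_spec("Z4-9Al", "C9H16O"),
    odorant_spec("Z6-11Al", "C11H20O"),
    odorant_spec("decanal", "C10H20O")
  )
}

#' Convert a mass concentration to molarity
#'
#' Converts ng/mL (equivalently microgram/L) to micromol/L using the
#' odorant's formula-derived molar mass: micromol/L = (ng/mL) / (g/mol).
#'
#' @param conc_ng_per_mL Concentration in ng/mL (non-negative).
#' @param spec An odorant spec from [odorant_spec()] (single row).
#' @return Concentration in micromol/L.
#' @export
#' @examples
#' ng_per_ml_to_umol_per_L(1, odorant_spec("Z4-11Al", "C11H20O"))
ng_per_ml_to_umol_per_L <- function(conc_ng_per_mL, spec) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1L)
  if (any(conc_ng_per_mL < 0)) abort_config("concentration must be non-negative")
  conc_ng_per_mL / spec$molar_mass_g_per_mol
}

#' @rdname ng_per_ml_to_umol_per_L
#' @param conc_umol_per_L Concentration in micromol/L.
#' @export
umol_per_L_to_ng_per_ml <- function(conc_umol_per_L, spec) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1L)
  conc_umol_per_L * spec$molar_mass_g_per_mol
}
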