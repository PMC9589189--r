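# Discrimination-test statistics and the genotype-based expectation model
# for panel performance.

#' Chi-square goodness of fit for a forced-choice trial
#'
#' Pearson chi-square (1 df) of the observed correct/incorrect split
#' against the chance expectation `(p0, 1 - p0)`; `p0 = 1/3` for a triangle
#' or odd-one-out test, `1/2` for a binary resemblance judgement. The Yates
#' continuity correction subtracts 0.5 from each absolute deviation.
#'
#' @param n_correct,n_total Correct answers and trial count.
#' @param p0 Chance probability of a correct answer.
#' @param correction `"none"` (default) or `"yates"`.
#' @return A tibble with `n_correct`, `n_total`, `p0`, `chi2`, `p_value`.
#' @export
#' @examples
#' goodness_of_fit(20, 29, p0 = 1 / 3)
goodness_of_fit <- function(n_correct, n_total, p0 = 1 / 3,
                            correction = c("none", "yates")) {
  correction <- match.arg(correction)
  if (n_total < 1) abort_data("n_total must be >= 1")
  if (n_correct < 0 || n_correct > n_total) {
    abort_data("n_correct must lie in [0, n_total]")
  }
  if (p0 <= 0 || p0 >= 1) {
    abort("expected count would be zero; p0 must lie in (0, 1)",
      class = "orscreen_degenerate_expectation")
  }
  obs <- c(n_correct, n_total - n_correct)
  exp <- n_total * c(p0, 1 - p0)
  dev <- abs(obs - exp)
  if (correction == "yates") dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / exp)
  tibble(
    n_correct = n_correct, n_total = n_total, p0 = p0,
    chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}

#' Genotype-based expectation for the number of correct panel answers
#'
#' Carriers of the functional haplotype answer correctly with probability
#' `p_detect`, the remaining panelists with chance probability `p_chance`;
#' the number correct is then the sum of two independent binomials. The
#' expectation is `n_carriers * p_detect + (n_total - n_carriers) *
#' p_chance` and the exact distribution is the convolution
#' `Binomial(n_carriers, p_detect) * Binomial(n_total - n_carriers,
#' p_chance)`.
#'
#' @param n_carriers Number of functional-haplotype carriers.
#' @param n_total Panel size (>= `n_carriers`).
#' @param p_detect Probability a carrier answers correctly.
#' @param p_chance Probability a non-carrier answers correctly.
#' @return A list with `expectation` (numeric) and `distribution` (tibble
#'   `k`, `prob` over 0..n_total).
#' @export
#' @examples
#' expected_correct(14, 29, p_detect = 1, p_chance = 1 / 3)$expectation # 19
expected_correct <- function(n_carriers, n_total, p_detect, p_chance) {
  if (n_carriers > n_total || n_carriers < 0) {
    abort_config("need 0 <= n_carriers <= n_total")
  }
  if (any(c(p_detect, p_chance) < 0 | c(p_detect, p_chance) > 1)) {
    abort_config("probabilities must lie in [0, 1]")
  }
  n_other <- n_total - n_carriers
  pc <- dbinom(0:n_carriers, n_carriers, p_detect)
  po <- dbinom(0:n_other, n_other, p_chance)
  prob <- as.numeric(stats::convolve(pc, rev(po), type = "open"))
  prob <- pmax(prob, 0)
  prob <- prob / sum(prob)
  list(
    expectation = n_carriers * p_detect + n_other * p_chance,
    distribution = tibble(k = 0:n_total, prob = prob)
  )
}

#' Count carriers of a variant among panelists
#'
#' A panelist is a carrier when at least one haplotype of the relevant
#' diplotype bears the named variant's site (so composite haplotypes that
#' include the site count as carriers). Percentages are reported to one
#' decimal.
#'
#' @param panelists Panel tibble in the [gen_panel()] schema (one or more
#'   rows per panelist; diplotypes are taken from the first row of each).
#' @param variant Single-variant label, e.g. `"L287P"` (OR10A6) or
#'   `"D296N"` (OR2W1).
#' @param defs Haplotype definition table.
#' @return A tibble with `variant`, `gene`, `n_carriers`, `n_total`,
#'   `pct_carriers`.
#' @export
#' @examples
#' pan <- gen_panel(panel_config(n_panelists = 29, seed = 1))
#' carrier_summary(pan, "L287P")
carrier_summary <- function(panelists, variant, defs = or_haplotype_defs()) {
  site_row <- defs |>
    filter(.data$haplotype_label == !!variant, nzchar(.data$variant_sites),
      !grepl(";", .data$variant_sites))
  if (nrow(site_row) != 1) {
    abort(paste0("unknown single-site variant label: ", variant),
      class = "orscreen_unknown_variant")
  }
  gene <- site_row$gene
  dip_col <- if (gene == "OR10A6") "or10a6_diplotype" else "or2w1_diplotype"
  if (!dip_col %in% names(panelists)) {
    abort_data(paste0("panel table lacks column ", dip_col))
  }

  per_panelist <- panelists |>
    group_by(.data$panelist_id) |>
    summarise(dip = dplyr::first(.data[[dip_col]]), .groups = "drop")
  if (anyNA(per_panelist$dip)) abort_data("missing diplotypes")

  haps <- strsplit(per_panelist$dip, "|", fixed = TRUE)
  carrier <- vapply(haps, function(h) {
    any(vapply(h, function(lbl) is_carrier_label(lbl, site_row$variant_sites,
      defs, gene), logical(1)))
  }, logical(1))

  n <- nrow(per_panelist)
  tibble(
    variant = variant, gene = gene,
    n_carriers = sum(carrier), n_total = n,
    pct_carriers = round(100 * sum(carrier) / n, 1)
  )
}

# does the haplotype labelled `lbl` (within `gene`) carry `site`?
is_carrier_label <- function(lbl, site, defs, gene) {
  row <- defs |>
    filter(.data$gene == !!gene, .data$haplotype_label == !!lbl)
  if (nrow(row) != 1) {
    abort(paste0("unknown haplotype label: ", lbl),
      class = "orscreen_unknown_haplotype")
  }
  site %in% strsplit(row$variant_sites, ";", fixed = TRUE)[[1]]
}

#' Summarize correct answers per trial
#'
#' @param panelists Panel tibble in the [gen_panel()] schema.
#' @return A tibble per trial: `trial_id`, `odorant`, `amount_ng`,
#'   `n_correct`, `n_total`.
#' @export
trial_summary <- function(panelists) {
  panelists |>
    group_by(.data$trial_id, .data$odorant, .data$amount_ng) |>
    summarise(
      n_correct = sum(.data$correct), n_total = dplyr::n(),
      .groups = "drop"
    )
}
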