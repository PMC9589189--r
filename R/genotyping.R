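# Haplotype assignment from per-site variant calls. A computational
# stand-in for manual Sanger-chromatogram haplotyping: unphased per-site
# genotypes are matched against the shipped haplotype definitions, and
# phase ambiguity is resolved by the population-frequency prior.

hap_site_list <- function(defs, gene) {
  d <- defs |> filter(.data$gene == !!gene)
  if (nrow(d) == 0) abort_data(paste0("no haplotype definitions for ", gene))
  sites <- lapply(strsplit(d$variant_sites, ";", fixed = TRUE), \(s) s[nzchar(s)])
  names(sites) <- d$haplotype_label
  sites
}

hap_freq <- function(defs, gene, freq_source) {
  d <- defs |> filter(.data$gene == !!gene)
  f <- if (freq_source == "panel") d$freq_pct else d$maf_pct
  # frequency floor for haplotypes absent from the chosen source, so they
  # stay assignable but never beat an observed haplotype in the prior
  f[is.na(f)] <- 0.01
  setNames(f, d$haplotype_label)
}

#' Assign a diplotype from unphased per-site genotypes
#'
#' Enumerates all unordered pairs of defined haplotypes and keeps those
#' whose per-site alternate-allele dosage matches every call. When several
#' pairs are consistent (phase ambiguity, as in a sample heterozygous at
#' multiple sites), the pair maximizing the product of population
#' frequencies is returned and the ambiguity flag is set.
#'
#' @param calls Tibble with columns `site`, `allele1`, `allele2`
#'   (`"ref"`/`"alt"` calls, unphased), covering every site of the gene's
#'   definitions.
#' @param gene `"OR10A6"` or `"OR2W1"`.
#' @param defs Haplotype definition table ([or_haplotype_defs()] schema).
#' @param freq_source `"panel"` (haplotype frequencies) or `"maf"`.
#' @return A one-row tibble: `gene`, `hap1`, `hap2` (alphabetical),
#'   `ambiguous`.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   site = c("rs79284513", "rs79338074", "rs4758258"),
#'   allele1 = c("ref", "ref", "alt"), allele2 = c("ref", "ref", "alt")
#' )
#' assign_diplotype(calls, "OR10A6")
assign_diplotype <- function(calls, gene, defs = or_haplotype_defs(),
                             freq_source = c("panel", "maf")) {
  freq_source <- match.arg(freq_source)
  sites <- hap_site_list(defs, gene)
  all_sites <- unique(unlist(sites))
  missing_sites <- setdiff(all_sites, calls$site)
  if (length(missing_sites) > 0) {
    abort_data(paste0("calls do not cover site(s): ",
      paste(missing_sites, collapse = ", ")))
  }
  ok <- calls$allele1 %in% c("ref", "alt") & calls$allele2 %in% c("ref", "alt")
  if (!all(ok)) abort_data("allele calls must be 'ref' or 'alt'")

  dosage <- setNames(
    (calls$allele1 == "alt") + (calls$allele2 == "alt"),
    calls$site
  )[all_sites]

  labels <- names(sites)
  carries <- vapply(labels, \(h) all_sites %in% sites[[h]], logical(length(all_sites)))
  carries <- matrix(carries, nrow = length(all_sites),
    dimnames = list(all_sites, labels))

  pairs <- expand.grid(i = seq_along(labels), j = seq_along(labels)) |>
    filter(.data$i <= .data$j)
  consistent <- vapply(seq_len(nrow(pairs)), function(r) {
    all(carries[, pairs$i[r]] + carries[, pairs$j[r]] == dosage)
  }, logical(1))

  if (!any(consistent)) {
    abort(paste0("no defined diplotype is consistent with the calls at: ",
      paste(all_sites[dosage > 0], collapse = ", ")),
      class = "orscreen_inconsistent_calls")
  }

  hits <- pairs[consistent, , drop = FALSE]
  freqs <- hap_freq(defs, gene, freq_source)
  score <- freqs[labels[hits$i]] * freqs[labels[hits$j]]
  best <- which.max(score)
  h1 <- labels[hits$i[best]]
  h2 <- labels[hits$j[best]]
  tibble(
    gene = gene,
    hap1 = min(h1, h2), hap2 = max(h1, h2),
    ambiguous = nrow(hits) > 1
  )
}

#' Regenerate per-site genotype calls from a diplotype
#'
#' Inverse of [assign_diplotype()]: the alternate-allele dosage at each
#' site is the number of haplotypes in the pair that carry it.
#'
#' @param hap1,hap2 Haplotype labels.
#' @inheritParams assign_diplotype
#' @return A tibble with `site`, `allele1`, `allele2` over all sites of
#'   the gene's definitions.
#' @export
genotype_calls <- function(hap1, hap2, gene, defs = or_haplotype_defs()) {
  sites <- hap_site_list(defs, gene)
  if (!all(c(hap1, hap2) %in% names(sites))) {
    abort(paste0("unknown haplotype label(s): ",
      paste(setdiff(c(hap1, hap2), names(sites)), collapse = ", ")),
      class = "orscreen_unknown_haplotype")
  }
  all_sites <- unique(unlist(sites))
  dosage <- (all_sites %in% sites[[hap1]]) + (all_sites %in% sites[[hap2]])
  tibble(
    site = all_sites,
    allele1 = if_else(dosage >= 1, "alt", "ref"),
    allele2 = if_else(dosage == 2, "alt", "ref")
  )
}

#' Is a diplotype a carrier of a variant?
#'
#' True iff either haplotype's variant sites include the named variant's
#' site; composite haplotypes containing the site count as carriers.
#'
#' @param diplotype Character vector of two haplotype labels, or a string
#'   `"hap1|hap2"`.
#' @param variant Single-variant label, e.g. `"L287P"`.
#' @inheritParams assign_diplotype
#' @return Logical scalar.
#' @export
#' @examples
#' is_carrier(c("ref", "L287P"), "L287P", gene = "OR10A6")
is_carrier <- function(diplotype, variant, gene, defs = or_haplotype_defs()) {
  if (length(diplotype) == 1L && grepl("|", diplotype, fixed = TRUE)) {
    diplotype <- strsplit(diplotype, "|", fixed = TRUE)[[1]]
  }
  stopifnot(length(diplotype) == 2L)
  vrow <- defs |>
    filter(.data$gene == !!gene, .data$haplotype_label == !!variant,
      nzchar(.data$variant_sites), !grepl(";", .data$variant_sites))
  if (nrow(vrow) != 1) {
    abort(paste0("unknown single-site variant label: ", variant),
      class = "orscreen_unknown_variant")
  }
  any(vapply(diplotype, \(lbl) is_carrier_label(lbl, vrow$variant_sites,
    defs, gene), logical(1)))
}

#' Simulate unphased genotype calls from population haplotype frequencies
#'
#' Draws two haplotypes per individual at the given frequencies and emits
#' the corresponding unphased per-site calls, for frequency-recovery
#' checks on [assign_diplotype()].
#'
#' @param n Number of individuals.
#' @inheritParams assign_diplotype
#' @param seed Integer seed.
#' @return A tibble `individual`, `site`, `allele1`, `allele2`, with the
#'   true haplotype draws as attribute `"truth"`.
#' @export
sim_genotypes <- function(n, gene, defs = or_haplotype_defs(),
                          freq_source = c("panel", "maf"), seed) {
  freq_source <- match.arg(freq_source)
  if (missing(seed)) abort_config("seed is mandatory")
  freqs <- hap_freq(defs, gene, freq_source)
  # only haplotypes observed in the chosen source are drawn
  observed <- freqs > 0.01 | names(freqs) == "ref"
  p <- freqs[observed] / sum(freqs[observed])
  withr::with_seed(as.integer(seed), {
    h1 <- sample(names(p), n, replace = TRUE, prob = p)
    h2 <- sample(names(p), n, replace = TRUE, prob = p)
  })
  sites <- hap_site_list(defs, gene)
  all_sites <- unique(unlist(sites))
  member <- vapply(sites, \(s) all_sites %in% s, logical(length(all_sites)))
  member <- matrix(member, nrow = length(all_sites),
    dimnames = list(all_sites, names(sites)))
  dosage <- member[, h1, drop = FALSE] + member[, h2, drop = FALSE] # sites x n
  calls <- tibble(
    individual = rep(seq_len(n), each = length(all_sites)),
    site = rep(all_sites, times = n),
    allele1 = if_else(as.vector(dosage) >= 1, "alt", "ref"),
    allele2 = if_else(as.vector(dosage) == 2, "alt", "ref")
  )
  structure(calls, truth = tibble(individual = seq_len(n), hap1 = h1, hap2 = h2))
}

#' Assign diplotypes for many individuals
#'
#' Vectorized wrapper over [assign_diplotype()] that deduplicates identical
#' dosage patterns, so large simulated cohorts are assigned cheaply.
#'
#' @param calls Tibble `individual`, `site`, `allele1`, `allele2`.
#' @inheritParams assign_diplotype
#' @return A tibble with one row per individual: `individual`, `gene`,
#'   `hap1`, `hap2`, `ambiguous`.
#' @export
assign_diplotypes <- function(calls, gene, defs = or_haplotype_defs(),
                              freq_source = c("panel", "maf")) {
  freq_source <- match.arg(freq_source)
  patterns <- calls |>
    mutate(dos = (.data$allele1 == "alt") + (.data$allele2 == "alt")) |>
    arrange(.data$site) |>
    group_by(.data$individual) |>
    summarise(pattern = paste(.data$dos, collapse = ""),
      .groups = "drop")
  uniq <- unique(patterns$pattern)
  assigned <- purrr::map_dfr(uniq, function(p) {
    ind <- patterns$individual[match(p, patterns$pattern)]
    one <- calls |> filter(.data$individual == ind)
    assign_diplotype(one, gene, defs, freq_source) |>
      mutate(pattern = p)
  })
  patterns |>
    left_join(assigned, by = "pattern") |>
    select("individual", "gene", "hap1", "hap2", "ambiguous")
}
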