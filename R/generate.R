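# Synthetic-data generators
#
# Every input the pipeline consumes can be simulated with the statistical
# structure the assays assume: 96-well luminescence plates (three basal and
# three post-stimulus reads per well, mock and OR1A1/carvone controls per
# plate), triplicate concentration-response plates, GC-MS peak-area tables
# with a decanal internal standard, and triangle-test panels conditioned on
# simulated OR10A6/OR2W1 diplotypes.

#' Ground-truth description of a receptor variant
#'
#' @param variant_id Variant label, e.g. `"OR10A6 L287P"`.
#' @param ec50_umolL EC50 in micromol/L (NA for nonresponders).
#' @param hillslope Hill coefficient (> 0).
#' @param amplitude Maximal response as a fraction of the positive-control
#'   amplitude (>= 0; 0 for nonresponders).
#' @param responder Logical; defaults to `!is.na(ec50_umolL)`.
#' @return A one-row tibble.
#' @export
#' @examples
#' receptor_truth("OR10A6 L287P", ec50_umolL = 28.21, amplitude = 1)
receptor_truth <- function(variant_id, ec50_umolL = NA_real_, hillslope = 1.2,
                           amplitude = 0, responder = !is.na(ec50_umolL)) {
  if (responder) {
    if (is.na(ec50_umolL) || ec50_umolL <= 0) {
      abort_config("a responder needs a positive ec50_umolL")
    }
    if (amplitude <= 0) abort_config("a responder needs a positive amplitude")
  }
  if (amplitude < 0) abort_config("amplitude must be >= 0")
  if (hillslope <= 0) abort_config("hillslope must be > 0")
  tibble(
    variant_id = variant_id, responder = responder,
    ec50_umolL = ec50_umolL, hillslope = hillslope, amplitude = amplitude
  )
}

#' Configuration for a synthetic library screen
#'
#' Defaults mirror the screening campaign design: 616 OR variants (391
#' wild-types plus 225 frequent haplotypes) in duplicate wells, one mock and
#' one OR1A1 + 30 micromol/L R-(-)-carvone positive-control well set per
#' 96-well plate, screened at 30 micromol/L Z4-11Al with OR10A6 L287P as the
#' single true responder.
#'
#' @param n_variants Number of receptor variants screened.
#' @param n_duplicates Wells per variant (and per control set) per plate.
#' @param basal_mean Mean basal luminescence (LU, > 0).
#' @param noise_cv Coefficient of variation of multiplicative read noise
#'   (>= 0).
#' @param plate_scale_sd SD of the per-plate multiplicative scale factor.
#' @param planted List of [receptor_truth()] rows planted in the library.
#' @param screen_conc_umolL Screening concentration (micromol/L, > 0).
#' @param odorant Screened odorant label.
#' @param positive_amplitude Positive-control signal amplitude (LU).
#' @param seed Integer seed (mandatory).
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_variants = 616, n_duplicates = 2,
                          basal_mean = 1000, noise_cv = 0.05,
                          plate_scale_sd = 0.10,
                          planted = list(receptor_truth("OR10A6 L287P",
                            ec50_umolL = 28.21, hillslope = 1.2, amplitude = 1
                          )),
                          screen_conc_umolL = 30, odorant = "Z4-11Al",
                          positive_amplitude = 5000, seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("seed is mandatory in a screen_config")
  }
  if (basal_mean <= 0) abort_config("basal_mean must be positive")
  if (screen_conc_umolL <= 0) abort_config("screen_conc_umolL must be positive")
  if (noise_cv < 0 || plate_scale_sd < 0) {
    abort_config("noise_cv and plate_scale_sd must be >= 0")
  }
  planted_tbl <- if (length(planted)) dplyr::bind_rows(planted) else
    receptor_truth("none")[0, ]
  if (anyDuplicated(planted_tbl$variant_id)) {
    abort_config("planted variant_ids must be unique")
  }
  if (n_variants < nrow(planted_tbl)) {
    abort_config("n_variants must be >= number of planted variants")
  }
  structure(
    list(
      n_variants = n_variants, n_duplicates = n_duplicates,
      basal_mean = basal_mean, noise_cv = noise_cv,
      plate_scale_sd = plate_scale_sd, planted = planted_tbl,
      screen_conc_umolL = screen_conc_umolL, odorant = odorant,
      positive_amplitude = positive_amplitude, seed = as.integer(seed)
    ),
    class = "screen_config"
  )
}

well_label <- function(idx) {
  paste0(LETTERS[(idx - 1L) %/% 12L + 1L], sprintf("%02d", (idx - 1L) %% 12L + 1L))
}

# three noisy reads around each mean; multiplicative Gaussian noise with a
# fixed CV so luminescence noise scales with signal
noisy_reads <- function(means, cv) {
  n <- length(means)
  reads <- matrix(rep(means, each = 3L), nrow = 3L) *
    pmax(1 + rnorm(3L * n, 0, cv), 0)
  t(reads)
}

#' Generate a synthetic library-screen plate set
#'
#' Lays out `n_variants` receptors across as many 96-well plates as needed
#' (duplicate wells on the same plate), adds a mock and an OR1A1
#' positive-control well set to every plate, and simulates three basal and
#' three post-stimulus luminescence reads per well. Planted responders have
#' their post-read mean elevated by
#' `amplitude * Hill(conc) * positive_amplitude`; mock wells and
#' non-responders have post mean equal to basal mean. All reads on a plate
#' share a multiplicative scale factor drawn with SD `plate_scale_sd`.
#'
#' @param cfg A [screen_config()].
#' @return A tibble of wells with columns `plate_id`, `well_id`,
#'   `variant_id`, `role`, `odorant`, `conc_umolL`, `basal_1..3`, `post_1..3`.
#' @export
#' @examples
#' wells <- gen_screen(screen_config(n_variants = 20, seed = 1))
gen_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  n_dup <- cfg$n_duplicates
  vpp <- (96L - 2L * n_dup) %/% n_dup # variants per plate
  n_plates <- ceiling(cfg$n_variants / vpp)

  n_fill <- cfg$n_variants - nrow(cfg$planted)
  variant_ids <- c(cfg$planted$variant_id, sprintf("OR_V%03d ref", seq_len(n_fill)))

  withr::with_seed(cfg$seed, {
    plate_scale <- pmax(rnorm(n_plates, 1, cfg$plate_scale_sd), 0.05)

    plan <- purrr::map_dfr(seq_len(n_plates), function(p) {
      vs <- variant_ids[seq((p - 1L) * vpp + 1L, min(p * vpp, cfg$n_variants))]
      ids <- c(rep("mock", n_dup), rep("OR1A1", n_dup), rep(vs, each = n_dup))
      roles <- c(rep("mock", n_dup), rep("positive", n_dup),
        rep("test", n_dup * length(vs)))
      tibble(
        plate_id = sprintf("P%02d", p),
        well_id = well_label(seq_along(ids)),
        variant_id = ids, role = roles,
        scale = plate_scale[p]
      )
    })

    # expected stimulus-induced signal per well, in LU
    plan <- plan |>
      left_join(cfg$planted, by = "variant_id") |>
      mutate(
        delta = dplyr::case_when(
          .data$role == "positive" ~ cfg$positive_amplitude,
          .data$role == "test" & !is.na(.data$responder) & .data$responder ~
            .data$amplitude * hill_fraction(
              cfg$screen_conc_umolL, .data$ec50_umolL, .data$hillslope
            ) * cfg$positive_amplitude,
          TRUE ~ 0
        ),
        odorant = if_else(.data$role == "positive", "R-(-)-carvone", cfg$odorant),
        conc_umolL = if_else(.data$role == "positive", 30, cfg$screen_conc_umolL)
      )

    basal <- noisy_reads(cfg$basal_mean * plan$scale, cfg$noise_cv)
    post <- noisy_reads((cfg$basal_mean + plan$delta) * plan$scale, cfg$noise_cv)
    colnames(basal) <- paste0("basal_", 1:3)
    colnames(post) <- paste0("post_", 1:3)

    dplyr::bind_cols(
      plan |> select("plate_id", "well_id", "variant_id", "role",
        "odorant", "conc_umolL"),
      as_tibble(basal), as_tibble(post)
    )
  })
}

#' Generate a synthetic concentration-response plate
#'
#' One plate carrying, for each tested concentration, `n_transfections` test
#' wells and as many matched mock wells, plus an OR1A1 positive-control well
#' set. Noise-free generation reproduces the Hill closed form exactly:
#' the mock-subtracted, positive-control-normalized response at `x` equals
#' `amplitude * (x/EC50)^h / (1 + (x/EC50)^h)`.
#'
#' @param truth A [receptor_truth()] row.
#' @param concentrations Strictly positive concentrations (micromol/L).
#' @param n_transfections Replicate transfections per concentration.
#' @param noise_cv Multiplicative read-noise CV.
#' @param seed Integer seed.
#' @param odorant Odorant label.
#' @param basal_mean,positive_amplitude Plate signal scale (LU).
#' @return A tibble of wells in the plate schema of [gen_screen()].
#' @export
#' @examples
#' tr <- receptor_truth("OR10A6 L287P", ec50_umolL = 28.21, amplitude = 1)
#' gen_dose_response(tr, c(1, 10, 100), noise_cv = 0, seed = 1)
gen_dose_response <- function(truth, concentrations, n_transfections = 3,
                              noise_cv = 0.05, seed, odorant = "Z4-11Al",
                              basal_mean = 1000, positive_amplitude = 5000) {
  if (length(concentrations) == 0) abort_config("empty concentration list")
  if (any(concentrations <= 0)) abort_config("concentrations must be > 0")
  if (missing(seed)) abort_config("seed is mandatory")
  stopifnot(is.data.frame(truth), nrow(truth) == 1L)
  concentrations <- sort(concentrations)

  resp <- if (truth$responder) {
    truth$amplitude * hill_fraction(concentrations, truth$ec50_umolL,
      truth$hillslope) * positive_amplitude
  } else {
    rep(0, length(concentrations))
  }

  plan <- dplyr::bind_rows(
    tibble(
      variant_id = truth$variant_id, role = "test", odorant = odorant,
      conc_umolL = rep(concentrations, each = n_transfections),
      delta = rep(resp, each = n_transfections)
    ),
    tibble(
      variant_id = "mock", role = "mock", odorant = odorant,
      conc_umolL = rep(concentrations, each = n_transfections),
      delta = 0
    ),
    tibble(
      variant_id = "OR1A1", role = "positive", odorant = "R-(-)-carvone",
      conc_umolL = rep(30, n_transfections),
      delta = positive_amplitude
    )
  )

  withr::with_seed(as.integer(seed), {
    basal <- noisy_reads(rep(basal_mean, nrow(plan)), noise_cv)
    post <- noisy_reads(basal_mean + plan$delta, noise_cv)
    colnames(basal) <- paste0("basal_", 1:3)
    colnames(post) <- paste0("post_", 1:3)
    dplyr::bind_cols(
      tibble(plate_id = "DR01", well_id = well_label(seq_len(nrow(plan)))),
      plan |> select(-"delta"),
      as_tibble(basal), as_tibble(post)
    )
  })
}

#' Configuration for a synthetic sensory panel
#'
#' Diplotypes at OR10A6 and OR2W1 are drawn independently from the
#' population haplotype frequencies in [or_haplotype_defs()]; carriers of a
#' functional OR10A6 haplotype answer a Z4-11Al triangle trial correctly
#' with the trial's `detect_prob`, everyone else with `chance_prob`.
#' Default trials present 0.1, 1 and 10 ng Z4-11Al with carrier detection
#' probabilities at chance, 0.9 and 1.0 respectively (a simple psychometric
#' stand-in; the source assay reports no psychometric function).
#'
#' @param n_panelists Number of panelists.
#' @param trials Tibble with columns `trial_id`, `odorant`, `amount_ng`,
#'   `detect_prob`.
#' @param chance_prob Guessing probability (1/3 for a triangle test).
#' @param defs Haplotype definition table ([or_haplotype_defs()] schema).
#' @param freq_source Which frequency column drives the draws: `"panel"`
#'   (haplotype frequencies, `freq_pct`) or `"maf"`.
#' @param force_carriers Optional integer: make exactly this many panelists
#'   functional-OR10A6 carriers (diplotype `L287P|ref`) and the rest
#'   non-carriers, instead of drawing OR10A6 diplotypes at random.
#' @param seed Integer seed (mandatory).
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_panelists = 29,
                         trials = tibble(
                           trial_id = c("T_0.1ng", "T_1ng", "T_10ng"),
                           odorant = "Z4-11Al",
                           amount_ng = c(0.1, 1, 10),
                           detect_prob = c(1 / 3, 0.9, 1.0)
                         ),
                         chance_prob = 1 / 3,
                         defs = or_haplotype_defs(),
                         freq_source = c("panel", "maf"),
                         force_carriers = NULL, seed) {
  if (missing(seed)) abort_config("seed is mandatory in a panel_config")
  if (nrow(trials) == 0) abort_config("trials must be non-empty")
  probs <- c(trials$detect_prob, chance_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_config("probabilities must lie in [0, 1]")
  }
  if (!is.null(force_carriers) && force_carriers > n_panelists) {
    abort_config("force_carriers cannot exceed n_panelists")
  }
  structure(
    list(
      n_panelists = n_panelists, trials = trials, chance_prob = chance_prob,
      defs = defs, freq_source = match.arg(freq_source),
      force_carriers = force_carriers, seed = as.integer(seed)
    ),
    class = "panel_config"
  )
}

draw_diplotypes <- function(n, defs, gene, freq_source) {
  d <- defs |> filter(.data$gene == !!gene)
  freq <- if (freq_source == "panel") d$freq_pct else d$maf_pct
  freq[is.na(freq)] <- 0
  if (sum(freq) <= 0) abort_config(paste0("no usable frequencies for ", gene))
  p <- freq / sum(freq)
  h1 <- sample(d$haplotype_label, n, replace = TRUE, prob = p)
  h2 <- sample(d$haplotype_label, n, replace = TRUE, prob = p)
  tibble(hap1 = pmin(h1, h2), hap2 = pmax(h1, h2))
}

#' Generate synthetic triangle-test panel responses
#'
#' @param cfg A [panel_config()].
#' @return A tibble with one row per panelist x trial: `panelist_id`,
#'   `or10a6_diplotype`, `or2w1_diplotype`, `trial_id`, `odorant`,
#'   `amount_ng`, `correct` (0/1).
#' @export
#' @examples
#' gen_panel(panel_config(n_panelists = 29, seed = 1))
gen_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  defs <- cfg$defs
  functional_haps <- defs$haplotype_label[defs$gene == "OR10A6" & defs$functional]

  withr::with_seed(cfg$seed, {
    if (is.null(cfg$force_carriers)) {
      g10 <- draw_diplotypes(cfg$n_panelists, defs, "OR10A6", cfg$freq_source)
    } else {
      k <- cfg$force_carriers
      g10 <- tibble(
        hap1 = c(rep("L287P", k), rep("ref", cfg$n_panelists - k)),
        hap2 = "ref"
      )
    }
    g2 <- draw_diplotypes(cfg$n_panelists, defs, "OR2W1", cfg$freq_source)

    panelists <- tibble(
      panelist_id = sprintf("PN%03d", seq_len(cfg$n_panelists)),
      or10a6_diplotype = paste(g10$hap1, g10$hap2, sep = "|"),
      or2w1_diplotype = paste(g2$hap1, g2$hap2, sep = "|"),
      carrier = g10$hap1 %in% functional_haps | g10$hap2 %in% functional_haps
    )

    out <- tidyr::crossing(panelists, cfg$trials) |>
      mutate(
        p_correct = if_else(.data$carrier, .data$detect_prob, cfg$chance_prob),
        correct = rbinom(dplyr::n(), 1L, .data$p_correct)
      ) |>
      select("panelist_id", "or10a6_diplotype", "or2w1_diplotype",
        "trial_id", "odorant", "amount_ng", "correct") |>
      arrange(.data$trial_id, .data$panelist_id)
    out
  })
}

#' Headspace-collection preset
#'
#' Parameterizes per-batch aldehyde emission for a fly strain. The
#' Zimbabwe preset draws the per-batch Z4-9Al/Z4-11Al ratio from a
#' lognormal whose arithmetic mean and SD match the reported 2.6 +/- 0.7
#' fold-ratio; the cosmopolitan preset emits no Z4-9Al at all.
#'
#' @param strain `"zimbabwe"` or `"cosmopolitan"`.
#' @param ratio_mean,ratio_sd Arithmetic mean and SD of the Z4-9Al/Z4-11Al
#'   fold-ratio (ignored for the cosmopolitan strain, where the ratio is 0).
#' @param mean_11al_ng Mean collected Z4-11Al per batch of 60 females over
#'   24 h (ng).
#' @param log_sd_11al Log-scale SD of per-batch Z4-11Al amount.
#' @param n_batches Number of collection batches.
#' @param is_ng Internal-standard amount (ng decanal; fixed at 100 in the
#'   protocol).
#' @param seed Integer seed (mandatory).
#' @return A `headspace_preset` list carrying derived lognormal parameters
#'   `log_mean_ratio` and `log_sd_ratio`.
#' @export
headspace_preset <- function(strain = c("zimbabwe", "cosmopolitan"),
                             ratio_mean = 2.6, ratio_sd = 0.7,
                             mean_11al_ng = 50, log_sd_11al = 0.3,
                             n_batches = 10, is_ng = 100, seed) {
  strain <- match.arg(strain)
  if (missing(seed)) abort_config("seed is mandatory in a headspace_preset")
  if (ratio_sd < 0) abort_config("ratio_sd must be >= 0")
  if (n_batches < 1) abort_config("n_batches must be >= 1")
  if (mean_11al_ng <= 0 || is_ng <= 0) {
    abort_config("amounts must be positive")
  }
  # moment-matched lognormal: E = ratio_mean, SD = ratio_sd
  if (strain == "zimbabwe") {
    s2 <- log(1 + (ratio_sd / ratio_mean)^2)
    log_mean_ratio <- log(ratio_mean) - s2 / 2
    log_sd_ratio <- sqrt(s2)
  } else {
    log_mean_ratio <- -Inf # no Z4-9Al in cosmopolitan effluvia
    log_sd_ratio <- 0
  }
  structure(
    list(
      strain = strain, ratio_mean = ratio_mean, ratio_sd = ratio_sd,
      log_mean_ratio = log_mean_ratio, log_sd_ratio = log_sd_ratio,
      mean_11al_ng = mean_11al_ng, log_sd_11al = log_sd_11al,
      n_batches = n_batches, is_ng = is_ng, seed = as.integer(seed)
    ),
    class = "headspace_preset"
  )
}

#' Generate synthetic GC-MS headspace peak-area tables
#'
#' Per collection batch, simulates peak areas for Z4-9Al, Z4-11Al and the
#' 100 ng decanal internal standard under a unit response factor, so that
#' internal-standard quantification recovers the generating amounts exactly
#' up to sampling noise.
#'
#' @param preset A [headspace_preset()].
#' @return A tibble with columns `sample_id`, `strain`, `area_z4_9al`,
#'   `area_z4_11al`, `area_is`, `is_ng`.
#' @export
#' @examples
#' gen_headspace(headspace_preset("zimbabwe", seed = 1))
gen_headspace <- function(preset) {
  stopifnot(inherits(preset, "headspace_preset"))
  n <- preset$n_batches
  withr::with_seed(preset$seed, {
    mu11 <- log(preset$mean_11al_ng) - preset$log_sd_11al^2 / 2
    ng_11al <- rlnorm(n, mu11, preset$log_sd_11al)
    ratio <- if (is.finite(preset$log_mean_ratio)) {
      rlnorm(n, preset$log_mean_ratio, preset$log_sd_ratio)
    } else {
      rep(0, n)
    }
    area_is <- 1e6 * rlnorm(n, 0, 0.1) # instrument-level area scale
    tibble(
      sample_id = sprintf("%s_%02d", toupper(substr(preset$strain, 1, 3)), 1:n),
      strain = preset$strain,
      area_z4_9al = area_is * ratio * ng_11al / preset$is_ng,
      area_z4_11al = area_is * ng_11al / preset$is_ng,
      area_is = area_is,
      is_ng = preset$is_ng
    )
  })
}
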