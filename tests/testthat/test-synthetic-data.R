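test_that("noise-free null screens have post mean equal to basal mean exactly", {
  cfg <- screen_config(
    n_variants = 12, planted = list(), noise_cv = 0,
    plate_scale_sd = 0, seed = 1
  )
  w <- gen_screen(cfg)
  non_pos <- dplyr::filter(w, role != "positive")
  expect_equal(
    (non_pos$post_1 + non_pos$post_2 + non_pos$post_3) / 3,
    (non_pos$basal_1 + non_pos$basal_2 + non_pos$basal_3) / 3
  )
  # positive-control wells carry exactly the positive amplitude
  pos <- dplyr::filter(w, role == "positive")
  expect_equal(pos$post_1 - pos$basal_1, rep(cfg$positive_amplitude, nrow(pos)))
})

test_that("generators are byte-identical under a fixed seed and schema-stable", {
  cfg <- screen_config(n_variants = 40, seed = 123)
  expect_identical(gen_screen(cfg), gen_screen(cfg))
  expect_false(identical(
    gen_screen(cfg),
    gen_screen(screen_config(n_variants = 40, seed = 124))
  ))

  hs <- headspace_preset("zimbabwe", seed = 5)
  expect_identical(gen_headspace(hs), gen_headspace(hs))

  pc <- panel_config(n_panelists = 10, seed = 9)
  expect_identical(gen_panel(pc), gen_panel(pc))

  # generated tables satisfy the reader schemas
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(gen_screen(cfg), f)
  expect_s3_class(read_plate_csv(f), "tbl_df")
})

test_that("screen layout carries mock, positive and duplicate test wells per plate", {
  cfg <- screen_config(n_variants = 50, n_duplicates = 2, seed = 2)
  w <- gen_screen(cfg)
  counts <- w |>
    dplyr::count(plate_id, role) |>
    tidyr::pivot_wider(names_from = role, values_from = n)
  expect_true(all(counts$mock == 2))
  expect_true(all(counts$positive == 2))
  per_variant <- w |>
    dplyr::filter(role == "test") |>
    dplyr::count(variant_id)
  expect_true(all(per_variant$n == 2))
  expect_equal(nrow(per_variant), 50)
})

test_that("invalid screen configurations are rejected", {
  expect_error(screen_config(basal_mean = -1, seed = 1),
    class = "orscreen_invalid_config")
  expect_error(screen_config(screen_conc_umolL = 0, seed = 1),
    class = "orscreen_invalid_config")
  expect_error(screen_config(seed = 1, n_variants = 0),
    class = "orscreen_invalid_config")
  expect_error(
    screen_config(planted = list(
      receptor_truth("A", ec50_umolL = 10, amplitude = 1),
      receptor_truth("A", ec50_umolL = 20, amplitude = 1)
    ), seed = 1),
    class = "orscreen_invalid_config"
  )
  expect_error(screen_config(), class = "orscreen_invalid_config")
  expect_error(receptor_truth("X", responder = TRUE),
    class = "orscreen_invalid_config")
  expect_error(receptor_truth("X", ec50_umolL = -4, amplitude = 1),
    class = "orscreen_invalid_config")
})

test_that("noise-free dose-response wells follow the Hill closed form", {
  # EC50 10, slope 1 at {1, 10, 100} gives fractions {1/11, 1/2, 10/11}
  tr <- receptor_truth("X", ec50_umolL = 10, hillslope = 1, amplitude = 0.8)
  w <- gen_dose_response(tr, c(1, 10, 100), noise_cv = 0, seed = 1)
  cv <- build_curve(w)
  resp <- cv |>
    dplyr::distinct(conc_umolL, response) |>
    dplyr::arrange(conc_umolL)
  expect_equal(resp$response, 0.8 * c(1 / 11, 1 / 2, 10 / 11))

  # Hill midpoint identity at the published OR10A6 L287P / Z4-11Al EC50
  t1 <- receptor_truth("OR10A6 L287P", ec50_umolL = 28.21, hillslope = 1.2,
    amplitude = 1)
  wm <- gen_dose_response(t1, c(1, 3, 28.21, 300, 1000), noise_cv = 0, seed = 1)
  cvm <- build_curve(wm)
  mid <- cvm$response[cvm$conc_umolL == 28.21 & cvm$replicate == 1]
  expect_equal(mid, 0.5)

  # non-responders give zero mock-subtracted response everywhere
  nr <- receptor_truth("OR10A6 ref")
  wn <- gen_dose_response(nr, c(1, 10, 100, 1000), noise_cv = 0, seed = 1)
  expect_equal(unique(build_curve(wn)$response), 0)

  expect_error(gen_dose_response(tr, numeric(0), seed = 1),
    class = "orscreen_invalid_config")
  expect_error(gen_dose_response(tr, c(0, 10), seed = 1),
    class = "orscreen_invalid_config")
})

test_that("panel generation ties correctness to functional-carrier status", {
  trials10 <- tibble::tibble(
    trial_id = "T1", odorant = "Z4-11Al", amount_ng = 10, detect_prob = 1
  )
  defs <- or_haplotype_defs()

  # perfect detection: forced carriers always correct, rest at chance
  cfg <- panel_config(
    n_panelists = 29, trials = trials10, force_carriers = 14,
    defs = defs, seed = 11
  )
  pan <- gen_panel(cfg)
  carriers <- pan$panelist_id[pan$or10a6_diplotype == "L287P|ref"]
  expect_length(carriers, 14)
  expect_true(all(pan$correct[pan$panelist_id %in% carriers] == 1))

  # everyone a carrier with detect_prob 1: all answers correct
  all_c <- gen_panel(panel_config(
    n_panelists = 12, trials = trials10, force_carriers = 12,
    defs = defs, seed = 3
  ))
  expect_true(all(all_c$correct == 1))

  # detect_prob equal to chance: genotype does not matter; fraction correct
  # stays within 3 binomial SEs of 1/3
  chance_trials <- tibble::tibble(
    trial_id = "T1", odorant = "Z4-11Al", amount_ng = 0.1, detect_prob = 1 / 3
  )
  big <- gen_panel(panel_config(
    n_panelists = 900, trials = chance_trials, defs = defs, seed = 4
  ))
  p_hat <- mean(big$correct)
  se <- sqrt((1 / 3) * (2 / 3) / 900)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)

  expect_error(
    panel_config(trials = dplyr::mutate(trials10, detect_prob = 1.2), seed = 1),
    class = "orscreen_invalid_config"
  )
})

test_that("headspace presets hit their closed forms and strain constraints", {
  # zero ratio spread: every batch carries exactly the preset fold ratio
  exact <- gen_headspace(headspace_preset("zimbabwe", ratio_sd = 0, seed = 8))
  expect_equal(exact$area_z4_9al / exact$area_z4_11al, rep(2.6, 10))

  # cosmopolitan effluvia contain no Z4-9Al
  cos <- gen_headspace(headspace_preset("cosmopolitan", seed = 8))
  expect_equal(cos$area_z4_9al, rep(0, 10))
  expect_true(all(cos$area_z4_11al > 0))
  expect_equal(cos$is_ng, rep(100, 10))

  expect_error(headspace_preset("zimbabwe", ratio_sd = -0.1, seed = 1),
    class = "orscreen_invalid_config")
  expect_error(headspace_preset("zimbabwe", n_batches = 0, seed = 1),
    class = "orscreen_invalid_config")
})
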