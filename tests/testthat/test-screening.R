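test_that("well summarization is mean(post) - mean(basal)", {
  w <- tibble::tibble(
    plate_id = "P01", well_id = c("A01", "A02", "A03"),
    variant_id = c("V1", "V2", "V3"), role = "test",
    odorant = "Z4-11Al", conc_umolL = 30,
    basal_1 = c(100, 100, 0), basal_2 = c(100, 110, 0), basal_3 = c(100, 90, 0),
    post_1 = c(100, 400, 3), post_2 = c(100, 410, 3), post_3 = c(100, 390, 3)
  )
  s <- summarize_wells(w)
  expect_equal(s$signal, c(0, 300, 3))

  expect_error(summarize_wells(dplyr::select(w, -post_3)),
    class = "orscreen_malformed_record")
  w$basal_2[1] <- NA
  expect_error(summarize_wells(w), class = "orscreen_malformed_record")
})

test_that("normalization divides by the plate positive control, then averages duplicates", {
  # variant at 150 against a 300 reference, measured twice -> 0.5
  plate <- make_plate(c(V1 = 150, V1 = 150, V2 = 120, V2 = 180))
  norm <- normalize_screen(plate)
  v <- dplyr::filter(norm, variant_id == "V1")
  expect_equal(v$normalized_rlu, 0.5)
  # duplicates averaged after normalization: (0.4 + 0.6) / 2
  expect_equal(dplyr::filter(norm, variant_id == "V2")$normalized_rlu, 0.5)
  # the reference well normalizes to 1 against itself
  expect_equal(dplyr::filter(norm, role == "positive")$normalized_rlu, 1)
  # mock reported alongside
  expect_true("mock" %in% norm$role)

  # degenerate reference names the plate
  bad <- make_plate(c(V1 = 10), pos_signal = 0)
  err <- expect_error(normalize_screen(bad),
    class = "orscreen_degenerate_reference")
  expect_match(conditionMessage(err), "P01")
})

test_that("2-sigma hit calling follows the declared mean + 2 SD identity", {
  # all equal: SD 0, threshold = value, strict exceedance -> no hits
  eq <- tibble::tibble(variant_id = letters[1:5], normalized_rlu = 0.3)
  res <- call_hits(eq)
  expect_equal(res$threshold, 0.3)
  expect_length(res$hits, 0)

  # {0,0,0,0,10}: no hit under either SD convention
  v <- tibble::tibble(variant_id = letters[1:5],
    normalized_rlu = c(0, 0, 0, 0, 10))
  pop <- call_hits(v, sd_convention = "population")
  expect_equal(pop$threshold, 10)
  expect_length(pop$hits, 0)
  smp <- call_hits(v, sd_convention = "sample")
  expect_equal(smp$threshold, 2 + 2 * sd(c(0, 0, 0, 0, 10)))
  expect_length(smp$hits, 0)
  # threshold identity holds in both cases
  expect_equal(smp$threshold, smp$screen_mean + 2 * smp$screen_sd)

  expect_error(call_hits(v[1, ]), class = "orscreen_insufficient_data")
})

test_that("false-positive classification needs full validation coverage", {
  v <- tibble::tibble(
    variant_id = sprintf("V%03d", 1:616),
    normalized_rlu = c(rep(1, 12), rep(0, 604))
  )
  res <- call_hits(v)
  expect_setequal(res$hits, sprintf("V%03d", 1:12))

  expect_error(classify_false_positives(res, c(V001 = TRUE)),
    class = "orscreen_incomplete_validation")

  # 12 unvalidated hits of 616 variants: fraction just under 2%
  none_ok <- setNames(rep(FALSE, 12), sprintf("V%03d", 1:12))
  fp <- classify_false_positives(res, none_ok)
  expect_equal(fp$fp_fraction, 12 / 616, tolerance = 1e-12)
  expect_lt(fp$fp_fraction, 0.02)

  all_ok <- setNames(rep(TRUE, 12), sprintf("V%03d", 1:12))
  expect_length(classify_false_positives(res, all_ok)$false_positives, 0)

  # no hits: empty set, fraction 0
  null_res <- call_hits(tibble::tibble(variant_id = c("a", "b"),
    normalized_rlu = c(0.1, 0.1)))
  expect_equal(classify_false_positives(null_res, c())$fp_fraction, 0)
})

test_that("screen analysis is invariant to per-plate rescaling of raw reads", {
  w <- gen_screen(screen_config(n_variants = 30, seed = 21))
  res <- run_screen(w)

  scaled <- w |>
    dplyr::mutate(dplyr::across(
      dplyr::matches("^(basal|post)_[123]$"),
      ~ dplyr::if_else(plate_id == "P01", .x * 3.7, .x)
    ))
  res2 <- run_screen(scaled)

  expect_equal(tidy(res2)$normalized_rlu, tidy(res)$normalized_rlu)
  expect_equal(res2$threshold, res$threshold)
  expect_identical(res2$hits, res$hits)
})

test_that("raising one variant's post reads never removes it from the hit set", {
  base <- gen_screen(screen_config(n_variants = 20, seed = 31))
  target <- "OR_V005 ref"
  was_hit <- FALSE
  for (bump in c(0, 500, 2000, 8000, 30000)) {
    w <- base |>
      dplyr::mutate(dplyr::across(
        dplyr::matches("^post_[123]$"),
        ~ dplyr::if_else(variant_id == target, .x + bump, .x)
      ))
    hit_now <- target %in% run_screen(w)$hits
    if (was_hit) expect_true(hit_now)
    was_hit <- hit_now
  }
  expect_true(was_hit) # the largest bump must be called
})

test_that("hit set matches a single-pass brute-force recomputation on small screens", {
  for (seed in 1:5) {
    w <- gen_screen(screen_config(n_variants = 10, seed = seed))
    res <- call_hits(normalize_screen(w), stat_level = "variants")

    # independent single pass over raw reads, base R only
    delta <- rowMeans(w[, c("post_1", "post_2", "post_3")]) -
      rowMeans(w[, c("basal_1", "basal_2", "basal_3")])
    ref <- tapply(delta[w$role == "positive"], w$plate_id[w$role == "positive"], mean)
    norm <- delta / ref[w$plate_id]
    test_rows <- w$role == "test"
    per_var <- tapply(norm[test_rows], w$variant_id[test_rows], mean)
    thr <- mean(per_var) + 2 * sd(per_var)
    brute_hits <- names(per_var)[per_var > thr]

    expect_setequal(res$hits, brute_hits)
    expect_equal(res$threshold, unname(thr))
  }
})

test_that("null screens stay under the 2% false-positive bound", {
  fracs <- vapply(1:30, function(s) {
    r <- run_screen(gen_screen(screen_config(planted = list(), seed = 5000 + s)))
    length(r$hits) / r$n_variants
  }, numeric(1))
  expect_lt(mean(fracs), 0.02)
})
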