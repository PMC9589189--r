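test_that("curve building mock-subtracts and normalizes as declared", {
  tr <- receptor_truth("X", ec50_umolL = 10, hillslope = 1, amplitude = 0.8)
  w <- gen_dose_response(tr, c(1, 3, 10, 30, 100), noise_cv = 0, seed = 1)

  # positive-control mode: responses are fractions of the OR1A1 amplitude
  cv <- build_curve(w, normalize_mode = "positive_control")
  expect_equal(max(cv$response), 0.8 * hill_function(100, 0, 1, 10, 1))

  # max mode: the largest response is exactly 1
  cvm <- build_curve(w, normalize_mode = "max")
  expect_equal(max(cvm$response), 1)

  # mock wells processed against their own mean leave zero residual spread
  expect_equal(attr(cv, "mock_sd"), 0)

  # missing mock pairing is an error
  no_mock <- dplyr::filter(w, role != "mock" | conc_umolL != 10)
  expect_error(build_curve(no_mock), class = "orscreen_unmatched_mock")
})

test_that("the Hill fit recovers exact model data and published parameter sets", {
  tr <- receptor_truth("X", ec50_umolL = 10, hillslope = 1, amplitude = 1)
  w <- gen_dose_response(tr, c(0.1, 1, 10, 100, 1000), noise_cv = 0, seed = 1)
  f <- fit_hill(build_curve(w), 1)
  expect_true(f$converged)
  expect_equal(f$ec50_umolL, 10, tolerance = 1e-4)
  expect_equal(f$hillslope, 1, tolerance = 1e-4)

  # published OR10A6 L287P / Z4-9Al EC50 refits from noise-free curves
  t9 <- receptor_truth("OR10A6 L287P", ec50_umolL = 41.15, hillslope = 1.2,
    amplitude = 0.9)
  w9 <- gen_dose_response(t9, dr_concs, noise_cv = 0, seed = 1, odorant = "Z4-9Al")
  f9 <- fit_hill(build_curve(w9), 1)
  expect_equal(f9$ec50_umolL, 41.15, tolerance = 1e-3)

  # the fitted function passes through (min + max) / 2 at the EC50
  expect_equal(
    hill_function(f9$ec50_umolL, f9$min, f9$max, f9$ec50_umolL, f9$hillslope),
    (f9$min + f9$max) / 2
  )

  expect_error(
    fit_hill(tibble::tibble(conc_umolL = c(1, 10, 100), response = c(0, 0.5, 1))),
    class = "orscreen_underdetermined_fit"
  )
})

test_that("the fit agrees with a grid-search oracle on a small curve", {
  conc <- c(1, 5, 20, 80, 300)
  resp <- hill_function(conc, 0.05, 0.95, 25, 1.3) +
    c(0.02, -0.01, 0.015, -0.02, 0.01)
  toy <- tibble::tibble(conc_umolL = conc, response = resp)

  # oracle: grid over (log10 EC50, slope) with analytic (min, max) per node
  log_grid <- seq(0, 3, by = 0.02)
  slope_grid <- seq(0.5, 3, by = 0.05)
  best <- list(sse = Inf)
  for (lg in log_grid) {
    for (sl in slope_grid) {
      g <- 1 / (1 + (conc / 10^lg)^sl) # weight on `min`
      # least squares for resp ~ min * g + max * (1 - g)
      X <- cbind(g, 1 - g)
      coefs <- solve(crossprod(X), crossprod(X, resp))
      sse <- sum((resp - X %*% coefs)^2)
      if (sse < best$sse) best <- list(sse = sse, lg = lg, sl = sl)
    }
  }

  f <- fit_hill(toy)
  expect_true(f$converged)
  expect_lt(abs(log10(f$ec50_umolL) - best$lg), 0.02 + 1e-9)
  expect_lt(abs(f$hillslope - best$sl), 0.05 + 1e-9)
  expect_lte(f$residual_ss, best$sse + 1e-12)
})

test_that("EC50 and slope are invariant to uniform response rescaling, and monotone data fit monotone", {
  conc <- c(1, 5, 20, 80, 300)
  resp <- hill_function(conc, 0, 1, 25, 1.3) + c(0.02, -0.01, 0.015, -0.02, 0.01)
  f1 <- fit_hill(tibble::tibble(conc_umolL = conc, response = resp))
  f2 <- fit_hill(tibble::tibble(conc_umolL = conc, response = 2 * resp))
  expect_equal(f2$ec50_umolL, f1$ec50_umolL, tolerance = 1e-6)
  expect_equal(f2$hillslope, f1$hillslope, tolerance = 1e-6)
  expect_equal(c(f2$min, f2$max), 2 * c(f1$min, f1$max), tolerance = 1e-6)

  expect_gt(f1$max - f1$min, 0) # increasing data, increasing fitted sigmoid
})

test_that("EC50 summaries give mean +/- sample SD or an ND call", {
  fits <- tibble::tibble(
    ec50_umolL = c(40, 40, 40), min = 0, max = 1, converged = TRUE
  )
  s <- summarize_ec50(fits, 1000)
  expect_equal(c(s$mean_ec50, s$sd_ec50), c(40, 0))
  expect_equal(s$status, "responder")

  s2 <- summarize_ec50(
    dplyr::mutate(fits, ec50_umolL = c(28, 26, 30)), 1000
  )
  expect_equal(c(s2$mean_ec50, s2$sd_ec50), c(28, 2))

  # flat curves up to 1000 umol/L: ND
  nr <- receptor_truth("OR10A6 ref")
  wn <- gen_dose_response(nr, dr_concs, noise_cv = 0.05, seed = 7)
  cvn <- build_curve(wn)
  sn <- summarize_ec50(fit_hill_all(cvn), max(dr_concs), attr(cvn, "mock_sd"))
  expect_equal(sn$status, "nonresponder")
  expect_true(is.na(sn$mean_ec50) && is.na(sn$sd_ec50))

  # EC50 beyond the tested range votes ND
  s3 <- summarize_ec50(
    dplyr::mutate(fits, ec50_umolL = c(2000, 3000, 2500)), 1000
  )
  expect_equal(s3$status, "nonresponder")
})

test_that("with assay-level noise the mean recovered EC50 stays within 15%", {
  tr <- receptor_truth("OR10A6 L287P", ec50_umolL = 28.21, hillslope = 1.2,
    amplitude = 1)
  means <- vapply(1:25, function(s) {
    w <- gen_dose_response(tr, dr_concs, noise_cv = 0.05, seed = s)
    mean(fit_hill_all(build_curve(w))$ec50_umolL)
  }, numeric(1))
  expect_lt(abs(mean(means) - 28.21) / 28.21, 0.15)
})

test_that("paired amplitude comparison matches the textbook paired t", {
  expect_equal(compare_amplitudes(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compare_amplitudes(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  a <- c(1, 2, 3); b <- c(2, 4, 6)
  res <- compare_amplitudes(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand)
  # antisymmetry: swapping the pair order flips the sign
  expect_equal(compare_amplitudes(b, a)$t, -res$t)

  expect_error(compare_amplitudes(1, c(1, 2)), class = "orscreen_invalid_data")
  expect_error(compare_amplitudes(1, 2), class = "orscreen_insufficient_data")
})
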