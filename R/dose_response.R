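# Concentration-response analysis: delta-signal, per-concentration mock
# subtraction, normalization, four-parameter Hill fitting, EC50
# summarization and nonresponder calling.

#' Four-parameter Hill function
#'
#' `f(x) = (min - max) / (1 + (x / ec50)^hillslope) + max`. With `min = 0`
#' and positive `hillslope` this is an increasing sigmoid with
#' `f(ec50) = (min + max) / 2`.
#'
#' @param x Concentration(s), same units as `ec50`.
#' @param min,max Lower and upper asymptote.
#' @param ec50 Half-maximal concentration (> 0).
#' @param hillslope Hill coefficient.
#' @return Response value(s).
#' @export
#' @examples
#' hill_function(10, 0, 1, 10, 1) # exactly 0.5
hill_function <- function(x, min, max, ec50, hillslope) {
  (min - max) / (1 + (x / ec50)^hillslope) + max
}

# fraction of maximal response, i.e. hill_function with min = 0, max = 1
hill_fraction <- function(x, ec50, hillslope) {
  hill_function(x, 0, 1, ec50, hillslope)
}

#' Build a concentration-response curve from plate wells
#'
#' For each well the basal average is subtracted from the post-stimulus
#' average (delta signal); the matched mock delta of the same
#' odorant/concentration is subtracted from each test delta; the
#' mock-subtracted values are then normalized either to the plate
#' positive-control delta (`"positive_control"`) or to the maximum
#' mock-subtracted value of the curve (`"max"`, which makes the largest
#' response exactly 1).
#'
#' @param wells Plate tibble ([gen_screen()] schema) holding test, mock and
#'   (for `positive_control` mode) positive wells.
#' @param normalize_mode `"positive_control"` or `"max"`.
#' @return A `dose_response_curve`: tibble with `variant_id`, `odorant`,
#'   `conc_umolL`, `replicate`, `response`, carrying attributes
#'   `mock_sd` (SD of mock-subtracted, normalized mock responses, used by
#'   the nonresponder criterion) and `normalize_mode`.
#' @export
#' @examples
#' tr <- receptor_truth("OR10A6 L287P", ec50_umolL = 28.21, amplitude = 1)
#' wells <- gen_dose_response(tr, c(1, 3, 10, 30, 100), noise_cv = 0, seed = 1)
#' build_curve(wells)
build_curve <- function(wells, normalize_mode = c("positive_control", "max")) {
  normalize_mode <- match.arg(normalize_mode)
  ws <- summarize_wells(wells)

  mocks <- ws |>
    filter(.data$role == "mock") |>
    group_by(.data$odorant, .data$conc_umolL) |>
    mutate(mock_mean = mean(.data$signal)) |>
    ungroup()
  mock_ref <- mocks |>
    distinct(.data$odorant, .data$conc_umolL, .data$mock_mean)

  test <- ws |> filter(.data$role == "test")
  unmatched <- test |>
    dplyr::anti_join(mock_ref, by = c("odorant", "conc_umolL"))
  if (nrow(unmatched) > 0) {
    abort(paste0("no matched mock well for: ", paste(
      unique(sprintf("%s @ %g umol/L", unmatched$odorant, unmatched$conc_umolL)),
      collapse = "; ")), class = "orscreen_unmatched_mock")
  }

  test <- test |>
    left_join(mock_ref, by = c("odorant", "conc_umolL")) |>
    mutate(raw_response = .data$signal - .data$mock_mean) |>
    group_by(.data$variant_id, .data$odorant, .data$conc_umolL) |>
    arrange(.data$well_id, .by_group = TRUE) |>
    mutate(replicate = row_number()) |>
    ungroup()

  mock_resid <- mocks$signal - mocks$mock_mean

  if (normalize_mode == "positive_control") {
    pos <- ws |> filter(.data$role == "positive")
    if (nrow(pos) == 0) {
      abort("no positive-control well for positive_control normalization",
        class = "orscreen_degenerate_reference")
    }
    ref <- mean(pos$signal)
    if (ref <= 0) {
      abort("non-positive positive-control signal",
        class = "orscreen_degenerate_reference")
    }
  } else {
    ref <- max(test$raw_response)
    if (ref <= 0) {
      abort("maximum mock-subtracted response is not positive",
        class = "orscreen_degenerate_normalization")
    }
  }

  out <- test |>
    mutate(response = .data$raw_response / ref) |>
    select("variant_id", "odorant", "conc_umolL", "replicate", "response") |>
    arrange(.data$replicate, .data$conc_umolL)

  structure(out,
    mock_sd = sd_by_convention(mock_resid / ref, "sample"),
    normalize_mode = normalize_mode,
    class = c("dose_response_curve", class(out))
  )
}

#' Fit the four-parameter Hill function to one replicate of a curve
#'
#' Least-squares fit of `(min, max, EC50, Hillslope)` by bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]), with EC50 optimized in
#' log10 space. Initialization: `min` and `max` at the smallest and largest
#' response, EC50 at the geometric mean of the tested concentrations,
#' Hillslope 1. Bounds: EC50 in `[min(conc)/100, max(conc) * 100]`,
#' Hillslope in `[0.1, 10]`. A fit is flagged non-converged if the
#' optimizer fails or the EC50 lands on a bound. Zero concentrations are
#' excluded from the log-space fit.
#'
#' @param curve A `dose_response_curve` from [build_curve()] (or any tibble
#'   with `conc_umolL` and `response`).
#' @param replicate Replicate index to fit (default 1; ignored when the
#'   curve has no `replicate` column).
#' @return A `hill_fit` object with elements `min`, `max`, `ec50_umolL`,
#'   `hillslope`, `converged`, `residual_ss`, `n`, `data`.
#' @export
#' @examples
#' tr <- receptor_truth("X", ec50_umolL = 10, hillslope = 1, amplitude = 1)
#' w <- gen_dose_response(tr, c(1, 3, 10, 30, 100), noise_cv = 0, seed = 1)
#' fit <- fit_hill(build_curve(w), replicate = 1)
#' tidy(fit)
fit_hill <- function(curve, replicate = 1L) {
  dat <- as_tibble(curve)
  if ("replicate" %in% names(dat)) {
    dat <- dat |> filter(.data$replicate == !!replicate)
  }
  dat <- dat |> filter(.data$conc_umolL > 0)
  conc <- dat$conc_umolL
  resp <- dat$response
  if (length(unique(conc)) < 4) {
    abort("need >= 4 distinct positive concentrations for a 4-parameter fit",
      class = "orscreen_underdetermined_fit")
  }

  lower <- c(min = -Inf, max = -Inf,
    logec50 = log10(min(conc) / 100), slope = 0.1)
  upper <- c(min = Inf, max = Inf,
    logec50 = log10(max(conc) * 100), slope = 10)
  par0 <- c(
    min = min(resp), max = max(resp),
    logec50 = mean(log10(conc)), slope = 1
  )

  residual_fn <- function(p) {
    resp - hill_function(conc, p[["min"]], p[["max"]], 10^p[["logec50"]],
      p[["slope"]])
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = residual_fn,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-12, ptol = 1e-12, maxiter = 500
      )
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    p <- par0
    converged <- FALSE
    rss <- sum(residual_fn(par0)^2)
  } else {
    p <- fit$par
    rss <- sum(fit$fvec^2)
    at_bound <- p[["logec50"]] <= lower[["logec50"]] + 1e-8 ||
      p[["logec50"]] >= upper[["logec50"]] - 1e-8
    converged <- fit$info %in% 1:4 && !at_bound
  }

  structure(
    list(
      variant_id = if ("variant_id" %in% names(dat)) dat$variant_id[1] else NA_character_,
      odorant = if ("odorant" %in% names(dat)) dat$odorant[1] else NA_character_,
      replicate = replicate,
      min = unname(p[["min"]]), max = unname(p[["max"]]),
      ec50_umolL = unname(10^p[["logec50"]]),
      hillslope = unname(p[["slope"]]),
      converged = converged, residual_ss = rss, n = length(resp),
      data = dat
    ),
    class = "hill_fit"
  )
}

#' Fit all replicates of a concentration-response curve
#'
#' @param curve A `dose_response_curve`.
#' @return A tibble with one row per replicate: `variant_id`, `odorant`,
#'   `replicate`, `min`, `max`, `ec50_umolL`, `hillslope`, `converged`,
#'   `residual_ss`.
#' @export
fit_hill_all <- function(curve) {
  reps <- sort(unique(curve$replicate))
  purrr::map_dfr(reps, function(r) {
    f <- fit_hill(curve, replicate = r)
    tibble(
      variant_id = f$variant_id, odorant = f$odorant, replicate = r,
      min = f$min, max = f$max, ec50_umolL = f$ec50_umolL,
      hillslope = f$hillslope, converged = f$converged,
      residual_ss = f$residual_ss
    )
  })
}

#' Summarize per-replicate EC50s into a mean +/- SD or an ND call
#'
#' Responders are summarized as the arithmetic mean and sample SD of the
#' per-replicate EC50s. A replicate votes "nonresponder" when its fit
#' failed, its fitted amplitude (`max - min`) is below `3 * mock_sd`, or
#' its fitted EC50 exceeds the maximum tested concentration; a strict
#' majority of nonresponder votes (2 of 3 at the standard replicate count)
#' yields status `"nonresponder"` with ND (`NA`) values.
#'
#' @param fits Tibble from [fit_hill_all()] (or a list of `hill_fit`s).
#' @param max_tested_umolL Highest tested concentration (micromol/L).
#' @param mock_sd SD of mock-subtracted, normalized mock responses (the
#'   `mock_sd` attribute of the fitted curve); 0 disables the amplitude
#'   criterion.
#' @return A one-row tibble: `mean_ec50`, `sd_ec50`, `n`, `status`.
#' @export
summarize_ec50 <- function(fits, max_tested_umolL, mock_sd = 0) {
  if (!is.data.frame(fits)) {
    fits <- purrr::map_dfr(fits, function(f) {
      tibble(ec50_umolL = f$ec50_umolL, min = f$min, max = f$max,
        converged = f$converged)
    })
  }
  if (nrow(fits) < 1) abort_data("need fits from >= 1 replicate")

  votes_nd <- !fits$converged |
    (fits$max - fits$min) < 3 * mock_sd |
    fits$ec50_umolL > max_tested_umolL
  n <- nrow(fits)

  if (sum(votes_nd) >= ceiling((n + 1) / 2)) {
    return(tibble(mean_ec50 = NA_real_, sd_ec50 = NA_real_, n = n,
      status = "nonresponder"))
  }
  usable <- fits$converged & !votes_nd
  if (any(!usable)) {
    warn(paste0(sum(!usable), " replicate fit(s) excluded from the EC50 summary"))
  }
  ec50 <- fits$ec50_umolL[usable]
  tibble(
    mean_ec50 = mean(ec50),
    sd_ec50 = if (length(ec50) > 1) sd(ec50) else 0,
    n = length(ec50),
    status = "responder"
  )
}

#' Paired two-tailed t test on response amplitudes
#'
#' Classic paired t on mock-subtracted raw amplitudes, paired by replicate
#' index. Identical paired samples return `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors of equal length (one value per replicate).
#' @return A tibble with `t`, `p_value`, `df`, `mean_diff`, `n`.
#' @export
#' @examples
#' compare_amplitudes(c(1, 2, 3), c(2, 4, 6))
compare_amplitudes <- function(a, b) {
  if (length(a) != length(b)) {
    abort_data("amplitude vectors must be paired (equal length)")
  }
  n <- length(a)
  if (n < 2) {
    abort("need >= 2 pairs for a paired t test",
      class = "orscreen_insufficient_data")
  }
  d <- a - b
  if (sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble(t = t_stat, p_value = p, df = n - 1, mean_diff = mean(d), n = n)
}
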