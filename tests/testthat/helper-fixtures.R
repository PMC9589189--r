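# shared fixtures built in code

# a minimal hand-built plate: one positive, one mock, test variants with
# known signals; basal fixed at 100 so delta arithmetic is transparent
make_plate <- function(test_signals, plate_id = "P01", pos_signal = 300,
                       mock_signal = 0) {
  n <- length(test_signals)
  ids <- names(test_signals) %||% sprintf("V%02d", seq_len(n))
  sig <- c(pos_signal, mock_signal, unname(test_signals))
  tibble::tibble(
    plate_id = plate_id,
    well_id = sprintf("A%02d", seq_len(n + 2)),
    variant_id = c("OR1A1", "mock", ids),
    role = c("positive", "mock", rep("test", n)),
    odorant = "Z4-11Al", conc_umolL = 30,
    basal_1 = 100, basal_2 = 100, basal_3 = 100,
    post_1 = 100 + sig, post_2 = 100 + sig, post_3 = 100 + sig
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table1_responders <- function() {
  dplyr::filter(or_ec50_reference(), responder)
}

dr_concs <- c(0.3, 1, 3, 10, 30, 100, 300, 1000)

# 100 default planted screens analysed once, shared between the
# false-positive-calibration and sole-hit acceptance checks
screen_mc_cache <- new.env(parent = emptyenv())
screen_mc_100 <- function() {
  if (is.null(screen_mc_cache$res)) {
    screen_mc_cache$res <- lapply(1:100, function(s) {
      run_screen(gen_screen(screen_config(seed = s)))
    })
  }
  screen_mc_cache$res
}
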