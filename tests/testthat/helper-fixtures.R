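# fixtures built in code: tiny trial tables and random datasets

# single-participant trial table from explicit vectors
make_trials <- function(y, r, symbol = "outgroup", valid = TRUE,
                        participant_id = "p1") {
  n <- length(y)
  tibble::tibble(
    participant_id = participant_id,
    arm = "social_conflict",
    block = 1L,
    trial = seq_len(n),
    symbol = rep_len(symbol, n),
    start_pos = 0.5,
    final_pos = 0.5,
    raw_distance = 0,
    y_value = y,
    valid = rep_len(valid, n),
    outcome_r = r,
    outcome_eur = ifelse(r == 1, 0.05, -0.05)
  )
}

# random two-symbol dataset with interleaved trials, for property tests
random_trials <- function(n_per_symbol = 10, seed = 1) {
  withr::with_seed(seed, {
    sym <- sample(rep(c("ingroup", "outgroup"), n_per_symbol))
    n <- length(sym)
    tibble::tibble(
      participant_id = "p1",
      arm = "social_conflict",
      block = 1L,
      trial = seq_len(n),
      symbol = sym,
      start_pos = 0.5,
      final_pos = 0.5,
      raw_distance = 0,
      y_value = runif(n),
      valid = TRUE,
      outcome_r = rbinom(n, 1, 0.5),
      outcome_eur = 0.05
    )
  })
}

# random parameter vector for a model, uniform in [0, 1]
random_params <- function(model_id, seed = 1) {
  spec <- aalearn::model_spec(model_id)
  withr::with_seed(seed, stats::setNames(runif(spec$k), spec$par_names))
}
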