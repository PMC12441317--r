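#' Parameter recovery study
#'
#' Validates the estimation chain: simulates agents with known parameters
#' drawn from the population distribution, refits the generating model to
#' each agent's data, and tabulates bias, RMSE and Pearson correlation of
#' recovered against true values per parameter.
#'
#' @param design an [task_design()] object.
#' @param model_id generating (and fitted) model, default 5.
#' @param n_agents number of simulated participants (default 50).
#' @param noise_sd response noise of the generator (default 0.10).
#' @param p_invalid per-trial invalidity probability (default 0; recovery
#'   isolates estimation error from exclusion effects).
#' @param seed master seed.
#' @param n_starts optimisation restarts per fit (default 10).
#' @param population truncated-normal population, see
#'   [default_population()].
#' @return a list with `params` (tibble per parameter: `param`, `bias`,
#'   `rmse`, `correlation`, `n`), `table` (per-agent long tibble of
#'   `true` and `recovered` values) and `n_failed` (fit failures,
#'   excluded from the summaries).
#' @export
parameter_recovery <- function(design, model_id = 5L, n_agents = 50L,
                               noise_sd = 0.10, p_invalid = 0,
                               seed = 1L, n_starts = 10L,
                               population = default_population(design$arm, model_id)) {
  co <- simulate_cohort(design, n_agents,
    seed = derive_seed(seed, 1L),
    population = population, model_id = model_id,
    noise_sd = noise_sd, p_invalid = p_invalid
  )
  trials <- exclude_participants(co$trials)
  fits <- fit_cohort(trials,
    models = model_id, n_starts = n_starts,
    seed = derive_seed(seed, 2L)
  )
  n_failed <- sum(fits$failed)
  ok <- fits[!fits$failed, , drop = FALSE]
  pn <- model_spec(model_id)$par_names
  rec <- ok |>
    tidyr::pivot_longer(dplyr::all_of(pn), names_to = "param", values_to = "recovered") |>
    dplyr::select("participant_id", "param", "recovered")
  tab <- dplyr::inner_join(
    dplyr::rename(co$truth, true = "value"), rec,
    by = c("participant_id", "param")
  )
  params <- tab |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(
      bias = mean(.data$recovered - .data$true),
      rmse = sqrt(mean((.data$recovered - .data$true)^2)),
      correlation = if (sd(.data$true) > 0 && sd(.data$recovered) > 0) {
        stats::cor(.data$true, .data$recovered)
      } else {
        NA_real_
      },
      n = dplyr::n(),
      .groups = "drop"
    )
  params <- params[match(pn, params$param), , drop = FALSE]
  list(params = params, table = tab, n_failed = n_failed)
}

#' Model recovery study
#'
#' Validates model selection: for each generating model, simulates
#' independent cohorts, fits all candidate models to every cohort, picks
#' the winner by summed BIC, and tabulates the confusion matrix of
#' generating against selected model.
#'
#' @param design an [task_design()] object.
#' @param generating_models integer vector of generator ids.
#' @param n_cohorts cohorts per generating model (default 10).
#' @param n_agents agents per cohort (default 16; a deliberately small
#'   cohort keeps the study fast while leaving the BIC ranking stable).
#' @param noise_sd generator response noise (default 0.10).
#' @param seed master seed.
#' @param n_starts optimisation restarts per fit (default 5).
#' @param models_to_fit candidate models (default `1:6`).
#' @return a list with `confusion` (matrix generating x selected; row sums
#'   equal `n_cohorts`) and `details` (tibble `generating`, `cohort`,
#'   `selected`, `seed`).
#' @export
model_recovery <- function(design, generating_models = c(1L, 5L),
                           n_cohorts = 10L, n_agents = 16L,
                           noise_sd = 0.10, seed = 1L, n_starts = 5L,
                           models_to_fit = 1:6) {
  details <- list()
  for (g in generating_models) {
    for (ci in seq_len(n_cohorts)) {
      cohort_seed <- derive_seed(seed, g, ci)
      co <- simulate_cohort(design, n_agents,
        seed = cohort_seed,
        population = default_population(design$arm, g),
        model_id = g, noise_sd = noise_sd, p_invalid = 0
      )
      fits <- fit_cohort(co$trials,
        models = models_to_fit,
        n_starts = n_starts, seed = derive_seed(cohort_seed, 1L)
      )
      cmp <- compare_models(fits)
      details[[length(details) + 1L]] <- tibble::tibble(
        generating = g, cohort = ci,
        selected = attr(cmp, "winner"), seed = cohort_seed
      )
    }
  }
  details <- dplyr::bind_rows(details)
  confusion <- matrix(0L,
    nrow = length(generating_models), ncol = length(models_to_fit),
    dimnames = list(
      paste0("gen_", generating_models),
      paste0("sel_", models_to_fit)
    )
  )
  for (i in seq_len(nrow(details))) {
    confusion[
      paste0("gen_", details$generating[i]),
      paste0("sel_", details$selected[i])
    ] <- confusion[
      paste0("gen_", details$generating[i]),
      paste0("sel_", details$selected[i])
    ] + 1L
  }
  list(confusion = confusion, details = details)
}
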