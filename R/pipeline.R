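.trial_columns <- c(
  "participant_id", "arm", "block", "trial", "symbol", "start_pos",
  "final_pos", "raw_distance", "y_value", "valid", "outcome_r", "outcome_eur"
)

#' Write a trial table to CSV
#'
#' Writes the fixed 12-column trial layout; missing outcomes (invalid
#' trials) are encoded as empty fields.
#'
#' @param trials trial table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  readr::write_csv(trials[, .trial_columns], path, na = "")
  invisible(path)
}

#' Load and validate a trial CSV
#'
#' Reads a trial table in the fixed column layout, checks the schema and
#' value ranges, and recomputes the per-symbol encounter index over valid
#' trials. Violations are reported with the offending column or row.
#'
#' @param path CSV file with header `participant_id, arm, block, trial,
#'   symbol, start_pos, final_pos, raw_distance, y_value, valid,
#'   outcome_r, outcome_eur`.
#' @return validated trial tibble (with an `encounter_k` column).
#' @export
load_trials <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(.trial_columns, header)
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- readr::read_csv(path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      arm = readr::col_character(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      symbol = readr::col_character(),
      start_pos = readr::col_double(),
      final_pos = readr::col_double(),
      raw_distance = readr::col_double(),
      y_value = readr::col_double(),
      valid = readr::col_logical(),
      outcome_r = readr::col_integer(),
      outcome_eur = readr::col_double()
    ),
    na = c("", "NA")
  )
  missing <- setdiff(.trial_columns, names(x))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(x[, c("participant_id", "trial")])
  if (any(dup)) {
    stop("duplicate (participant_id, trial) at row ", which(dup)[1], call. = FALSE)
  }
  bad_y <- which(x$valid & (is.na(x$y_value) | x$y_value < 0 | x$y_value > 1))
  if (length(bad_y)) {
    stop("y_value out of [0, 1] (or missing on a valid trial) at row ", bad_y[1],
      call. = FALSE
    )
  }
  bad_sym <- which(!x$symbol %in% c("ingroup", "outgroup"))
  if (length(bad_sym)) {
    stop("unknown symbol at row ", bad_sym[1], call. = FALSE)
  }
  bad_out <- which(x$valid & is.na(x$outcome_r))
  if (length(bad_out)) {
    stop("valid trial without outcome at row ", bad_out[1], call. = FALSE)
  }
  bad_inv <- which(!x$valid & (!is.na(x$outcome_r) | x$outcome_eur != 0))
  if (length(bad_inv)) {
    stop("invalid trial carries an outcome at row ", bad_inv[1], call. = FALSE)
  }
  unsorted <- x |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$trial, strictly = TRUE), .groups = "drop")
  if (any(!unsorted$ok)) {
    stop("trials not strictly ordered for participant ",
      unsorted$participant_id[!unsorted$ok][1],
      call. = FALSE
    )
  }
  x |>
    dplyr::group_by(.data$participant_id, .data$symbol) |>
    dplyr::mutate(
      encounter_k = dplyr::if_else(.data$valid, cumsum(.data$valid), NA_integer_)
    ) |>
    dplyr::ungroup()
}

#' Run configuration for a full analysis
#'
#' A run is reproducible from `(config, seed)` alone: the master seed is
#' fanned out deterministically to sequence generation, agents, and every
#' optimisation start.
#'
#' @param arm study arm.
#' @param n_participants cohort size (defaults to the usable sample of the
#'   matching arm: 47 conflict, 50 social control, 47 non-social).
#' @param models model ids to fit (default `1:6`).
#' @param n_starts restarts per fit.
#' @param mode fitting mode.
#' @param seed master seed.
#' @param noise_sd,p_invalid generator settings.
#' @param model_id generating model.
#' @param population parameter population (default per arm).
#' @param run_recovery also run a parameter-recovery study (default
#'   `FALSE`).
#' @param out_dir output directory.
#' @return an object of class `aal_config` (a fully serialisable list).
#' @export
run_config <- function(arm = "social_conflict",
                       n_participants = NULL,
                       models = 1:6,
                       n_starts = 10L,
                       mode = "teacher_forced",
                       seed = 1L,
                       noise_sd = 0.10,
                       p_invalid = 0.01,
                       model_id = 5L,
                       population = NULL,
                       run_recovery = FALSE,
                       out_dir = tempfile("aal_run_")) {
  n_default <- c(social_conflict = 47L, social_control = 50L, nonsocial_control = 47L)
  structure(
    list(
      arm = arm,
      n_participants = n_participants %||% unname(n_default[arm]),
      models = models,
      n_starts = n_starts,
      mode = mode,
      seed = as.integer(seed),
      noise_sd = noise_sd,
      p_invalid = p_invalid,
      model_id = as.integer(model_id),
      population = population,
      run_recovery = run_recovery,
      out_dir = out_dir
    ),
    class = "aal_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulate -> exclude -> fit -> compare pipeline
#'
#' Executes all stages for one configuration, writing every artefact as
#' CSV plus a human-readable markdown report to `config$out_dir`, and
#' returns the artefacts invisibly. A stage failure aborts with the stage
#' name; artefacts written before the failure are left in place.
#'
#' @param config an [run_config()] object.
#' @param quiet suppress progress messages (default `TRUE`).
#' @return (invisibly) a list: `trials`, `ratings`, `truth`, `exclusion`,
#'   `fits`, `comparison`, `slopes`, and `recovery` when requested.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "aal_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  design <- .stage("design", task_design(config$arm))
  say("simulating ", config$n_participants, " participants (", config$arm, ")")
  co <- .stage("simulate", simulate_cohort(
    design, config$n_participants,
    seed = derive_seed(config$seed, 1L),
    population = config$population %||% default_population(config$arm, config$model_id),
    model_id = config$model_id,
    noise_sd = config$noise_sd, p_invalid = config$p_invalid
  ))
  write_trials(co$trials, file.path(config$out_dir, "trials.csv"))
  readr::write_csv(co$ratings, file.path(config$out_dir, "ratings.csv"))
  readr::write_csv(co$truth, file.path(config$out_dir, "true_parameters.csv"))

  exclusion <- .stage("exclude", apply_exclusion(co$trials))
  readr::write_csv(exclusion, file.path(config$out_dir, "exclusion.csv"))
  kept <- .stage("exclude", exclude_participants(co$trials))

  say("fitting models ", paste(config$models, collapse = ","))
  fits <- .stage("fit", fit_cohort(
    kept,
    models = config$models, n_starts = config$n_starts,
    seed = derive_seed(config$seed, 2L), mode = config$mode
  ))
  readr::write_csv(fits, file.path(config$out_dir, "fits.csv"), na = "")

  comparison <- .stage("compare", compare_models(fits))
  readr::write_csv(comparison, file.path(config$out_dir, "comparison.csv"))
  slopes <- .stage("slopes", per_symbol_slopes(kept))
  readr::write_csv(slopes$slopes, file.path(config$out_dir, "slopes.csv"))

  recovery <- NULL
  if (isTRUE(config$run_recovery)) {
    say("running parameter recovery")
    recovery <- .stage("recover", parameter_recovery(
      design,
      model_id = config$model_id, n_agents = config$n_participants,
      noise_sd = config$noise_sd, seed = derive_seed(config$seed, 3L),
      n_starts = config$n_starts
    ))
    readr::write_csv(recovery$params, file.path(config$out_dir, "recovery_params.csv"))
  }

  .stage("report", write_run_report(
    file.path(config$out_dir, "report.md"),
    config, exclusion, comparison, slopes, recovery
  ))
  say("done; artefacts in ", config$out_dir)
  invisible(list(
    trials = co$trials, ratings = co$ratings, truth = co$truth,
    exclusion = exclusion, fits = fits, comparison = comparison,
    slopes = slopes, recovery = recovery
  ))
}

# markdown run report echoing the comparison-table layout
write_run_report <- function(path, config, exclusion, comparison, slopes,
                             recovery = NULL) {
  lines <- c(
    "# Approach-avoidance learning run report",
    "",
    sprintf(
      "- arm: %s | n = %d | generator: model %d | noise sd = %.2f | seed = %d",
      config$arm, config$n_participants, config$model_id,
      config$noise_sd, config$seed
    ),
    sprintf(
      "- excluded participants: %d of %d",
      sum(!exclusion$keep), nrow(exclusion)
    ),
    "",
    "## Model comparison (summed BIC; lower is better)",
    "",
    "| model | K | mean R2 | summed BIC |",
    "|---|---|---|---|",
    vapply(seq_len(nrow(comparison)), function(i) {
      fmt <- if (comparison$winner[i]) "| **model %d** | **%d** | **%.3f** | **%.1f** |" else "| model %d | %d | %.3f | %.1f |"
      sprintf(
        fmt, comparison$model_id[i], comparison$k[i],
        comparison$mean_r2[i], comparison$sum_bic[i]
      )
    }, character(1)),
    ""
  )
  if (!is.null(slopes$contrast)) {
    lines <- c(lines, sprintf(
      "Per-symbol slope contrast (out-group vs in-group): t = %.3f, df = %.1f, p = %.4f",
      slopes$contrast$t, slopes$contrast$df, slopes$contrast$p
    ), "")
  }
  if (!is.null(recovery)) {
    lines <- c(
      lines, "## Parameter recovery", "",
      "| param | bias | RMSE | correlation |", "|---|---|---|---|",
      vapply(seq_len(nrow(recovery$params)), function(i) {
        sprintf(
          "| %s | %.3f | %.3f | %.3f |",
          recovery$params$param[i], recovery$params$bias[i],
          recovery$params$rmse[i], recovery$params$correlation[i]
        )
      }, character(1)),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}
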