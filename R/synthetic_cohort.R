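#' Configuration of one synthetic agent
#'
#' Bundles everything needed to forward-simulate a participant: the
#' generating learning model and its true parameters, the response-noise
#' level, the per-trial probability of an invalid (no-movement) trial, and
#' the impression-rating distribution.
#'
#' Parameter defaults correspond to the mean model-5 estimates of the
#' conflict arm (`alpha_pos = 0.38`, `alpha_neg = 0.01`, `beta = 0.67`,
#' `v1_in = 0.70`, `v1_out = 0.80`); impression defaults encode a stable
#' in-group bias of about half a point on the 1-7 scale (in-group 4.2,
#' out-group 3.7, sd 1.1) with no pre/post change.
#'
#' @param generating_model integer 1..6.
#' @param true_params named numeric vector matching the model's parameter
#'   names (see [model_spec()]); all in `[0, 1]`.
#' @param noise_sd sd of the Gaussian response noise added on the oriented
#'   `[0, 1]` scale (default 0.10).
#' @param p_invalid per-trial probability of an invalid trial
#'   (default 0.01).
#' @param impression_means named numeric, mean pre-rating per group.
#' @param impression_sd sd of the ratings (default 1.1).
#' @param identification_score in-group identification score, 1-7
#'   (metadata; default 4.3).
#' @param round_ratings round simulated ratings to the integer 1-7 Likert
#'   grid (default `TRUE`).
#' @return an object of class `aal_agent`.
#' @export
agent_config <- function(generating_model = 5L,
                         true_params = c(
                           alpha_pos = 0.38, alpha_neg = 0.01,
                           beta = 0.67, v1_in = 0.70, v1_out = 0.80
                         ),
                         noise_sd = 0.10,
                         p_invalid = 0.01,
                         impression_means = c(ingroup = 4.2, outgroup = 3.7),
                         impression_sd = 1.1,
                         identification_score = 4.3,
                         round_ratings = TRUE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p_invalid < 0 || p_invalid >= 1) stop("p_invalid must be in [0, 1)", call. = FALSE)
  if (any(impression_means < 1 | impression_means > 7)) {
    stop("impression means must lie in [1, 7]", call. = FALSE)
  }
  .expand_params(generating_model, true_params) # validates names and bounds
  structure(
    list(
      generating_model = as.integer(generating_model),
      true_params = true_params,
      noise_sd = noise_sd,
      p_invalid = p_invalid,
      impression_means = impression_means,
      impression_sd = impression_sd,
      identification_score = identification_score,
      round_ratings = round_ratings
    ),
    class = "aal_agent"
  )
}

#' Forward-simulate one participant
#'
#' Runs the agent through the full task: a pseudo-randomised symbol
#' sequence is drawn, and on each valid trial the agent emits the
#' generating model's teacher-forced prediction plus Gaussian noise
#' (clamped to `[0, 1]`) on the oriented scale, which is mapped back
#' through orientation and de-normalisation to a signed distance and a
#' final manikin position; the outcome is then sampled from the design's
#' schedule. Invalid trials are injected with probability `p_invalid`;
#' they produce no outcome, do not advance the encounter index and do not
#' update the agent's value.
#'
#' @param agent an [agent_config()] object.
#' @param design an [task_design()] object.
#' @param seed integer seed; the whole participant is reproducible from it.
#' @param participant_id identifier stored in the output tables.
#' @return a list with `trials` (tibble, one row per trial in the fixed
#'   column layout, plus `encounter_k`) and `ratings` (tibble
#'   `participant_id`, `group`, `time`, `rating`).
#' @export
simulate_participant <- function(agent, design, seed, participant_id = "p1") {
  stopifnot(inherits(agent, "aal_agent"), inherits(design, "aal_design"))
  ex <- .expand_params(agent$generating_model, agent$true_params)
  seqs <- build_trial_sequence(design, derive_seed(seed, 1L))
  n_total <- design$n_blocks * design$trials_per_block

  withr::with_seed(derive_seed(seed, 2L), {
    enc <- c(ingroup = 0L, outgroup = 0L)
    last_y <- c(ingroup = NA_real_, outgroup = NA_real_)
    last_r <- c(ingroup = NA_real_, outgroup = NA_real_)

    block <- integer(n_total)
    symbol <- character(n_total)
    start_pos <- final_pos <- raw_distance <- y_value <- numeric(n_total)
    encounter_k <- integer(n_total)
    valid <- logical(n_total)
    outcome_r <- integer(n_total)
    outcome_eur <- numeric(n_total)

    t <- 0L
    for (b in seq_len(design$n_blocks)) {
      for (s in seqs[[b]]) {
        t <- t + 1L
        block[t] <- b
        symbol[t] <- s
        start <- runif(1, design$start_jitter[1], design$start_jitter[2])
        start_pos[t] <- start
        if (runif(1) < agent$p_invalid) {
          valid[t] <- FALSE
          final_pos[t] <- start
          raw_distance[t] <- 0
          y_value[t] <- NA_real_
          encounter_k[t] <- NA_integer_
          outcome_r[t] <- NA_integer_
          outcome_eur[t] <- 0
          next
        }
        k <- enc[[s]] + 1L
        pred <- if (k == 1L) {
          ex$v1[[s]]
        } else {
          delta <- last_r[[s]] - last_y[[s]]
          a <- if (delta >= 0) ex$alpha_pos[[s]] else ex$alpha_neg[[s]]
          (last_y[[s]] + a * delta) * ex$beta[[s]]
        }
        y <- clamp(pred + rnorm(1, 0, agent$noise_sd))
        raw <- oriented_to_raw(y, s, design)
        out <- sample_outcome(design, s, raw)

        valid[t] <- TRUE
        encounter_k[t] <- k
        y_value[t] <- y
        raw_distance[t] <- raw
        final_pos[t] <- start + raw
        outcome_r[t] <- out$outcome_r
        outcome_eur[t] <- out$outcome_eur

        enc[[s]] <- k
        last_y[[s]] <- y
        last_r[[s]] <- out$outcome_r
      }
    }

    trials <- tibble::tibble(
      participant_id = participant_id,
      arm = design$arm,
      block = block,
      trial = seq_len(n_total),
      symbol = symbol,
      encounter_k = encounter_k,
      start_pos = start_pos,
      final_pos = final_pos,
      raw_distance = raw_distance,
      y_value = y_value,
      valid = valid,
      outcome_r = outcome_r,
      outcome_eur = outcome_eur
    )
    ratings <- simulate_impressions(agent)
    ratings$participant_id <- participant_id
    ratings <- ratings[, c("participant_id", "group", "time", "rating")]
    list(trials = trials, ratings = ratings)
  })
}

#' Simulate pre/post impression ratings for one agent
#'
#' Pre- and post-learning ratings for the in-group and out-group are drawn
#' from the same group-specific mean (the generator encodes a group main
#' effect but a null time effect: only sampling noise distinguishes pre
#' from post), then optionally rounded and clamped to the 1-7 Likert grid.
#' Draws come from the current RNG stream.
#'
#' @param agent an [agent_config()] object.
#' @return tibble with columns `group`, `time` (`"pre"`/`"post"`),
#'   `rating`.
#' @export
simulate_impressions <- function(agent) {
  stopifnot(inherits(agent, "aal_agent"))
  groups <- names(agent$impression_means)
  grid <- expand.grid(
    group = groups, time = c("pre", "post"),
    stringsAsFactors = FALSE
  )
  rating <- rnorm(
    nrow(grid),
    mean = agent$impression_means[grid$group],
    sd = agent$impression_sd
  )
  if (agent$round_ratings) rating <- round(rating)
  rating <- clamp(rating, 1, 7)
  tibble::tibble(group = grid$group, time = grid$time, rating = rating)
}

#' Default parameter population for a study arm
#'
#' Truncated-normal population means and sds for the model-5 generator,
#' per arm. The two 80/20 arms use the respective fitted conflict and
#' non-social means. The random-reward control arm showed a stable
#' in-group approach bias with no trial-by-trial change in the original
#' data (it was not modelled for that reason), so its generator encodes
#' that steady state: valence-symmetric learning-rate means, the conflict
#' response weight, and equal initial values placed at the stationary
#' point of the teacher-forced dynamics under a 50/50 schedule,
#' `v1 = 0.5 * alpha * beta / (1 - beta * (1 - alpha)) ~= 0.22` at the
#' population means — values fluctuate around a stable bias (approach
#' in-group, avoid out-group) with no drift and no symbol asymmetry.
#'
#' @param arm study arm name.
#' @param model_id generating model (default 5).
#' @return a named list, one `c(mean, sd)` pair per model parameter.
#' @export
default_population <- function(arm = c(
                                 "social_conflict", "social_control",
                                 "nonsocial_control"
                               ),
                               model_id = 5L) {
  arm <- match.arg(arm)
  base <- switch(arm,
    social_conflict = list(
      alpha_pos = c(0.38, 0.39), alpha_neg = c(0.01, 0.02),
      beta = c(0.67, 0.18), v1_in = c(0.70, 0.24), v1_out = c(0.80, 0.21)
    ),
    nonsocial_control = list(
      alpha_pos = c(0.36, 0.39), alpha_neg = c(0.01, 0.02),
      beta = c(0.68, 0.17), v1_in = c(0.67, 0.26), v1_out = c(0.88, 0.19)
    ),
    social_control = list(
      alpha_pos = c(0.38, 0.39), alpha_neg = c(0.38, 0.39),
      beta = c(0.67, 0.18), v1_in = c(0.22, 0.22), v1_out = c(0.22, 0.22)
    )
  )
  if (model_id == 5L) {
    return(base)
  }
  # map the model-5 population onto the parameter set of another model
  spec <- model_spec(model_id)
  pool <- c(base, list(
    alpha = base$alpha_pos, alpha_in = base$alpha_pos, alpha_out = base$alpha_pos,
    alpha_pos_in = base$alpha_pos, alpha_pos_out = base$alpha_pos,
    alpha_neg_in = base$alpha_neg, alpha_neg_out = base$alpha_neg,
    beta_in = base$beta, beta_out = base$beta
  ))
  pool[spec$par_names]
}

#' Simulate a cohort of independent agents
#'
#' Draws each agent's true parameters from truncated-normal population
#' distributions (truncated to the `[0, 1]` bounds), derives a
#' per-participant seed deterministically from the cohort seed, and
#' forward-simulates every participant with [simulate_participant()].
#'
#' @param design an [task_design()] object.
#' @param n_participants number of agents.
#' @param seed integer master seed.
#' @param population named list of `c(mean, sd)` pairs, one per parameter
#'   of the generating model; default [default_population()] for the
#'   design's arm.
#' @param model_id generating model (default 5).
#' @param noise_sd,p_invalid,... passed to [agent_config()].
#' @return a list with `trials` (long tibble over participants), `truth`
#'   (tibble `participant_id`, `model`, `param`, `value`) and `ratings`.
#' @examples
#' co <- simulate_cohort(task_design("social_conflict"), 3, seed = 7)
#' nrow(co$trials) # 360
#' @export
simulate_cohort <- function(design, n_participants, seed,
                            population = default_population(design$arm, model_id),
                            model_id = 5L,
                            noise_sd = 0.10, p_invalid = 0.01, ...) {
  stopifnot(inherits(design, "aal_design"), n_participants >= 1)
  spec <- model_spec(model_id)
  if (!setequal(names(population), spec$par_names)) {
    stop("population must name exactly the parameters of model ", model_id,
      call. = FALSE
    )
  }
  bad_sd <- vapply(population, function(p) p[2] < 0, logical(1))
  if (any(bad_sd)) stop("population sd(s) must be >= 0", call. = FALSE)

  ids <- sprintf("p%03d", seq_len(n_participants))
  truths <- withr::with_seed(derive_seed(seed, 0L), {
    lapply(seq_len(n_participants), function(i) {
      vapply(
        spec$par_names,
        function(pn) rtruncnorm(1, population[[pn]][1], population[[pn]][2]),
        numeric(1)
      )
    })
  })

  sims <- lapply(seq_len(n_participants), function(i) {
    agent <- agent_config(
      generating_model = model_id, true_params = truths[[i]],
      noise_sd = noise_sd, p_invalid = p_invalid, ...
    )
    simulate_participant(agent, design, derive_seed(seed, i), ids[i])
  })

  truth <- dplyr::bind_rows(lapply(seq_len(n_participants), function(i) {
    tibble::tibble(
      participant_id = ids[i], model = model_id,
      param = spec$par_names, value = unname(truths[[i]])
    )
  }))
  list(
    trials = dplyr::bind_rows(lapply(sims, `[[`, "trials")),
    truth = truth,
    ratings = dplyr::bind_rows(lapply(sims, `[[`, "ratings"))
  )
}
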