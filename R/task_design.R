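#' Task design for the approach-avoidance learning task
#'
#' Encodes one of the three study arms of the intergroup approach-avoidance
#' paradigm: a manikin on a horizontal line is moved towards (approach,
#' positive distance) or away from (avoidance, negative distance) one of two
#' symbols, and the signed movement direction determines a probabilistic
#' monetary outcome.
#'
#' The three arms differ only in the reward schedule:
#' \describe{
#'   \item{`social_conflict`}{approaching the in-group symbol is rewarded on
#'     20\% of trials (avoiding on 80\%), approaching the out-group symbol on
#'     80\% (avoiding on 20\%) — incentives conflict with an in-group
#'     approach bias.}
#'   \item{`social_control`}{reward probability 0.5 for every symbol and
#'     direction (random outcomes).}
#'   \item{`nonsocial_control`}{the 80/20 schedule of the conflict arm, but
#'     the symbols carry no social meaning; symbol 1 plays the in-group
#'     role, symbol 2 the out-group role.}
#' }
#'
#' @param arm one of `"social_conflict"`, `"social_control"`,
#'   `"nonsocial_control"`.
#' @param n_blocks number of blocks (default 3).
#' @param trials_per_block trials per block, split evenly over the two
#'   symbols (default 40, i.e. 20 per symbol).
#' @param max_run maximum number of consecutive same-symbol trials
#'   (default 2).
#' @param outcome_magnitude absolute monetary outcome per trial in EUR
#'   (default 0.05; gain on reward, loss on punishment).
#' @param start_jitter numeric length-2 interval of line fractions from
#'   which the manikin start position is drawn uniformly (default
#'   `c(0.40, 0.60)`).
#' @param max_excursion largest absolute signed distance `D` representable
#'   on the normalised scale (default 0.60).
#' @param reward_schedule optional 2x2 numeric matrix overriding the arm
#'   default, rows `c("ingroup", "outgroup")`, columns
#'   `c("approach", "avoid")`, entries reward probabilities in `[0, 1]`.
#'
#' @return an object of class `aal_design` (a list with the above fields).
#' @examples
#' d <- task_design("social_conflict")
#' d$reward_schedule["outgroup", "approach"] # 0.8
#' @export
task_design <- function(arm = c("social_conflict", "social_control", "nonsocial_control"),
                        n_blocks = 3L,
                        trials_per_block = 40L,
                        max_run = 2L,
                        outcome_magnitude = 0.05,
                        start_jitter = c(0.40, 0.60),
                        max_excursion = 0.60,
                        reward_schedule = NULL) {
  arm <- match.arg(arm)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  max_run <- as.integer(max_run)
  if (trials_per_block %% 2L != 0L) {
    stop("trials_per_block must be even (equal per-symbol counts)", call. = FALSE)
  }
  if (max_run < 1L) stop("max_run must be >= 1", call. = FALSE)
  if (length(start_jitter) != 2L || start_jitter[1] > start_jitter[2]) {
    stop("start_jitter must be an ordered length-2 interval", call. = FALSE)
  }
  if (max_excursion <= 0) stop("max_excursion must be positive", call. = FALSE)

  if (is.null(reward_schedule)) {
    reward_schedule <- switch(arm,
      social_control = matrix(0.5, 2, 2,
        dimnames = list(c("ingroup", "outgroup"), c("approach", "avoid"))
      ),
      # conflict and non-social arms share the 80/20 schedule
      matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2,
        dimnames = list(c("ingroup", "outgroup"), c("approach", "avoid"))
      )
    )
  }
  stopifnot(
    is.matrix(reward_schedule),
    identical(rownames(reward_schedule), c("ingroup", "outgroup")),
    identical(colnames(reward_schedule), c("approach", "avoid"))
  )
  if (any(reward_schedule < 0 | reward_schedule > 1)) {
    stop("reward probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (arm == "social_control" && any(reward_schedule != 0.5)) {
    stop("social_control arm requires all reward probabilities equal to 0.5",
      call. = FALSE
    )
  }
  if (arm %in% c("social_conflict", "nonsocial_control")) {
    ok <- all(abs(rowSums(reward_schedule) - 1) < 1e-12)
    if (!ok) {
      stop("conflict-type schedules require P(reward|approach) + P(reward|avoid) = 1 per symbol",
        call. = FALSE
      )
    }
  }

  structure(
    list(
      arm = arm,
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      max_run = max_run,
      outcome_magnitude = outcome_magnitude,
      start_jitter = start_jitter,
      max_excursion = max_excursion,
      reward_schedule = reward_schedule
    ),
    class = "aal_design"
  )
}

#' @export
print.aal_design <- function(x, ...) {
  cat(sprintf(
    "<aal_design> arm=%s, %d blocks x %d trials (max run %d), outcome +/-%.2f EUR\n",
    x$arm, x$n_blocks, x$trials_per_block, x$max_run, x$outcome_magnitude
  ))
  print(x$reward_schedule)
  invisible(x)
}

# exact feasibility of completing a two-symbol sequence under a run limit:
# with `a` of the trailing symbol and `b` of the other remaining, and a
# trailing run of length l (<= m), a completion exists iff
#   a <= (m - l) + m * b   (the a's fit between the b's)
#   b <= m * (a + 1)       (the b's fit between the a's)
.can_finish <- function(a, b, l, m) {
  a <= (m - l) + m * b && b <= m * (a + 1)
}

#' Build a pseudo-randomised symbol sequence
#'
#' Draws, per block, an order of the two symbols with exactly half the
#' trials each and no more than `max_run` consecutive trials of the same
#' symbol. The sequence is sampled constructively: at each position a
#' symbol is drawn (with probability proportional to its remaining count)
#' from the set of choices that provably still allow the block to be
#' completed, so generation never dead-ends and tight constraints such as
#' `max_run = 1` are handled exactly.
#'
#' @param design an [task_design()] object.
#' @param seed integer seed; identical seeds give identical sequences.
#' @return a list of length `design$n_blocks`; each element a character
#'   vector of `"ingroup"` / `"outgroup"` labels of length
#'   `design$trials_per_block`.
#' @examples
#' seqs <- build_trial_sequence(task_design("social_conflict"), seed = 1)
#' table(seqs[[1]])
#' @export
build_trial_sequence <- function(design, seed) {
  stopifnot(inherits(design, "aal_design"))
  per_symbol <- design$trials_per_block %/% 2L
  m <- design$max_run
  if (!.can_finish(per_symbol, per_symbol, 0L, m)) {
    stop("infeasible sequence constraint: cannot place ", per_symbol,
      " trials per symbol with max_run = ", m,
      call. = FALSE
    )
  }
  labels <- c("ingroup", "outgroup")
  withr::with_seed(seed, {
    lapply(seq_len(design$n_blocks), function(b) {
      cnt <- c(per_symbol, per_symbol)
      last <- 0L
      run <- 0L
      out <- character(design$trials_per_block)
      for (t in seq_len(design$trials_per_block)) {
        cand <- integer(0)
        for (s in 1:2) {
          if (cnt[s] == 0L) next
          l_new <- if (s == last) run + 1L else 1L
          if (l_new > m) next
          o <- 3L - s
          if (.can_finish(cnt[s] - 1L, cnt[o], l_new, m)) cand <- c(cand, s)
        }
        if (length(cand) == 0L) {
          stop("sequence generation dead-ended; constraint infeasible", call. = FALSE)
        }
        s <- if (length(cand) == 1L) cand else {
          cand[sample.int(length(cand), 1L, prob = cnt[cand])]
        }
        run <- if (s == last) run + 1L else 1L
        last <- s
        cnt[s] <- cnt[s] - 1L
        out[t] <- labels[s]
      }
      out
    })
  })
}

#' Sample the monetary outcome of one valid trial
#'
#' The movement direction (approach if `raw_distance > 0`, avoid
#' otherwise; an exact zero counts as avoidance, since approach is defined
#' strictly as a positive distance) selects the reward probability from
#' the design's schedule; the outcome is a Bernoulli draw on the current
#' RNG stream.
#'
#' @param design an [task_design()] object.
#' @param symbol `"ingroup"` or `"outgroup"`.
#' @param raw_distance signed movement as a line fraction; must be a valid
#'   trial (`NA` distances are rejected — outcomes are undefined for
#'   invalid trials).
#' @return a list with `outcome_r` (1 reward, 0 punishment) and
#'   `outcome_eur` (signed EUR amount).
#' @export
sample_outcome <- function(design, symbol, raw_distance) {
  stopifnot(inherits(design, "aal_design"))
  symbol <- match.arg(symbol, c("ingroup", "outgroup"))
  if (is.na(raw_distance)) {
    stop("outcome undefined for invalid trial (missing distance)", call. = FALSE)
  }
  direction <- if (raw_distance > 0) "approach" else "avoid"
  p <- design$reward_schedule[symbol, direction]
  r <- as.integer(runif(1) < p)
  list(
    outcome_r = r,
    outcome_eur = if (r == 1L) design$outcome_magnitude else -design$outcome_magnitude
  )
}

#' Normalise a signed distance to the unit interval
#'
#' Maps the raw signed distance (line fraction moved towards the symbol)
#' affinely onto `[0, 1]`: `(raw + D) / (2 D)` with
#' `D = design$max_excursion`, so that 0.5 means no movement, 1 the
#' largest approach and 0 the largest avoidance.
#'
#' @param raw_distance signed distance(s), `|raw| <= D`.
#' @param design an [task_design()] object.
#' @return value(s) in `[0, 1]`.
#' @examples
#' normalize_distance(-0.3, task_design("social_conflict")) # 0.25
#' @export
normalize_distance <- function(raw_distance, design) {
  stopifnot(inherits(design, "aal_design"))
  D <- design$max_excursion
  bad <- abs(raw_distance) > D + 1e-12
  if (any(bad, na.rm = TRUE)) {
    stop("|raw_distance| exceeds max_excursion D = ", D, call. = FALSE)
  }
  (raw_distance + D) / (2 * D)
}

#' Orient a normalised distance onto the reward dimension
#'
#' For the in-group symbol (symbol 1 in the non-social arm) the normalised
#' distance is inverted (`1 - x`), so that for both symbols larger oriented
#' values point along the direction rewarded with high probability in the
#' 80/20 arms. The map is an involution on in-group values and the
#' identity for out-group values.
#'
#' @param unit_value value(s) in `[0, 1]`.
#' @param symbol `"ingroup"` or `"outgroup"` (recycled against
#'   `unit_value`).
#' @return oriented value(s) in `[0, 1]`.
#' @export
orient_value <- function(unit_value, symbol) {
  if (any(unit_value < -1e-12 | unit_value > 1 + 1e-12, na.rm = TRUE)) {
    stop("unit_value must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(unit_value), length(symbol))
  u <- rep_len(unit_value, n)
  s <- rep_len(symbol, n)
  u[s == "ingroup"] <- 1 - u[s == "ingroup"]
  u
}

#' Convert an oriented value back to a raw signed distance
#'
#' Inverse of `normalize_distance` composed with [orient_value()]; used by
#' the simulator to turn a model response on the oriented `[0, 1]` scale
#' back into a signed movement.
#'
#' @inheritParams orient_value
#' @param design an [task_design()] object.
#' @return signed distance(s) in `[-D, D]`.
#' @export
oriented_to_raw <- function(unit_value, symbol, design) {
  stopifnot(inherits(design, "aal_design"))
  u <- orient_value(unit_value, symbol) # involution undoes the inversion
  D <- design$max_excursion
  u * 2 * D - D
}

#' Maximum achievable variable payout
#'
#' The ceiling of the performance-dependent compensation: a reward on
#' every trial plus the retained endowment of the one-shot dictator game
#' played after the task (default 1 EUR).
#'
#' @param design an [task_design()] object.
#' @param dictator_endowment endowment of the post-task dictator game in
#'   EUR (default 1).
#' @return scalar EUR amount.
#' @examples
#' max_variable_payout(task_design("social_conflict")) # 7
#' @export
max_variable_payout <- function(design, dictator_endowment = 1) {
  stopifnot(inherits(design, "aal_design"))
  design$n_blocks * design$trials_per_block * design$outcome_magnitude +
    dictator_endowment
}

#' Apply the invalid-trial exclusion rule
#'
#' A participant is excluded when any block x symbol cell contains more
#' than one invalid (no-movement) trial — i.e. more than 5\% of the 20
#' trials of that cell under the default design.
#'
#' @param trials a trial table (as produced by [simulate_cohort()] or
#'   [load_trials()]) with columns `participant_id`, `block`, `symbol`,
#'   `valid`.
#' @return a tibble with one row per participant: `participant_id`,
#'   `keep` (logical) and `reasons` (character; semicolon-separated
#'   offending cells, `""` when kept).
#' @export
apply_exclusion <- function(trials) {
  required <- c("participant_id", "block", "symbol", "valid")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  cells <- trials |>
    dplyr::group_by(.data$participant_id, .data$block, .data$symbol) |>
    dplyr::summarise(n_invalid = sum(!.data$valid), .groups = "drop")
  cells |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      keep = all(.data$n_invalid <= 1L),
      reasons = paste(
        sprintf(
          "block %d/%s: %d invalid",
          .data$block[.data$n_invalid > 1L],
          .data$symbol[.data$n_invalid > 1L],
          .data$n_invalid[.data$n_invalid > 1L]
        ),
        collapse = "; "
      ),
      .groups = "drop"
    )
}

#' Drop excluded participants from a trial table
#'
#' @inheritParams apply_exclusion
#' @return the trial table restricted to participants passing
#'   [apply_exclusion()].
#' @export
exclude_participants <- function(trials) {
  keep <- apply_exclusion(trials)
  dplyr::semi_join(
    trials,
    dplyr::filter(keep, .data$keep),
    by = "participant_id"
  )
}
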