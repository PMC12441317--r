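test_that("arm schedules encode the study contrasts", {
  conflict <- task_design("social_conflict")
  expect_equal(conflict$reward_schedule["outgroup", "approach"], 0.8)
  expect_equal(conflict$reward_schedule["ingroup", "approach"], 0.2)
  expect_equal(unname(rowSums(conflict$reward_schedule)), c(1, 1))

  control <- task_design("social_control")
  expect_true(all(control$reward_schedule == 0.5))

  nonsocial <- task_design("nonsocial_control")
  expect_identical(nonsocial$reward_schedule, conflict$reward_schedule)
})

test_that("malformed designs are rejected", {
  expect_error(task_design("social_conflict", trials_per_block = 41), "even")
  expect_error(task_design("social_conflict", max_run = 0), "max_run")
  bad <- matrix(c(0.2, 0.8, 0.9, 0.2), 2, 2,
    dimnames = list(c("ingroup", "outgroup"), c("approach", "avoid"))
  )
  expect_error(task_design("social_conflict", reward_schedule = bad), "sum|= 1")
  allhalf <- matrix(0.4, 2, 2,
    dimnames = list(c("ingroup", "outgroup"), c("approach", "avoid"))
  )
  expect_error(task_design("social_control", reward_schedule = allhalf), "0.5")
})

test_that("trial sequences respect counts and the run-length constraint", {
  d <- task_design("social_conflict")
  for (seed in 1:25) {
    seqs <- build_trial_sequence(d, seed)
    expect_length(seqs, d$n_blocks)
    for (b in seqs) {
      expect_length(b, 40L)
      expect_equal(as.integer(table(b)), c(20L, 20L))
      expect_lte(max(rle(b)$lengths), d$max_run)
    }
  }
})

test_that("identical seeds give identical sequences; max_run = 1 alternates", {
  d <- task_design("social_conflict")
  expect_identical(build_trial_sequence(d, 7), build_trial_sequence(d, 7))
  expect_false(identical(build_trial_sequence(d, 7), build_trial_sequence(d, 8)))

  d1 <- task_design("social_conflict", max_run = 1)
  seqs <- build_trial_sequence(d1, 3)
  for (b in seqs) expect_equal(max(rle(b)$lengths), 1L)
})

test_that("empirical reward rates match the schedule", {
  draws <- function(design, symbol, raw, n, seed) {
    withr::with_seed(seed, {
      mean(vapply(
        seq_len(n),
        function(i) sample_outcome(design, symbol, raw)$outcome_r,
        integer(1)
      ))
    })
  }
  n <- 5000
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  conflict <- task_design("social_conflict")
  expect_lt(abs(draws(conflict, "outgroup", 0.3, n, 1) - 0.80), se3(0.8))
  expect_lt(abs(draws(conflict, "ingroup", 0.3, n, 2) - 0.20), se3(0.2))
  expect_lt(abs(draws(conflict, "outgroup", -0.3, n, 3) - 0.20), se3(0.2))
  control <- task_design("social_control")
  expect_lt(abs(draws(control, "ingroup", 0.3, n, 4) - 0.50), se3(0.5))
})

test_that("outcomes carry the right sign and invalid trials are rejected", {
  d <- task_design("social_conflict")
  out <- withr::with_seed(1, sample_outcome(d, "outgroup", 0.2))
  expect_true(out$outcome_r %in% c(0L, 1L))
  expect_equal(out$outcome_eur, ifelse(out$outcome_r == 1, 0.05, -0.05))
  expect_error(sample_outcome(d, "outgroup", NA_real_), "invalid")
})

test_that("distance normalisation is the documented affine map", {
  d <- task_design("social_conflict")
  expect_equal(normalize_distance(0, d), 0.5)
  expect_equal(normalize_distance(0.6, d), 1)
  expect_equal(normalize_distance(-0.6, d), 0)
  expect_equal(normalize_distance(-0.3, d), 0.25)
  expect_error(normalize_distance(0.61, d), "max_excursion")
})

test_that("orientation inverts in-group values and is an involution", {
  expect_equal(orient_value(0.8, "ingroup"), 0.2)
  expect_equal(orient_value(0.5, "ingroup"), 0.5)
  expect_equal(orient_value(0.8, "outgroup"), 0.8)
  u <- seq(0, 1, by = 0.05)
  expect_equal(orient_value(orient_value(u, "ingroup"), "ingroup"), u)
  expect_error(orient_value(1.2, "outgroup"), "0, 1")
})

test_that("normalise-then-orient maps [-D, D] bijectively onto [0, 1]", {
  d <- task_design("social_conflict")
  raw <- seq(-d$max_excursion, d$max_excursion, length.out = 41)
  for (s in c("ingroup", "outgroup")) {
    y <- orient_value(normalize_distance(raw, d), s)
    expect_true(all(y >= 0 & y <= 1))
    expect_equal(sort(y), seq(0, 1, length.out = 41))
    # round trip back to raw
    expect_equal(oriented_to_raw(y, s, d), raw)
  }
})

test_that("exclusion drops only participants with >1 invalid trial per cell", {
  base <- expand.grid(
    block = 1:3, symbol = c("ingroup", "outgroup"),
    rep = 1:20, stringsAsFactors = FALSE
  )
  mk <- function(id, invalid_idx) {
    tibble::tibble(
      participant_id = id, block = base$block, symbol = base$symbol,
      valid = !(seq_len(nrow(base)) %in% invalid_idx)
    )
  }
  # two invalid trials in block 1 / ingroup
  two_in_one_cell <- which(base$block == 1 & base$symbol == "ingroup")[1:2]
  # exactly one invalid trial in every block x symbol cell
  one_everywhere <- vapply(
    split(seq_len(nrow(base)), paste(base$block, base$symbol)),
    `[`, integer(1), 1
  )
  trials <- dplyr::bind_rows(
    mk("dropped", two_in_one_cell),
    mk("kept_borderline", one_everywhere),
    mk("kept_clean", integer(0))
  )
  res <- apply_exclusion(trials)
  expect_false(res$keep[res$participant_id == "dropped"])
  expect_match(res$reasons[res$participant_id == "dropped"], "block 1/ingroup")
  expect_true(res$keep[res$participant_id == "kept_borderline"])
  expect_true(res$keep[res$participant_id == "kept_clean"])
  expect_setequal(
    unique(exclude_participants(trials)$participant_id),
    c("kept_borderline", "kept_clean")
  )
  expect_error(apply_exclusion(trials[, c("block", "symbol")]), "lacks column")
})

test_that("the payout ceiling follows from the design", {
  expect_equal(max_variable_payout(task_design("social_conflict")), 7)
})
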