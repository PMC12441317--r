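test_that("bic matches independent arithmetic and is monotone", {
  expect_equal(bic(1.2, 120, 5), 120 * log(0.01) + 5 * log(120))
  expect_equal(bic(100, 100, 3), 3 * log(100)) # ln(SSE/n) = 0
  expect_equal(bic(0.6, 60, 3), 60 * log(0.01) + 3 * log(60))
  expect_error(bic(0, 100, 3), "sse")
  expect_error(bic(1, 0, 3), ">= 1")

  cases <- withr::with_seed(1, tibble::tibble(
    sse = runif(200, 0.01, 50),
    n = sample(10:500, 200, replace = TRUE),
    k = sample(1:9, 200, replace = TRUE)
  ))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      # oracle written as an algebraically different expansion
      oracle <- n * (log(sse) - log(n)) + k * log(n)
      expect_lt(abs(bic(sse, n, k) - oracle), 1e-9)
      expect_gt(bic(sse * 1.1, n, k), bic(sse, n, k))
      expect_gt(bic(sse, n, k + 1), bic(sse, n, k))
    })
  }
})

test_that("r_squared matches hand arithmetic and guards its domain", {
  y <- c(0.2, 0.4, 0.6)
  expect_equal(r_squared(predictions = y, observations = y), 1)
  expect_equal(r_squared(predictions = rep(mean(y), 3), observations = y), 0)
  expect_equal(r_squared(predictions = c(0.3, 0.4, 0.5), observations = y), 0.75)
  expect_error(r_squared(predictions = c(1, 2), observations = rep(0.5, 2)), "variance")
  expect_error(r_squared(predictions = 1, observations = 1), "length|>= 2")
})

test_that("model comparison selects the lowest summed BIC, ties by parsimony", {
  mk_fits <- function(bics_by_model, r2 = 0.2) {
    rows <- list()
    for (m in seq_along(bics_by_model)) {
      for (p in seq_along(bics_by_model[[m]])) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant_id = paste0("p", p), model_id = m,
          bic = bics_by_model[[m]][p], r2 = r2, failed = FALSE
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  cmp <- compare_models(mk_fits(list(c(-40, -60), c(-50, -70))))
  expect_equal(attr(cmp, "winner"), 2L)
  expect_equal(cmp$sum_bic, c(-100, -120))

  # equal summed BIC: the model with fewer parameters wins
  tie <- compare_models(mk_fits(list(c(-50, -50), c(-50, -50))))
  expect_equal(attr(cmp, "winner"), 2L)
  expect_equal(attr(tie, "winner"), 1L)

  # participants with failed cells are dropped listwise and counted
  fits <- mk_fits(list(c(-40, -60), c(-50, -70)))
  fits$failed[fits$participant_id == "p1" & fits$model_id == 1] <- TRUE
  cmp2 <- compare_models(fits)
  expect_equal(attr(cmp2, "n_dropped"), 1L)
  expect_equal(cmp2$n_participants, c(1L, 1L))

  ragged <- mk_fits(list(c(-40, -60), c(-50, -70)))[-1, ]
  expect_error(compare_models(ragged), "ragged")
})

test_that("welch_t reproduces the Welch-Satterthwaite formulas", {
  res <- welch_t(c(0.3, 0.5, 0.7), c(0.1, 0.2, 0.3))
  # independent hand evaluation
  va <- 0.04 / 3
  vb <- 0.01 / 3
  t_hand <- (0.5 - 0.2) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$t, 2.3238, tolerance = 1e-4)
  expect_equal(res$df, 2.941, tolerance = 1e-3)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)

  # equal variances and n: Welch t equals the pooled-variance t
  a <- withr::with_seed(2, rnorm(20))
  b <- withr::with_seed(3, rnorm(20))
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(welch_t(a, b)$t, unname(pooled$statistic), tolerance = 1e-10)

  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "variance")
})

test_that("paired-t sample size reproduces the planning analysis", {
  expect_equal(required_sample_size_paired_t(0.444, 0.05, 0.80), 42L)
  expect_equal(required_sample_size_paired_t(1.0, 0.05, 0.80), 10L)
  # monotone: easier detection -> fewer participants
  expect_gte(
    required_sample_size_paired_t(0.3, 0.05, 0.8),
    required_sample_size_paired_t(0.5, 0.05, 0.8)
  )
  expect_gte(
    required_sample_size_paired_t(0.444, 0.01, 0.8),
    required_sample_size_paired_t(0.444, 0.05, 0.8)
  )
  expect_gte(
    required_sample_size_paired_t(0.444, 0.05, 0.9),
    required_sample_size_paired_t(0.444, 0.05, 0.8)
  )
  # the floor: vanishing power demands the minimum admissible n
  expect_equal(required_sample_size_paired_t(0.444, 0.05, 1e-6), 2L)
  expect_error(required_sample_size_paired_t(-0.1), "d must be > 0")
})

test_that("per-symbol slopes capture monotone trends and flag sparse cells", {
  inc <- make_trials(seq(0.1, 0.9, length.out = 9), rep(1L, 9), symbol = "outgroup")
  inc$raw_distance <- seq(-0.4, 0.4, length.out = 9)
  flat <- make_trials(rep(0.5, 9), rep(1L, 9), symbol = "ingroup")
  flat$trial <- flat$trial + 9L
  res <- per_symbol_slopes(dplyr::bind_rows(inc, flat))
  s <- res$slopes
  expect_gt(s$slope[s$symbol == "outgroup"], 0)
  expect_equal(s$slope[s$symbol == "ingroup"], 0)

  sparse <- make_trials(0.5, 1L, symbol = "ingroup")
  res2 <- per_symbol_slopes(dplyr::bind_rows(inc, sparse))
  expect_true(is.na(res2$slopes$slope[res2$slopes$symbol == "ingroup"]))
})
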