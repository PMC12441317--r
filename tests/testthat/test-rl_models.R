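test_that("the model space has the documented parameter counts", {
  expect_equal(vapply(1:6, param_count, integer(1)), c(3L, 4L, 5L, 5L, 5L, 7L))
  expect_error(param_count(7), "1..6")
  expect_error(model_spec(0), "1..6")
})

test_that("prediction error is outcome minus carried value", {
  expect_equal(prediction_error(1, 0.7), 0.3)
  expect_equal(prediction_error(0, 0.7), -0.7)
  expect_equal(prediction_error(1, 1), 0)
  expect_equal(prediction_error(0, 0), 0)
})

test_that("teacher-forced predictions reproduce hand-evaluated updates", {
  tr <- make_trials(y = c(0.6, 0.5), r = c(1L, 0L))

  p2 <- predict_series(2, c(alpha = 0.4, beta = 0.8, v1_in = 0.5, v1_out = 0.5), tr)
  expect_equal(p2$prediction, c(0.5, 0.608)) # (0.6 + 0.4*0.4)*0.8
  expect_equal(p2$delta[1], 0.4) # r - observed y
  expect_equal(sse(p2), 0.021664)

  p1 <- predict_series(1, c(alpha = 0.4, v1_in = 0.5, v1_out = 0.5), tr)
  expect_equal(p1$prediction[2], 0.76) # no response scaling

  # negative-valence branch with the conflict-arm mean parameters
  tr5 <- make_trials(y = c(0.8, 0.5), r = c(0L, 1L))
  p5 <- predict_series(
    5,
    c(alpha_pos = 0.38, alpha_neg = 0.01, beta = 0.67, v1_in = 0.5, v1_out = 0.5),
    tr5
  )
  expect_equal(p5$prediction[2], (0.8 + 0.01 * (-0.8)) * 0.67) # 0.53064
})

test_that("sse sums squared residuals and rejects empty traces", {
  trace <- tibble::tibble(residual = c(0.1, -0.2))
  expect_equal(sse(trace), 0.05)
  expect_equal(sse(tibble::tibble(y = c(0.2, 0.4), prediction = c(0.2, 0.4))), 0)
  expect_error(sse(tibble::tibble(residual = numeric(0))), "empty")
})

test_that("richer models collapse exactly onto their nested special cases", {
  for (seed in 1:20) {
    tr <- random_trials(n_per_symbol = 10, seed = seed)
    v1 <- withr::with_seed(seed + 100, runif(2))
    al <- withr::with_seed(seed + 200, runif(1))
    be <- withr::with_seed(seed + 300, runif(1))
    for (mode in c("teacher_forced", "latent")) {
      ref1 <- predict_series(1, c(alpha = al, v1_in = v1[1], v1_out = v1[2]),
        tr,
        mode = mode
      )
      ref2 <- predict_series(
        2, c(alpha = al, beta = be, v1_in = v1[1], v1_out = v1[2]),
        tr,
        mode = mode
      )
      p2_as_1 <- predict_series(
        2, c(alpha = al, beta = 1, v1_in = v1[1], v1_out = v1[2]),
        tr,
        mode = mode
      )
      p3 <- predict_series(
        3, c(alpha = al, beta_in = be, beta_out = be, v1_in = v1[1], v1_out = v1[2]),
        tr,
        mode = mode
      )
      p4 <- predict_series(
        4, c(alpha_in = al, alpha_out = al, beta = be, v1_in = v1[1], v1_out = v1[2]),
        tr,
        mode = mode
      )
      p5 <- predict_series(
        5, c(alpha_pos = al, alpha_neg = al, beta = be, v1_in = v1[1], v1_out = v1[2]),
        tr,
        mode = mode
      )
      p6 <- predict_series(
        6,
        c(
          alpha_pos_in = al, alpha_pos_out = al, alpha_neg_in = al,
          alpha_neg_out = al, beta = be, v1_in = v1[1], v1_out = v1[2]
        ),
        tr,
        mode = mode
      )
      expect_lt(max(abs(p2_as_1$prediction - ref1$prediction)), 1e-12)
      for (p in list(p3, p4, p5, p6)) {
        expect_lt(max(abs(p$prediction - ref2$prediction)), 1e-12)
      }
    }
  }
})

test_that("predictions stay in [0, 1] for bounded parameters and data", {
  for (seed in 1:15) {
    tr <- random_trials(n_per_symbol = 12, seed = seed)
    for (m in 1:6) {
      pars <- random_params(m, seed = seed * 10 + m)
      for (mode in c("teacher_forced", "latent")) {
        trace <- predict_series(m, pars, tr, mode = mode)
        expect_true(all(trace$prediction >= 0 & trace$prediction <= 1))
        expect_true(all(trace$delta >= -1 & trace$delta <= 1))
      }
    }
  }
})

test_that("alpha = 0, beta = 1 makes prediction equal the previous response", {
  tr <- random_trials(n_per_symbol = 8, seed = 5)
  p <- predict_series(2, c(alpha = 0, beta = 1, v1_in = 0.5, v1_out = 0.5), tr)
  for (s in c("ingroup", "outgroup")) {
    ps <- p[p$symbol == s, ]
    expect_equal(ps$prediction[-1], ps$y[-nrow(ps)])
  }
})

test_that("latent-mode traces agree with an independent recomputation", {
  # brute-force oracle: literal step-by-step evaluation of the update rule
  oracle <- function(tr, a_pos, a_neg, beta, v1) {
    pred <- numeric(nrow(tr))
    for (s in c("ingroup", "outgroup")) {
      idx <- which(tr$symbol == s)
      v <- v1[[s]]
      for (j in seq_along(idx)) {
        pred[idx[j]] <- v
        r <- tr$outcome_r[idx[j]]
        delta <- r - v
        a <- if (delta >= 0) a_pos else a_neg
        v <- (v + a * delta) * beta
      }
    }
    pred
  }
  for (seed in 1:10) {
    tr <- random_trials(n_per_symbol = 10, seed = seed)
    pars <- random_params(5, seed = seed + 50)
    got <- predict_series(5, pars, tr, mode = "latent")
    want <- oracle(
      tr, pars[["alpha_pos"]], pars[["alpha_neg"]], pars[["beta"]],
      list(ingroup = pars[["v1_in"]], outgroup = pars[["v1_out"]])
    )
    expect_lt(max(abs(got$prediction[order(got$trial)] - want)), 1e-12)
  }
})

test_that("mismatched parameters and unsorted trials are rejected", {
  tr <- make_trials(y = c(0.6, 0.5), r = c(1L, 0L))
  expect_error(
    predict_series(2, c(alpha = 0.4, v1_in = 0.5, v1_out = 0.5), tr),
    "parameter names"
  )
  expect_error(
    predict_series(1, c(alpha = 1.4, v1_in = 0.5, v1_out = 0.5), tr),
    "bounds"
  )
  shuffled <- tr[2:1, ]
  expect_error(
    predict_series(1, c(alpha = 0.4, v1_in = 0.5, v1_out = 0.5), shuffled),
    "ordered"
  )
})
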