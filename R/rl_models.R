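#' The six-model Rescorla-Wagner space
#'
#' All models predict the oriented normalised distance `V` on each
#' encounter with a symbol from the outcome history of that symbol, via
#' the delta rule `V(t) = V(t-1) + alpha * (r(t) - V(t-1))`, optionally
#' scaled by a response parameter `beta` that captures how faithfully the
#' latent value is translated into the emitted distance. Every model
#' carries two free initial values `v1_in` and `v1_out`, one per symbol,
#' encoding a prior approach bias.
#'
#' \tabular{lll}{
#'   id \tab free parameters \tab K \cr
#'   1 \tab `alpha, v1_in, v1_out` \tab 3 \cr
#'   2 \tab `alpha, beta, v1_in, v1_out` \tab 4 \cr
#'   3 \tab `alpha, beta_in, beta_out, v1_in, v1_out` \tab 5 \cr
#'   4 \tab `alpha_in, alpha_out, beta, v1_in, v1_out` \tab 5 \cr
#'   5 \tab `alpha_pos, alpha_neg, beta, v1_in, v1_out` \tab 5 \cr
#'   6 \tab `alpha_pos_in, alpha_pos_out, alpha_neg_in, alpha_neg_out,
#'           beta, v1_in, v1_out` \tab 7
#' }
#'
#' Model 5 splits the learning rate by the sign of the prediction error
#' (`alpha_pos` for `delta >= 0`, `alpha_neg` for `delta < 0`); model 6
#' additionally splits it by symbol. All parameters are bounded to
#' `[0, 1]`.
#'
#' @param model_id integer in 1..6.
#' @return for `model_spec()`, a list with `model_id`, `par_names`,
#'   `lower`, `upper` and `k`; for `param_count()`, the integer number of
#'   free parameters K.
#' @examples
#' param_count(5) # 5
#' model_spec(6)$par_names
#' @export
model_spec <- function(model_id) {
  model_id <- as.integer(model_id)
  if (length(model_id) != 1L || is.na(model_id) || model_id < 1L || model_id > 6L) {
    stop("model_id must be a single integer in 1..6", call. = FALSE)
  }
  par_names <- switch(model_id,
    c("alpha", "v1_in", "v1_out"),
    c("alpha", "beta", "v1_in", "v1_out"),
    c("alpha", "beta_in", "beta_out", "v1_in", "v1_out"),
    c("alpha_in", "alpha_out", "beta", "v1_in", "v1_out"),
    c("alpha_pos", "alpha_neg", "beta", "v1_in", "v1_out"),
    c(
      "alpha_pos_in", "alpha_pos_out", "alpha_neg_in", "alpha_neg_out",
      "beta", "v1_in", "v1_out"
    )
  )
  k <- length(par_names)
  list(
    model_id = model_id,
    par_names = par_names,
    lower = stats::setNames(rep(0, k), par_names),
    upper = stats::setNames(rep(1, k), par_names),
    k = k
  )
}

#' @rdname model_spec
#' @export
param_count <- function(model_id) {
  model_spec(model_id)$k
}

#' Rescorla-Wagner prediction error
#'
#' `delta = r - v`: the discrepancy between the received binary outcome
#' and the value it was compared against.
#'
#' @param outcome_r binary outcome(s), 1 reward / 0 punishment.
#' @param prev_value value(s) in `[0, 1]`.
#' @return prediction error(s) in `[-1, 1]`.
#' @export
prediction_error <- function(outcome_r, prev_value) {
  stopifnot(all(outcome_r %in% c(0, 1)), all(prev_value >= 0 & prev_value <= 1))
  outcome_r - prev_value
}

# expand a named parameter vector of any model into the per-symbol
# internal form (alpha_pos_s, alpha_neg_s, beta_s, v1_s); every model is a
# constrained special case of model 6 with a response weight
.expand_params <- function(model_id, params) {
  spec <- model_spec(model_id)
  if (!setequal(names(params), spec$par_names)) {
    stop(
      "parameter names do not match model ", model_id, "; expected: ",
      paste(spec$par_names, collapse = ", "),
      call. = FALSE
    )
  }
  p <- params[spec$par_names]
  if (any(p < spec$lower - 1e-12 | p > spec$upper + 1e-12)) {
    stop("parameter(s) outside [0, 1] bounds", call. = FALSE)
  }
  g <- function(a_pos_in, a_pos_out, a_neg_in, a_neg_out, b_in, b_out) {
    list(
      alpha_pos = c(ingroup = unname(a_pos_in), outgroup = unname(a_pos_out)),
      alpha_neg = c(ingroup = unname(a_neg_in), outgroup = unname(a_neg_out)),
      beta = c(ingroup = unname(b_in), outgroup = unname(b_out)),
      v1 = c(ingroup = unname(p["v1_in"]), outgroup = unname(p["v1_out"]))
    )
  }
  switch(model_id,
    g(p["alpha"], p["alpha"], p["alpha"], p["alpha"], 1, 1),
    g(p["alpha"], p["alpha"], p["alpha"], p["alpha"], p["beta"], p["beta"]),
    g(p["alpha"], p["alpha"], p["alpha"], p["alpha"], p["beta_in"], p["beta_out"]),
    g(p["alpha_in"], p["alpha_out"], p["alpha_in"], p["alpha_out"], p["beta"], p["beta"]),
    g(p["alpha_pos"], p["alpha_pos"], p["alpha_neg"], p["alpha_neg"], p["beta"], p["beta"]),
    g(
      p["alpha_pos_in"], p["alpha_pos_out"], p["alpha_neg_in"], p["alpha_neg_out"],
      p["beta"], p["beta"]
    )
  )
}

# one-symbol prediction series. y, r: observed oriented responses and
# outcomes in encounter order. The value updated with encounter k's
# outcome becomes the prediction for encounter k+1; delta >= 0 selects the
# positive-valence learning rate.
.predict_symbol <- function(y, r, a_pos, a_neg, beta, v1, mode) {
  n <- length(y)
  pred <- numeric(n)
  pred[1] <- v1
  if (n == 1L) {
    return(list(pred = pred, delta = r[1] - (if (mode == "teacher_forced") y[1] else pred[1])))
  }
  if (mode == "teacher_forced") {
    # carried value is the observed previous response: fully vectorised
    delta <- r - y
    alpha <- ifelse(delta >= 0, a_pos, a_neg)
    pred[2:n] <- (y[1:(n - 1)] + alpha[1:(n - 1)] * delta[1:(n - 1)]) * beta
  } else {
    delta <- numeric(n)
    delta[1] <- r[1] - pred[1]
    for (k in 2:n) {
      a <- if (delta[k - 1] >= 0) a_pos else a_neg
      pred[k] <- (pred[k - 1] + a * delta[k - 1]) * beta
      delta[k] <- r[k] - pred[k]
    }
  }
  list(pred = pred, delta = delta)
}

#' Per-trial model predictions for one participant
#'
#' Computes the prediction trace of a model over the valid trials of a
#' single participant. In `teacher_forced` mode (the fitting default) the
#' value carried into each update is the participant's observed previous
#' oriented response for that symbol; in `latent` mode it is the model's
#' own previous prediction. The prediction for the first encounter with a
#' symbol is its initial value `v1` (not scaled by `beta`), and its
#' residual counts towards the SSE.
#'
#' @param model_id integer 1..6, see [model_spec()].
#' @param params named numeric vector with exactly the model's parameter
#'   names.
#' @param trials tibble of one participant's trials with columns `trial`,
#'   `symbol`, `y_value`, `outcome_r`, `valid` (invalid trials are
#'   skipped: no update, no residual). Must be in chronological order.
#' @param mode `"teacher_forced"` or `"latent"`.
#' @return a tibble (one row per valid trial, in order): `trial`,
#'   `symbol`, `encounter_k`, `y`, `outcome_r`, `prediction`, `delta`,
#'   `residual`.
#' @examples
#' tr <- tibble::tibble(
#'   trial = 1:2, symbol = "outgroup", y_value = c(0.6, 0.5),
#'   outcome_r = c(1, 0), valid = TRUE
#' )
#' predict_series(2, c(alpha = 0.4, beta = 0.8, v1_in = 0.5, v1_out = 0.5), tr)
#' @export
predict_series <- function(model_id, params, trials,
                           mode = c("teacher_forced", "latent")) {
  mode <- match.arg(mode)
  req <- c("trial", "symbol", "y_value", "outcome_r", "valid")
  missing <- setdiff(req, names(trials))
  if (length(missing)) {
    stop("trials lack column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(trials$trial, strictly = TRUE)) {
    stop("trials must be strictly ordered by trial index", call. = FALSE)
  }
  ex <- .expand_params(model_id, params)
  v <- trials[trials$valid, , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid trials", call. = FALSE)
  out <- vector("list", 2L)
  for (i in 1:2) {
    s <- c("ingroup", "outgroup")[i]
    vs <- v[v$symbol == s, , drop = FALSE]
    if (nrow(vs) == 0L) next
    tr <- .predict_symbol(
      vs$y_value, vs$outcome_r,
      ex$alpha_pos[[s]], ex$alpha_neg[[s]], ex$beta[[s]], ex$v1[[s]], mode
    )
    out[[i]] <- tibble::tibble(
      trial = vs$trial, symbol = s, encounter_k = seq_len(nrow(vs)),
      y = vs$y_value, outcome_r = vs$outcome_r,
      prediction = tr$pred, delta = tr$delta,
      residual = vs$y_value - tr$pred
    )
  }
  res <- dplyr::bind_rows(out)
  res[order(res$trial), , drop = FALSE]
}

#' Sum of squared errors of a prediction trace
#'
#' The fitting objective: the squared residuals between observed oriented
#' responses and model predictions, summed over all valid trials
#' (first encounters included).
#'
#' @param trace a tibble from [predict_series()] (needs columns `y` and
#'   `prediction`), or any data frame with a `residual` column.
#' @return non-negative scalar.
#' @export
sse <- function(trace) {
  if (NROW(trace) == 0L) stop("empty prediction trace", call. = FALSE)
  r <- if ("residual" %in% names(trace)) trace$residual else trace$y - trace$prediction
  sum(r^2)
}

# fast SSE used inside the optimiser: operates on pre-split per-symbol
# vectors to avoid data-frame overhead in the inner loop
.sse_fast <- function(model_id, params, split_data, mode) {
  ex <- .expand_params(model_id, params)
  total <- 0
  for (s in names(split_data)) {
    d <- split_data[[s]]
    tr <- .predict_symbol(d$y, d$r, ex$alpha_pos[[s]], ex$alpha_neg[[s]],
      ex$beta[[s]], ex$v1[[s]],
      mode = mode
    )
    total <- total + sum((d$y - tr$pred)^2)
  }
  total
}
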