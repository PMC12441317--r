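.all_param_names <- c(
  "alpha", "alpha_in", "alpha_out", "alpha_pos", "alpha_neg",
  "alpha_pos_in", "alpha_pos_out", "alpha_neg_in", "alpha_neg_out",
  "beta", "beta_in", "beta_out", "v1_in", "v1_out"
)

# split one participant's valid trials into per-symbol (y, r) vectors in
# encounter order; the representation the optimiser objective works on
.split_trials <- function(trials) {
  v <- trials[trials$valid & !is.na(trials$y_value), , drop = FALSE]
  v <- v[order(v$trial), , drop = FALSE]
  out <- list()
  for (s in c("ingroup", "outgroup")) {
    vs <- v[v$symbol == s, , drop = FALSE]
    if (nrow(vs)) out[[s]] <- list(y = vs$y_value, r = vs$outcome_r)
  }
  out
}

# one full sweep of 1-D refinements over each parameter; gradient-free
# fallback for starts where the quasi-Newton step fails
.coordinate_refine <- function(par, obj, lower, upper, sweeps = 3L) {
  for (sw in seq_len(sweeps)) {
    for (j in seq_along(par)) {
      f1 <- function(x) {
        p <- par
        p[j] <- x
        obj(p)
      }
      o <- optimize(f1, lower = lower[j], upper = upper[j], tol = 1e-8)
      if (o$objective < obj(par)) par[j] <- o$minimum
    }
  }
  par
}

#' Fit one model to one participant by multi-start SSE minimisation
#'
#' Minimises the sum of squared errors between the participant's oriented
#' responses and the model's predictions, using bound-constrained
#' quasi-Newton optimisation (`optim` method `"L-BFGS-B"`) restarted from
#' `n_starts` random start vectors drawn uniformly in `[0, 1]` per
#' parameter. The lowest-SSE solution is returned; ties within `1e-10`
#' are broken by the lowest start index so the result is deterministic
#' given the seed. Starts where the quasi-Newton step fails fall back to
#' a gradient-free coordinate refinement and are flagged.
#'
#' @param trials one participant's trial table (must have passed the
#'   exclusion rule; at least 2 valid trials per symbol).
#' @param model_id integer 1..6.
#' @param n_starts number of random restarts (default 10).
#' @param seed integer seed controlling the start values.
#' @param mode `"teacher_forced"` (default) or `"latent"`, see
#'   [predict_series()].
#' @return a one-row tibble: `participant_id`, `model_id`, one column per
#'   parameter in the six-model union (NA where not applicable), `sse`,
#'   `n_obs`, `bic` (`-Inf` sentinel for a numerically perfect fit),
#'   `r2`, `n_starts`, `best_start`, `converged`, `fallback`, `seed`.
#' @export
fit_participant <- function(trials, model_id, n_starts = 10L, seed = 1L,
                            mode = c("teacher_forced", "latent")) {
  mode <- match.arg(mode)
  spec <- model_spec(model_id)
  sd_ <- .split_trials(trials)
  n_per <- vapply(sd_, function(d) length(d$y), integer(1))
  if (length(sd_) < 2L || any(n_per < 2L)) {
    stop("need at least 2 valid trials per symbol to fit", call. = FALSE)
  }
  obj <- function(par) {
    names(par) <- spec$par_names
    .sse_fast(model_id, par, sd_, mode)
  }
  k <- spec$k
  # byrow: start i depends only on the first i*k draws, so the start set
  # for n_starts is a prefix of the set for any larger n_starts
  starts <- withr::with_seed(
    seed,
    matrix(runif(n_starts * k), ncol = k, byrow = TRUE)
  )

  res <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[i, ], obj,
        method = "L-BFGS-B",
        lower = rep(0, k), upper = rep(1, k)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      par <- .coordinate_refine(starts[i, ], obj, rep(0, k), rep(1, k))
      res[[i]] <- list(par = par, value = obj(par), converged = TRUE, fallback = TRUE)
    } else {
      res[[i]] <- list(
        par = fit$par, value = fit$value,
        converged = fit$convergence == 0L, fallback = FALSE
      )
    }
  }
  values <- vapply(res, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) {
    stop("all optimisation starts failed for model ", model_id, call. = FALSE)
  }
  best <- which(values <= min(values) + 1e-10)[1]
  est <- stats::setNames(res[[best]]$par, spec$par_names)

  v <- trials[trials$valid & !is.na(trials$y_value), , drop = FALSE]
  best_sse <- res[[best]]$value
  n_obs <- nrow(v)
  row <- tibble::tibble(
    participant_id = trials$participant_id[1],
    model_id = as.integer(model_id)
  )
  for (pn in .all_param_names) row[[pn]] <- unname(est[pn])[1]
  row$sse <- best_sse
  row$n_obs <- n_obs
  row$bic <- if (best_sse > 0) bic(best_sse, n_obs, spec$k) else -Inf
  row$r2 <- if (var(v$y_value) > 0) {
    r_squared(sse_val = best_sse, observations = v$y_value)
  } else {
    NA_real_
  }
  row$n_starts <- as.integer(n_starts)
  row$best_start <- as.integer(best)
  row$converged <- res[[best]]$converged
  row$fallback <- res[[best]]$fallback
  row$seed <- as.integer(seed)
  row$failed <- FALSE
  row$error <- NA_character_
  row
}

#' Extract the fitted parameter vector from a fit row
#'
#' @param fit a one-row tibble from [fit_participant()].
#' @return named numeric vector with the fitted model's parameters.
#' @export
fit_params <- function(fit) {
  stopifnot(nrow(fit) == 1L)
  pn <- model_spec(fit$model_id)$par_names
  stats::setNames(as.numeric(fit[1, pn]), pn)
}

#' Fit a set of models to every participant of a cohort
#'
#' Runs [fit_participant()] for each participant x model cell, with
#' per-cell seeds derived deterministically from the master seed.
#' Failures in individual cells are caught and returned as flagged rows
#' (`failed = TRUE` with the error message) rather than aborting the
#' cohort.
#'
#' @param trials cohort trial table (participants should have passed the
#'   exclusion rule; see [exclude_participants()]).
#' @param models integer vector of model ids (default `1:6`).
#' @param n_starts,mode passed to [fit_participant()].
#' @param seed master seed.
#' @param progress print one line per participant (default `FALSE`).
#' @return tibble of fit rows, one per participant x model.
#' @export
fit_cohort <- function(trials, models = 1:6, n_starts = 10L, seed = 1L,
                       mode = c("teacher_forced", "latent"),
                       progress = FALSE) {
  mode <- match.arg(mode)
  ids <- unique(trials$participant_id)
  out <- vector("list", length(ids) * length(models))
  idx <- 0L
  for (i in seq_along(ids)) {
    pt <- trials[trials$participant_id == ids[i], , drop = FALSE]
    if (progress) message("fitting participant ", ids[i])
    for (m in models) {
      idx <- idx + 1L
      cell_seed <- derive_seed(seed, i, m)
      out[[idx]] <- tryCatch(
        fit_participant(pt, m, n_starts = n_starts, seed = cell_seed, mode = mode),
        error = function(e) {
          row <- tibble::tibble(
            participant_id = ids[i], model_id = as.integer(m)
          )
          for (pn in .all_param_names) row[[pn]] <- NA_real_
          row$sse <- NA_real_
          row$n_obs <- NA_integer_
          row$bic <- NA_real_
          row$r2 <- NA_real_
          row$n_starts <- as.integer(n_starts)
          row$best_start <- NA_integer_
          row$converged <- NA
          row$fallback <- NA
          row$seed <- as.integer(cell_seed)
          row$failed <- TRUE
          row$error <- conditionMessage(e)
          row
        }
      )
    }
  }
  dplyr::bind_rows(out)
}
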