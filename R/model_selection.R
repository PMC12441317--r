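#' Bayesian information criterion for an SSE fit
#'
#' `BIC = n * ln(SSE / n) + k * ln(n)`, the Gaussian-residual form used to
#' penalise model complexity when fitting by least squares. Smaller is
#' better.
#'
#' @param sse sum of squared errors, strictly positive (a numerically
#'   perfect fit has no finite BIC on this scale).
#' @param n_obs number of observations, >= 1.
#' @param k number of free parameters, >= 1.
#' @return scalar BIC.
#' @examples
#' bic(1.2, 120, 5) # about -528.68
#' @export
bic <- function(sse, n_obs, k) {
  stopifnot(length(sse) == 1L, length(n_obs) == 1L, length(k) == 1L)
  if (is.na(sse) || sse <= 0) {
    stop("BIC undefined for sse <= 0 (perfect fit); handle as sentinel upstream",
      call. = FALSE
    )
  }
  if (n_obs < 1 || k < 1) stop("n_obs and k must be >= 1", call. = FALSE)
  n_obs * log(sse / n_obs) + k * log(n_obs)
}

#' Coefficient of determination of a fit
#'
#' `R^2 = 1 - SSE / SST`, with the total sum of squares taken about the
#' participant's mean oriented response. Accepts a prediction trace, a
#' pair of prediction/observation vectors, or a precomputed SSE plus the
#' observations.
#'
#' @param trace a tibble from [predict_series()].
#' @param predictions,observations numeric vectors (alternative input).
#' @param sse_val precomputed SSE (alternative input, with
#'   `observations`).
#' @return scalar `<= 1`.
#' @export
r_squared <- function(trace = NULL, predictions = NULL, observations = NULL,
                      sse_val = NULL) {
  if (!is.null(trace)) {
    observations <- trace$y
    sse_val <- sum((trace$y - trace$prediction)^2)
  } else if (!is.null(predictions)) {
    if (length(predictions) != length(observations)) {
      stop("predictions and observations must have equal length", call. = FALSE)
    }
    sse_val <- sum((observations - predictions)^2)
  }
  if (is.null(sse_val) || is.null(observations)) {
    stop("supply a trace, predictions + observations, or sse_val + observations",
      call. = FALSE
    )
  }
  if (length(observations) < 2L) stop("need >= 2 observations", call. = FALSE)
  sst <- sum((observations - mean(observations))^2)
  if (sst == 0) stop("observations have zero variance; R^2 undefined", call. = FALSE)
  1 - sse_val / sst
}

#' Compare fitted models by summed BIC
#'
#' Sums BIC per model over participants and averages per-participant
#' R-squared; the winner is the model with the smallest summed BIC, ties
#' broken by the smaller number of free parameters. Participants with any
#' failed cell among the compared models are dropped listwise (with a
#' count reported), so every model is summed over the same participants.
#'
#' @param fits a fit table from [fit_cohort()].
#' @return an object of class `aal_comparison`: a tibble with one row per
#'   model (`model_id`, `k`, `mean_r2`, `sum_bic`, `n_participants`,
#'   `winner`), with attributes `winner` (model id) and `n_dropped`.
#' @export
compare_models <- function(fits) {
  stopifnot(all(c("participant_id", "model_id", "bic", "r2", "failed") %in% names(fits)))
  models <- sort(unique(fits$model_id))
  bad <- unique(fits$participant_id[fits$failed | !is.finite(fits$bic)])
  ok <- fits[!(fits$participant_id %in% bad), , drop = FALSE]
  n_cells <- table(ok$participant_id)
  incomplete <- names(n_cells)[n_cells < length(models)]
  if (length(incomplete)) {
    stop("ragged fit table: participants missing model cells without failure flags: ",
      paste(head(incomplete, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(ok) == 0L) stop("no complete participants to compare", call. = FALSE)
  tab <- ok |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      k = param_count(.data$model_id[1]),
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      sum_bic = sum(.data$bic),
      n_participants = dplyr::n_distinct(.data$participant_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$model_id)
  ranked <- order(tab$sum_bic, tab$k, tab$model_id)
  winner <- tab$model_id[ranked[1]]
  tab$winner <- tab$model_id == winner
  structure(tab,
    class = c("aal_comparison", class(tab)),
    winner = winner, n_dropped = length(bad)
  )
}

#' @export
print.aal_comparison <- function(x, ...) {
  cat("Model comparison (summed BIC; lower is better)\n")
  NextMethod()
  cat(sprintf(
    "winner: model %d (%d participant(s) dropped for failed fits)\n",
    attr(x, "winner"), attr(x, "n_dropped")
  ))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value; thin wrapper around [stats::t.test()] returning
#' the three quantities of interest.
#'
#' @param sample_a,sample_b numeric vectors, each with at least 2 values;
#'   at least one must have positive variance.
#' @return a list with `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    stop("both samples have zero variance; Welch t undefined", call. = FALSE)
  }
  tt <- t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Required sample size for a paired-samples t-test
#'
#' Smallest `n` whose two-sided paired t-test at significance level
#' `alpha` reaches the target power for a standardised mean difference
#' `d` (the effect size on the difference scores), computed exactly from
#' the noncentral t distribution with `df = n - 1` and noncentrality
#' `d * sqrt(n)`.
#'
#' @param d effect size (dz), > 0.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param n_max search ceiling (default 1e6).
#' @return integer minimal sample size (>= 2).
#' @examples
#' required_sample_size_paired_t(0.444, 0.05, 0.80) # 42
#' @export
required_sample_size_paired_t <- function(d, alpha = 0.05, power = 0.80,
                                          n_max = 1e6) {
  if (d <= 0) stop("effect size d must be > 0", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  pwr <- function(n) {
    df <- n - 1
    tc <- qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  }
  n <- 2L
  while (pwr(n) < power) {
    n <- n + 1L
    if (n > n_max) stop("no n <= n_max reaches the target power", call. = FALSE)
  }
  n
}

#' Per-participant, per-symbol OLS slopes of distance over trials
#'
#' A lightweight descriptive of trial-by-trial change: for every
#' participant x symbol cell, the ordinary-least-squares slope (and
#' intercept) of the raw signed distance on the trial index over valid
#' trials; plus a group-level Welch t contrast of the slopes between the
#' two symbols.
#'
#' @param trials cohort trial table.
#' @return a list with `slopes` (tibble `participant_id`, `symbol`,
#'   `slope`, `intercept`, `n`) and `contrast` (Welch t of out-group vs
#'   in-group slopes; `NULL` when either side has fewer than 2 cells).
#' @export
per_symbol_slopes <- function(trials) {
  v <- trials[trials$valid & !is.na(trials$raw_distance), , drop = FALSE]
  slopes <- v |>
    dplyr::group_by(.data$participant_id, .data$symbol) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) {
        return(tibble::tibble(n = nrow(d), slope = NA_real_, intercept = NA_real_))
      }
      cf <- coef(lm(raw_distance ~ trial, data = d))
      tibble::tibble(n = nrow(d), slope = unname(cf[2]), intercept = unname(cf[1]))
    }) |>
    dplyr::ungroup()
  a <- slopes$slope[slopes$symbol == "outgroup" & !is.na(slopes$slope)]
  b <- slopes$slope[slopes$symbol == "ingroup" & !is.na(slopes$slope)]
  contrast <- if (length(a) >= 2L && length(b) >= 2L && (var(a) > 0 || var(b) > 0)) {
    welch_t(a, b)
  } else {
    NULL
  }
  list(slopes = slopes, contrast = contrast)
}
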