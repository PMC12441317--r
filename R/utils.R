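# internal helpers: seeding, truncated normals, clamping

#' Derive a child seed from a master seed
#'
#' Deterministically fans a master seed out to per-participant or per-fit
#' seeds so that a whole run is reproducible from a single integer while
#' sub-streams stay distinct.
#'
#' @param master integer master seed.
#' @param i,j non-negative integer stream indices (e.g. participant, model).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, i, j = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483629 # largest prime < 2^31
  s <- (abs(master) %% m)
  s <- (s * 48271 + i * 16807 + j * 69621 + 1) %% m
  as.integer(s %% 2147483645 + 1)
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# truncated-normal draws via inverse-CDF; used for population parameters
# bounded to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (sd == 0) {
    if (mean < lo || mean > hi) stop("point mass outside bounds", call. = FALSE)
    return(rep(mean, n))
  }
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  clamp(qnorm(u, mean, sd), lo, hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
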