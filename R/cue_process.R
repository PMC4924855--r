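#' Sample a weekly cue count
#'
#' Cues — social exposure, opportunity — arrive from many unrelated sources,
#' so the number encountered in a week is modelled as one Poisson draw with
#' intensity `lam`. The draw consumes the current R random stream, so results
#' are reproducible under `set.seed()`.
#'
#' @param lam expected cue count per week, >= 0
#' @param n number of weekly counts to draw (default 1)
#' @return integer vector of cue counts
#' @export
sample_cue_count <- function(lam, n = 1L) {
  if (any(lam < 0)) stop("'lam' must be nonnegative", call. = FALSE)
  stats::rpois(n, lam)
}

#' Cue contribution to weekly consumption
#'
#' Each cue event adds `q/7` (one seventh of the maximum weekly consumption)
#' to acting out, but the total cue contribution may not exceed `q (1 - V)`,
#' otherwise the weekly maximum `q` would be exceeded:
#' `f = min(R * q / 7, q * (1 - V))`.
#'
#' @param R cue count (nonnegative integer)
#' @param V vulnerability in \[0, 1\]
#' @param q maximum weekly consumption
#' @return cue-driven consumption in \[0, q (1 - V)\]
#' @export
cue_contribution <- function(R, V, q) {
  if (any(R < 0)) stop("'R' must be nonnegative", call. = FALSE)
  pmin(R * q / 7, q * (1 - V))
}

#' Total weekly consumption under cue forcing
#'
#' `A = q V + f(R; q)` with the cap above, so `A <= q` always; when `V = 1`
#' the deterministic part already saturates the week and cues add nothing.
#'
#' @param C craving
#' @param S effect of self-control
#' @param E external control parameter
#' @param R cue count
#' @param params a [model_params()] object
#' @return list with components `A` (consumption) and `V` (vulnerability)
#' @export
total_consumption <- function(C, S, E, R, params) {
  V <- vulnerability(C, S, E)
  A <- deterministic_consumption(V, params$q) + cue_contribution(R, V, params$q)
  list(A = A, V = V)
}
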