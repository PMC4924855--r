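#' Addiction vulnerability
#'
#' The clamped linear combination `V = min(1, max(0, C - S - E))`. Acting-out
#' intensity is proportional to `V`: craving raises it, the effect of
#' self-control and a protective environment (`E > 0`) lower it; peer pressure
#' enters as `E < 0`. Vectorized over its arguments.
#'
#' @param C craving
#' @param S effect of self-control
#' @param E external control parameter
#' @return vulnerability in \[0, 1\]
#' @export
#' @examples
#' vulnerability(0.5, 0, 0)   # 0.5
#' vulnerability(0, 0.5, 0)   # clamps to 0
vulnerability <- function(C, S, E) {
  pmin(1, pmax(0, C - S - E))
}

#' Deterministic weekly consumption
#'
#' In the cue-free model consumption is proportional to vulnerability,
#' `A = q V`, so it ranges from 0 to the weekly maximum `q`.
#'
#' @param V vulnerability in \[0, 1\]
#' @param q maximum weekly consumption
#' @return consumption in \[0, q\]
#' @export
deterministic_consumption <- function(V, q) {
  q * V
}

#' One-week craving update
#'
#' `C' = C + b * min(1, 1 - C) * A - d * C`: craving decays geometrically at
#' rate `d` when the behaviour is not acted out, and grows with consumption
#' `A` at an impact that shrinks linearly as craving approaches saturation.
#' For `C` in \[0, 1\], `A` in \[0, q\] and `b q < 1` the result stays in
#' \[0, 1\] — no clamping is applied.
#'
#' @param C craving in \[0, 1\]
#' @param A weekly consumption in \[0, q\]
#' @param params a [model_params()] object
#' @return next-week craving
#' @export
update_craving <- function(C, A, params) {
  C + params$b * pmin(1, 1 - C) * A - params$d * C
}

#' One-week self-control update
#'
#' `S' = S + p * max(0, S_plus - S) - h C - k A`: the self-control resource
#' restores toward its ceiling `S_plus` proportionally to the left-over
#' capacity (resilience `p`), and is depleted by craving and by acting out.
#' The restoration term vanishes when `S >= S_plus`; `S` may go negative
#' under sustained depletion.
#'
#' @param S effect of self-control
#' @param C craving in \[0, 1\]
#' @param A weekly consumption in \[0, q\]
#' @param params a [model_params()] object
#' @return next-week effect of self-control
#' @export
update_selfcontrol <- function(S, C, A, params) {
  S + params$p * pmax(0, params$S_plus - S) - params$h * C - params$k * A
}

#' Construct a weekly system state
#'
#' @param t week index (nonnegative integer)
#' @param C craving in \[0, 1\]
#' @param S effect of self-control
#' @param E external control parameter at week `t`
#' @param lam Poisson cue intensity at week `t` (expected cues/week, >= 0)
#' @return a named list of class `system_state`
#' @export
system_state <- function(t = 0, C = 0, S = 0.5, E = 0, lam = 0) {
  if (t < 0 || t != round(t)) stop("'t' must be a nonnegative integer", call. = FALSE)
  if (C < 0 || C > 1) stop("'C' must lie in [0, 1]", call. = FALSE)
  if (lam < 0) stop("'lam' must be nonnegative", call. = FALSE)
  structure(list(t = as.integer(t), C = C, S = S, E = E, lam = lam),
            class = "system_state")
}

#' Advance the state by one week
#'
#' Applies the craving and self-control updates synchronously: both `C(t+1)`
#' and `S(t+1)` are evaluated from the week-`t` values of `(C, S, A)`. The
#' realized weekly consumption `A_total` (deterministic part plus any cue
#' contribution) is supplied by the caller; drivers `E` and `lam` are carried
#' through unchanged — schedule updates belong to the scenario layer.
#'
#' @param state a [system_state()]
#' @param A_total realized weekly consumption, in \[0, q\]
#' @param params a [model_params()] object
#' @return the week-`t+1` `system_state`
#' @export
step_state <- function(state, A_total, params) {
  if (A_total < -1e-12 || A_total > params$q + 1e-12)
    stop("A_total = ", format(A_total), " outside [0, q = ",
         format(params$q), "]", call. = FALSE)
  system_state(t = state$t + 1L,
               C = update_craving(state$C, A_total, params),
               S = update_selfcontrol(state$S, state$C, A_total, params),
               E = state$E, lam = state$lam)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("week %d: C = %.6g, S = %.6g (E = %g, lambda = %g)\n",
              x$t, x$C, x$S, x$E, x$lam))
  invisible(x)
}
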