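#' Construct a validated parameter set for the craving/self-control map
#'
#' The weekly map has seven structural constants. `d` is the unlearning
#' (craving decay) rate per week; `b` the cue sensitivity, i.e. the impact of
#' one unit of consumption on craving; `q` the maximum consumption per week
#' (kg pure alcohol/week in the alcohol instantiation); `p` the psychological
#' resilience with which the self-control resource restores toward its ceiling
#' `S_plus`; and `h`, `k` the per-week depletion of self-control per unit of
#' craving and consumption respectively.
#'
#' The constructor enforces `b * q < 1`. Under that condition craving started
#' in \[0, 1\] provably stays in \[0, 1\] without any clamping, so the
#' simulator never clips state; a parameter set violating the condition is
#' rejected rather than silently clamped, because clamping would mask a
#' parameter-regime error.
#'
#' @param d unlearning rate, in (0, 1)
#' @param b cue sensitivity, >= 0, with `b * q < 1`
#' @param q maximum weekly consumption, > 0
#' @param p resilience (self-control restoration rate), > 0
#' @param S_plus maximum effect of self-control, >= 0
#' @param h self-control depletion per unit craving, >= 0
#' @param k self-control depletion per unit consumption, >= 0
#' @return an object of class `craving_params` (a named list)
#' @seealso [default_params()], [calibrate_params()]
#' @export
#' @examples
#' model_params(d = 0.2, b = 0.5, q = 0.8, p = 0.4, S_plus = 0.5,
#'              h = 0.2, k = 0.25)
model_params <- function(d, b, q, p, S_plus, h, k) {
  for (nm in c("d", "b", "q", "p", "S_plus", "h", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (d <= 0 || d >= 1) stop("parameter 'd' must satisfy 0 < d < 1", call. = FALSE)
  if (p <= 0) stop("parameter 'p' must be positive", call. = FALSE)
  if (q <= 0) stop("parameter 'q' must be positive", call. = FALSE)
  if (b < 0) stop("parameter 'b' must be nonnegative", call. = FALSE)
  if (h < 0) stop("parameter 'h' must be nonnegative", call. = FALSE)
  if (k < 0) stop("parameter 'k' must be nonnegative", call. = FALSE)
  if (S_plus < 0) stop("parameter 'S_plus' must be nonnegative", call. = FALSE)
  if (b * q >= 1)
    stop("parameter set rejected: b * q = ", format(b * q),
         " >= 1; boundedness of craving requires b * q < 1", call. = FALSE)
  structure(list(d = d, b = b, q = q, p = p, S_plus = S_plus, h = h, k = k),
            class = "craving_params")
}

#' Derive a calibrated parameter set from its three free constants
#'
#' Only `d`, `q` and `S_plus` are chosen freely; the remaining four constants
#' follow from calibration identities rather than being set independently:
#' \itemize{
#'   \item `b = 2 d / q` — consumption at half maximum (`A = q/2`) leaves
#'     craving stationary at `C = 1/2`;
#'   \item `p = 2 d` — self-control must restore on a faster time scale than
#'     craving decays;
#'   \item `h/2 = k q / 2 = p S_plus / 2` — the two depletion terms are of
#'     equal strength and together match the maximal restoring force, giving
#'     `h = p S_plus` and `k = p S_plus / q`.
#' }
#' The identities are computed here, not hard-coded, so they stay testable.
#'
#' @param d unlearning rate (default 0.2, a decay time of the order of months)
#' @param q maximum weekly consumption (default 0.8 kg pure alcohol)
#' @param S_plus maximum effect of self-control (default 0.5)
#' @return a `craving_params` object
#' @export
calibrate_params <- function(d = 0.2, q = 0.8, S_plus = 0.5) {
  b <- 2 * d / q
  p <- 2 * d
  h <- p * S_plus
  k <- p * S_plus / q
  model_params(d = d, b = b, q = q, p = p, S_plus = S_plus, h = h, k = k)
}

#' Default parameter set for the alcohol instantiation
#'
#' `d = 0.2`, `q = 0.8`, `S_plus = 0.5` with the derived values
#' `b = 0.5`, `p = 0.4`, `h = 0.2`, `k = 0.25` (see [calibrate_params()]).
#'
#' @return a `craving_params` object
#' @export
default_params <- function() calibrate_params()

#' @export
print.craving_params <- function(x, ...) {
  cat("Craving/self-control map parameters:\n")
  cat(sprintf("  d = %g (unlearning), b = %g (cue sensitivity), q = %g (max consumption)\n",
              x$d, x$b, x$q))
  cat(sprintf("  p = %g (resilience), S_plus = %g (self-control ceiling)\n",
              x$p, x$S_plus))
  cat(sprintf("  h = %g, k = %g (depletion per unit craving / consumption)\n",
              x$h, x$k))
  invisible(x)
}
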