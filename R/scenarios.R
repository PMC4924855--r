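# Scenario simulations: the stochastic weekly loop plus the three study
# designs — addiction onset under lifestyle change, stationary relapse
# dynamics, and the 7-week therapeutic intervention with its Monte Carlo
# success estimate.

# One record per week t: draw the cue count from lambda(t), form consumption
# A(t) from the current state, then advance (C, S) synchronously. E_vec and
# lam_vec give the drivers for records t0 .. t0+n-1; returns the records and
# the end state at week t0+n. Uses the current RNG stream (seeding is the
# caller's job, so phases can be chained on one stream).
.sim_core <- function(params, C0, S0, E_vec, lam_vec, t0 = 0L, n = length(E_vec)) {
  C <- numeric(n); S <- numeric(n)
  R <- integer(n); A <- numeric(n); V <- numeric(n)
  Ct <- C0; St <- S0
  for (i in seq_len(n)) {
    C[i] <- Ct; S[i] <- St
    R[i] <- sample_cue_count(lam_vec[i])
    av <- total_consumption(Ct, St, E_vec[i], R[i], params)
    A[i] <- av$A; V[i] <- av$V
    C_next <- update_craving(Ct, A[i], params)
    S_next <- update_selfcontrol(St, Ct, A[i], params)
    Ct <- C_next; St <- S_next
  }
  list(records = data.frame(t = t0 + seq_len(n) - 1L, C = C, S = S,
                            E = E_vec, lambda = lam_vec, R = R, A = A, V = V),
       C_end = Ct, S_end = St)
}

.as_trajectory <- function(df, params, seed = NA_integer_) {
  structure(df, class = c("craving_trajectory", "data.frame"),
            params = params, seed = seed)
}

#' Simulate the stochastic weekly model
#'
#' Iterates the map for `T_weeks` weeks: each week a Poisson cue count is
#' drawn at the current intensity, weekly consumption is formed from the
#' current state and the (capped) cue contribution, and craving and
#' self-control are updated synchronously from the week's values. Drivers
#' `E` and `lambda` may be scalars (stationary environment) or vectors of
#' length `T_weeks + 1` giving their value at each week `0 .. T_weeks`.
#'
#' With `lambda = 0` the simulation reduces exactly to the deterministic
#' map. Given the same `seed`, two runs are identical bit for bit.
#'
#' @param params a [model_params()] object
#' @param C0,S0 initial craving and self-control effect (defaults: abstinent
#'   start at full self-control)
#' @param E external control parameter (scalar or length `T_weeks + 1`)
#' @param lambda cue intensity (scalar or length `T_weeks + 1`)
#' @param T_weeks horizon in weeks (>= 1)
#' @param seed optional integer seed; if `NULL` the current RNG stream is used
#' @return a `craving_trajectory`: a data frame with one row per week
#'   `t = 0 .. T_weeks` and columns `t, C, S, E, lambda, R, A, V`
#' @export
simulate_trajectory <- function(params, C0 = 0, S0 = params$S_plus,
                                E = 0, lambda = 0, T_weeks, seed = NULL) {
  if (T_weeks < 1) stop("'T_weeks' must be at least 1", call. = FALSE)
  if (C0 < 0 || C0 > 1) stop("'C0' must lie in [0, 1]", call. = FALSE)
  n <- T_weeks + 1L
  E_vec <- if (length(E) == 1L) rep(E, n) else E
  lam_vec <- if (length(lambda) == 1L) rep(lambda, n) else lambda
  if (length(E_vec) != n || length(lam_vec) != n)
    stop("driver vectors must have length T_weeks + 1", call. = FALSE)
  if (any(lam_vec < 0)) stop("'lambda' must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim <- .sim_core(params, C0, S0, E_vec, lam_vec, t0 = 0L, n = n)
  .as_trajectory(sim$records, params, if (is.null(seed)) NA_integer_ else seed)
}

#' @export
print.craving_trajectory <- function(x, ...) {
  cat(sprintf("Weekly trajectory, %d weeks (t = %d .. %d)", nrow(x) - 1L,
              x$t[1], x$t[nrow(x)]))
  if (!is.na(attr(x, "seed"))) cat(sprintf(", seed %d", attr(x, "seed")))
  cat(sprintf("\n  final week: C = %.4f, S = %.4f, V = %.4f\n",
              x$C[nrow(x)], x$S[nrow(x)], x$V[nrow(x)]))
  invisible(x)
}

#' Onset schedule: lifestyle change drivers
#'
#' On entering a new community the environment is initially protective
#' (`E0 = 1`) and cues are moderate (`lam0 = 0.5`); week by week `E` drops by
#' `dE` to a stationary floor `E_end` while the cue intensity rises by `dlam`
#' to a ceiling `lam_end`. The stationary end values determine whether the
#' abstinent state survives. Default drifts of 0.01/week traverse the
#' bistable window within roughly three years.
#'
#' @param E0 initial external parameter
#' @param dE weekly decrement of `E` (>= 0)
#' @param E_end stationary floor for `E`
#' @param lam0 initial cue intensity
#' @param dlam weekly increment of `lambda` (>= 0)
#' @param lam_end stationary ceiling for `lambda`
#' @return a named list of class `onset_schedule`
#' @export
onset_schedule <- function(E0 = 1, dE = 0.01, E_end = 0,
                           lam0 = 0.5, dlam = 0.01, lam_end = 1) {
  if (E_end > E0) stop("'E_end' must not exceed 'E0'", call. = FALSE)
  if (lam0 > lam_end) stop("'lam0' must not exceed 'lam_end'", call. = FALSE)
  if (dE < 0 || dlam < 0) stop("'dE' and 'dlam' must be nonnegative", call. = FALSE)
  structure(list(E0 = E0, dE = dE, E_end = E_end,
                 lam0 = lam0, dlam = dlam, lam_end = lam_end),
            class = "onset_schedule")
}

#' Simulate addiction onset under lifestyle change
#'
#' Starts abstinent (`C = 0`, `S = S_plus`) and runs the stochastic model
#' while the drivers follow the schedule: `E(t) = max(E_end, E0 - dE t)`,
#' `lambda(t) = min(lam_end, lam0 + dlam t)`. The vulnerability column of
#' the returned trajectory marks the switch to dependence more sharply than
#' craving itself.
#'
#' @param params a [model_params()] object
#' @param schedule an [onset_schedule()]
#' @param T_weeks horizon in weeks
#' @param seed optional integer seed
#' @return a `craving_trajectory`
#' @export
run_onset <- function(params, schedule = onset_schedule(), T_weeks = 500,
                      seed = NULL) {
  t <- 0:T_weeks
  E_vec <- pmax(schedule$E_end, schedule$E0 - schedule$dE * t)
  lam_vec <- pmin(schedule$lam_end, schedule$lam0 + schedule$dlam * t)
  simulate_trajectory(params, C0 = 0, S0 = params$S_plus,
                      E = E_vec, lambda = lam_vec,
                      T_weeks = T_weeks, seed = seed)
}

#' Simulate a stationary environment (relapse regime)
#'
#' Fixed `E` and `lambda` over the whole horizon. At the reference setting
#' `E = 0.1525`, `lambda = 1` over ten years the vulnerability alternates
#' between near-abstinent and near-saturated excursions: repeated relapses
#' triggered by locally higher cue intensity, with recovery when cues
#' locally thin out.
#'
#' @param params a [model_params()] object
#' @param E external control parameter (scalar)
#' @param lambda cue intensity (scalar)
#' @param T_weeks horizon in weeks (default 520, about ten years)
#' @param C0,S0 initial state (defaults: abstinent at full self-control)
#' @param seed optional integer seed
#' @return a `craving_trajectory`
#' @export
run_stationary <- function(params, E = 0.1525, lambda = 1, T_weeks = 520,
                           C0 = 0, S0 = params$S_plus, seed = NULL) {
  simulate_trajectory(params, C0 = C0, S0 = S0, E = E, lambda = lambda,
                      T_weeks = T_weeks, seed = seed)
}

#' Therapeutic intervention protocol
#'
#' A post-treatment lifestyle is fixed first (`S_plus`, `lambda`, `E`
#' baseline); the treatment itself, lasting `duration_weeks`, doubles the
#' self-control restoring force by raising resilience to `p_treat` and
#' halves cue exposure to `lam_treat`. Success is judged by the
#' vulnerability at `eval_week` weeks after the start of treatment being
#' below `success_threshold`; exact equality counts as failure (the
#' conservative tie-break).
#'
#' @param duration_weeks treatment length in weeks
#' @param p_treat resilience during treatment
#' @param lam_treat cue intensity during treatment
#' @param S_plus_base,lam_base,E_base the post-treatment environment
#' @param eval_week evaluation time, counted from treatment start
#' @param success_threshold vulnerability cut-off in (0, 1)
#' @return a named list of class `intervention_protocol`
#' @export
intervention_protocol <- function(duration_weeks = 7, p_treat = 0.8,
                                  lam_treat = 0.25, S_plus_base = 0.5,
                                  lam_base = 0.5, E_base = 0,
                                  eval_week = 100, success_threshold = 0.5) {
  if (duration_weeks < 0 || duration_weeks != round(duration_weeks))
    stop("'duration_weeks' must be a nonnegative integer", call. = FALSE)
  if (duration_weeks >= eval_week)
    stop("'duration_weeks' must be below 'eval_week'", call. = FALSE)
  if (success_threshold <= 0 || success_threshold >= 1)
    stop("'success_threshold' must lie in (0, 1)", call. = FALSE)
  if (lam_treat < 0 || lam_base < 0)
    stop("cue intensities must be nonnegative", call. = FALSE)
  structure(list(duration_weeks = as.integer(duration_weeks),
                 p_treat = p_treat, lam_treat = lam_treat,
                 S_plus_base = S_plus_base, lam_base = lam_base,
                 E_base = E_base, eval_week = as.integer(eval_week),
                 success_threshold = success_threshold),
            class = "intervention_protocol")
}

# Stable addicted (highest-C stable) equilibrium under the baseline
# environment; errors when none exists — nothing to treat.
.addicted_start <- function(base_params, E_base) {
  eqs <- find_equilibria(base_params, E_base)
  eqs <- eqs[eqs$stable & eqs$C_star > 1e-6, , drop = FALSE]
  if (nrow(eqs) == 0)
    stop("no stable addicted equilibrium exists under the baseline ",
         "parameters; there is nothing to treat", call. = FALSE)
  eqs[which.max(eqs$C_star), ]
}

#' Run one therapeutic intervention
#'
#' The individual starts addicted: the initial state is the stable addicted
#' deterministic equilibrium of the baseline environment (for the defaults
#' at `E = 0`: `C = 2/3`, `S = -1/3`). Weeks `0 .. duration_weeks - 1` run
#' with the treatment parameters (`p_treat`, `lam_treat`); from
#' `duration_weeks` to `eval_week` the baseline environment applies. Cues
#' stay stochastic throughout, on one RNG stream, so the whole run is
#' reproducible from the seed. Success iff `V(eval_week) < threshold`.
#'
#' @param params a [model_params()] object (its `S_plus` is replaced by the
#'   protocol's baseline value)
#' @param protocol an [intervention_protocol()]
#' @param seed optional integer seed
#' @return a list with `success` (logical), `V_eval` (vulnerability at the
#'   evaluation week) and `trajectory` (weeks `0 .. eval_week`)
#' @export
run_intervention <- function(params, protocol = intervention_protocol(),
                             seed = NULL) {
  base_params <- model_params(d = params$d, b = params$b, q = params$q,
                              p = params$p, S_plus = protocol$S_plus_base,
                              h = params$h, k = params$k)
  treat_params <- model_params(d = params$d, b = params$b, q = params$q,
                               p = protocol$p_treat,
                               S_plus = protocol$S_plus_base,
                               h = params$h, k = params$k)
  start <- .addicted_start(base_params, protocol$E_base)
  if (!is.null(seed)) set.seed(seed)

  dur <- protocol$duration_weeks
  n_post <- protocol$eval_week - dur + 1L   # records dur .. eval_week
  if (dur > 0) {
    ph1 <- .sim_core(treat_params, start$C_star, start$S_star,
                     E_vec = rep(protocol$E_base, dur),
                     lam_vec = rep(protocol$lam_treat, dur),
                     t0 = 0L, n = dur)
    ph2 <- .sim_core(base_params, ph1$C_end, ph1$S_end,
                     E_vec = rep(protocol$E_base, n_post),
                     lam_vec = rep(protocol$lam_base, n_post),
                     t0 = dur, n = n_post)
    records <- rbind(ph1$records, ph2$records)
  } else {
    ph2 <- .sim_core(base_params, start$C_star, start$S_star,
                     E_vec = rep(protocol$E_base, n_post),
                     lam_vec = rep(protocol$lam_base, n_post),
                     t0 = 0L, n = n_post)
    records <- ph2$records
  }
  traj <- .as_trajectory(records, base_params,
                         if (is.null(seed)) NA_integer_ else seed)
  V_eval <- records$V[records$t == protocol$eval_week]
  list(success = V_eval < protocol$success_threshold,
       V_eval = V_eval, trajectory = traj)
}

#' Monte Carlo estimate of the intervention success rate
#'
#' Runs `n` independent replicates of [run_intervention()]. Replicate seeds
#' are drawn once from the master seed, so replicate `r` is reproducible in
#' isolation from `(master_seed, r)`. The success rate comes with a 95%
#' Wilson score confidence interval.
#'
#' @param params a [model_params()] object
#' @param protocol an [intervention_protocol()]
#' @param n number of replicates (>= 1)
#' @param master_seed integer seed for the replicate-seed stream
#' @return an object of class `mc_summary`: a list with `n_replicates`,
#'   `n_success`, `success_rate`, `ci_low`, `ci_high`, `master_seed`
#' @export
monte_carlo_intervention <- function(params, protocol = intervention_protocol(),
                                     n = 50, master_seed = 1) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  set.seed(master_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n)
  successes <- vapply(seq_len(n), function(r) {
    run_intervention(params, protocol, seed = rep_seeds[r])$success
  }, logical(1))
  k <- sum(successes)
  ci <- if (n > 1) {
    suppressWarnings(stats::prop.test(k, n, correct = FALSE)$conf.int)
  } else c(0, 1)
  structure(list(n_replicates = as.integer(n), n_success = as.integer(k),
                 success_rate = k / n, ci_low = ci[1], ci_high = ci[2],
                 master_seed = master_seed),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Intervention Monte Carlo: %d / %d successes (%.1f%%)\n",
              x$n_success, x$n_replicates, 100 * x$success_rate))
  cat(sprintf("  95%% Wilson CI: [%.1f%%, %.1f%%]   (master seed %d)\n",
              100 * x$ci_low, 100 * x$ci_high, x$master_seed))
  invisible(x)
}
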