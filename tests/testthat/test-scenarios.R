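p0 <- default_params()

test_that("simulated trajectories are reproducible and respect the fixed points", {
  # abstinent start, no cues: constant trajectory at the abstinent fixed point
  tr <- simulate_trajectory(p0, C0 = 0, S0 = 0.5, E = 0, lambda = 0,
                            T_weeks = 50)
  expect_true(all(tr$C == 0))
  expect_true(all(tr$V == 0))
  # addicted basin: converges to the saturated equilibrium
  tr2 <- simulate_trajectory(p0, C0 = 0.6, S0 = 0, E = 0, lambda = 0,
                             T_weeks = 300)
  expect_equal(tail(tr2$C, 1), 2 / 3, tolerance = 1e-6)
  expect_equal(tail(tr2$S, 1), -1 / 3, tolerance = 1e-6)
  # bit-for-bit reproducibility under a fixed seed
  a <- simulate_trajectory(p0, E = 0.1, lambda = 1, T_weeks = 120, seed = 7)
  b <- simulate_trajectory(p0, E = 0.1, lambda = 1, T_weeks = 120, seed = 7)
  expect_identical(a, b)
})

test_that("every scenario trajectory satisfies the state bounds week by week", {
  set.seed(51)
  trajs <- list(
    run_onset(p0, onset_schedule(), T_weeks = 300, seed = 1),
    run_stationary(p0, E = 0.1525, lambda = 1, T_weeks = 300, seed = 2),
    run_intervention(p0, seed = 3)$trajectory
  )
  for (tr in trajs) {
    expect_true(all(tr$C >= 0 & tr$C <= 1))
    expect_true(all(tr$A >= -1e-12 & tr$A <= p0$q + 1e-12))
    expect_true(all(tr$V >= 0 & tr$V <= 1))
    expect_true(all(tr$S <= max(tr$S[1], 0.5) + 1e-12))
    expect_identical(tr$t, seq(0L, nrow(tr) - 1L))
  }
})

test_that("onset schedules drive E down to its floor and lambda up to its ceiling", {
  sch <- onset_schedule(E0 = 1, dE = 0.01, E_end = 0, lam0 = 0.5,
                        dlam = 0.01, lam_end = 1)
  tr <- run_onset(p0, sch, T_weeks = 200, seed = 4)
  expect_equal(tr$E, pmax(0, 1 - 0.01 * (0:200)))
  expect_equal(tr$lambda, pmin(1, 0.5 + 0.01 * (0:200)))
  expect_equal(c(tr$C[1], tr$S[1]), c(0, p0$S_plus))
  # degenerate schedule: constant drivers are allowed
  trc <- run_onset(p0, onset_schedule(E0 = 0.5, dE = 0, E_end = 0.5,
                                      lam0 = 0.2, dlam = 0, lam_end = 0.2),
                   T_weeks = 100, seed = 5)
  expect_true(all(trc$E == 0.5) && all(trc$lambda == 0.2))
  expect_error(onset_schedule(lam0 = 0.5, lam_end = 0.2), "lam0")
})

test_that("a protective stationary environment keeps vulnerability low", {
  # strong protection: V = C - S - E clamps to zero except under extreme pileups
  maxV <- vapply(1:20, function(s)
    max(run_stationary(p0, E = 1, lambda = 1, T_weeks = 520, seed = s)$V),
    numeric(1))
  expect_true(all(maxV < 0.5))
  # no cues from an abstinent start: identically zero vulnerability
  tr <- run_stationary(p0, E = 0.1525, lambda = 0, T_weeks = 520, seed = 1)
  expect_true(all(tr$V == 0))
})

test_that("the treated parameter set removes the addicted equilibrium", {
  treat <- model_params(d = p0$d, b = p0$b, q = p0$q, p = 0.8,
                        S_plus = 0.5, h = p0$h, k = p0$k)
  eqs <- find_equilibria(treat, 0)
  expect_identical(eqs$regime, "abstinent")
})

test_that("interventions are deterministic successes without cues, failures without treatment", {
  # no cues anywhere: craving decays out of the addicted basin during treatment
  proto0 <- intervention_protocol(lam_treat = 0, lam_base = 0)
  out <- run_intervention(p0, proto0, seed = 1)
  expect_true(out$success)
  expect_equal(out$trajectory$C[1], 2 / 3, tolerance = 1e-12)
  expect_equal(out$trajectory$S[1], -1 / 3, tolerance = 1e-12)
  mc <- monte_carlo_intervention(p0, proto0, n = 100, master_seed = 1)
  expect_equal(mc$success_rate, 1)
  # zero-length treatment: the system sits at the addicted fixed point (V = 1)
  protod <- intervention_protocol(duration_weeks = 0, lam_base = 0)
  outd <- run_intervention(p0, protod, seed = 1)
  expect_false(outd$success)
  expect_equal(outd$V_eval, 1)
  # nothing to treat when the baseline has no addicted equilibrium
  expect_error(run_intervention(p0, intervention_protocol(E_base = 0.3)),
               "nothing to treat")
})

test_that("intervention runs and Monte Carlo summaries are reproducible", {
  o1 <- run_intervention(p0, seed = 99)
  o2 <- run_intervention(p0, seed = 99)
  expect_identical(o1$success, o2$success)
  expect_identical(o1$trajectory, o2$trajectory)
  m1 <- monte_carlo_intervention(p0, n = 50, master_seed = 5)
  m2 <- monte_carlo_intervention(p0, n = 50, master_seed = 5)
  expect_identical(m1, m2)
  expect_lte(m1$ci_low, m1$success_rate)
  expect_gte(m1$ci_high, m1$success_rate)
  expect_equal(m1$n_success, round(m1$success_rate * m1$n_replicates))
})

test_that("success rate responds monotonically to cue pressure and treatment length", {
  rate <- function(proto, n = 300, seed = 17)
    monte_carlo_intervention(p0, proto, n = n, master_seed = seed)$success_rate
  se <- sqrt(0.25 / 300)
  # more cues during treatment cannot help (within sampling error)
  r_lam <- vapply(c(0, 0.25, 0.5), function(l)
    rate(intervention_protocol(lam_treat = l)), numeric(1))
  expect_gte(r_lam[1], r_lam[2] - 2 * se)
  expect_gte(r_lam[2], r_lam[3] - 2 * se)
  # longer treatment helps (within sampling error)
  r_dur <- vapply(c(0, 7, 14), function(d)
    rate(intervention_protocol(duration_weeks = d)), numeric(1))
  expect_gte(r_dur[2], r_dur[1] - 2 * se)
  expect_gte(r_dur[3], r_dur[2] - 2 * se)
})
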