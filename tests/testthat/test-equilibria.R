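p0 <- default_params()

test_that("abstinent equilibrium exists exactly for E >= -S_plus and is stable", {
  eq <- abstinent_equilibrium(p0, 0)
  expect_equal(c(eq$C_star, eq$S_star), c(0, 0.5))
  expect_equal(sort(c(eq$eig1, eq$eig2)), c(0.6, 0.8))   # diag(1-d, 1-p)
  expect_true(eq$stable)
  eq_b <- abstinent_equilibrium(p0, -0.5)                # boundary: V = 0 exactly
  expect_equal(nrow(eq_b), 1L)
  expect_true(eq_b$boundary)
  expect_equal(nrow(abstinent_equilibrium(p0, -0.6)), 0L)
})

test_that("interior solver finds the unstable saddle and respects regime validity", {
  eqs <- interior_equilibria(p0, 0)
  expect_equal(nrow(eqs), 1L)   # second quadratic root has V = 1: saturated branch
  expect_equal(c(eqs$C_star, eqs$S_star), c(0.5, 0), tolerance = 1e-12)
  expect_false(eqs$stable)
  expect_equal(c(eqs$eig1, eqs$eig2),
               c(0.8 + sqrt(0.08), 0.8 - sqrt(0.08)), tolerance = 1e-10)
  expect_equal(nrow(interior_equilibria(p0, 0.3)), 0L)   # negative discriminant
  two <- interior_equilibria(p0, 0.01)                   # both roots interior
  expect_equal(nrow(two), 2L)
  expect_true(all(is.finite(c(two$eig1, two$eig2))))
})

test_that("saturated equilibrium has E-independent coordinates and validity E <= 0", {
  eq <- saturated_equilibrium(p0, 0)
  expect_equal(c(eq$C_star, eq$S_star), c(2 / 3, -1 / 3), tolerance = 1e-12)
  expect_true(eq$stable)
  expect_equal(sort(c(eq$eig1, eq$eig2)), c(0.4, 0.6))
  eq2 <- saturated_equilibrium(p0, -0.4)
  expect_equal(c(eq2$C_star, eq2$S_star), c(eq$C_star, eq$S_star))
  expect_equal(nrow(saturated_equilibrium(p0, 0.1)), 0L)
})

test_that("regime Jacobians match hand differentiation", {
  expect_equal(jacobian_matrix(p0, 0, 0.5, 0, "abstinent"),
               matrix(c(0.8, 0, -0.2, 0.6), 2, 2, byrow = TRUE))
  expect_equal(jacobian_matrix(p0, 0.5, 0, 0, "interior"),
               matrix(c(0.8, -0.2, -0.4, 0.8), 2, 2, byrow = TRUE))
  expect_equal(jacobian_matrix(p0, 2 / 3, -1 / 3, 0, "saturated"),
               matrix(c(0.4, 0, -0.2, 0.6), 2, 2, byrow = TRUE))
})

test_that("the degenerate reduction k*q = p is detected", {
  pd <- model_params(d = 0.2, b = 0.5, q = 0.8, p = 0.2, S_plus = 0.5,
                     h = 0.2, k = 0.25)
  expect_error(interior_equilibria(pd, 0), "k\\*q == p")
  # the numeric oracle still works there
  expect_gte(nrow(brute_force_equilibria(pd, 0)), 1L)
})

test_that("closed-form solvers find exactly the oracle's fixed points", {
  set.seed(41)
  for (i in 1:200) {
    pp <- random_params()
    E <- runif(1, -0.8, 0.5)
    cf <- find_equilibria(pp, E)
    bf <- brute_force_equilibria(pp, E, n_grid = 7L)
    expect_equal(nrow(cf), nrow(bf),
                 info = sprintf("draw %d: E=%.4f", i, E))
    if (nrow(cf) == nrow(bf) && nrow(cf) > 0) {
      expect_lt(max(abs(cf$C_star - bf[, "C"]), abs(cf$S_star - bf[, "S"])),
                1e-6)
    }
  }
})

test_that("branch sweep has the two-stable/one-unstable structure with a refined fold", {
  bd <- sweep_branches(p0, -0.6, 0.35, 0.005)
  br <- bd$branches
  # abstinent branch present exactly for E >= -S_plus
  absE <- sort(unique(br$E[br$regime == "abstinent"]))
  expect_equal(min(absE), -0.5)
  expect_true(all(br$E[br$regime == "abstinent"] >= -0.5))
  expect_false(any(abs(br$E - (-0.505)) < 1e-9 & br$regime == "abstinent"))
  # equilibrium count per grid point is 1, 2 or 3
  cnt <- table(br$E)
  expect_true(all(cnt %in% 1:3))
  # where two stable branches coexist there is exactly one unstable between them
  for (E in unique(br$E)) {
    sub <- br[br$E == E, ]
    if (sum(sub$stable) == 2) {
      uns <- sub[!sub$stable, , drop = FALSE]
      if (nrow(uns) == 1) {
        expect_true(uns$C_star > min(sub$C_star[sub$stable]) &&
                    uns$C_star < max(sub$C_star[sub$stable]))
      } else {
        # the unstable branch terminates by merging with a stable branch at a
        # regime boundary (E = -S_plus); the merged point carries the flag
        expect_true(any(sub$boundary))
      }
    }
  }
  # interior-pair fold at the smaller root of 4E^2 - 10E + 0.25 = 0
  E_fold <- (10 - sqrt(96)) / 8
  expect_lt(min(abs(bd$folds - E_fold)), 1e-6)
})

test_that("hysteresis: the two stable states attract different histories", {
  for (E in c(-0.3, -0.1, 0)) {
    eqs <- find_equilibria(p0, E)
    stab <- eqs[eqs$stable, ]
    expect_equal(nrow(stab), 2L)
    end_abst <- iterate_deterministic(p0, 0, p0$S_plus, E, 600)
    end_add <- iterate_deterministic(p0, max(stab$C_star) + 1e-3,
                                     min(stab$S_star), E, 600)
    expect_lt(abs(end_abst["C"] - min(stab$C_star)), 1e-6)
    expect_lt(abs(end_add["C"] - max(stab$C_star)), 1e-6)
    expect_gt(abs(end_add["C"] - end_abst["C"]), 0.5)
  }
})

test_that("stability classification agrees with perturbed deterministic trajectories", {
  eqs <- find_equilibria(p0, 0)
  for (i in seq_len(nrow(eqs))) {
    x0 <- c(eqs$C_star[i] + 1e-4, eqs$S_star[i] - 1e-4)
    x0[1] <- min(max(x0[1], 0), 1)
    dist <- function(n) {
      xe <- iterate_deterministic(p0, x0[1], x0[2], 0, n)
      max(abs(xe - c(eqs$C_star[i], eqs$S_star[i])))
    }
    if (eqs$stable[i]) {
      expect_lt(dist(500), 1e-6)
    } else {
      expect_gt(max(vapply(c(50, 100, 500), dist, numeric(1))), 1e-2)
    }
  }
})
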