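# Fixed points of the deterministic (lambda = 0) weekly map. The double clamp
# in V and the restoration max make the map piecewise linear-quadratic, with
# three regimes: abstinent (V clamped at 0), interior (0 < V < 1) and
# saturated (V clamped at 1). Each regime admits a closed-form solution.

.regime_tol <- 1e-9

.eq_row <- function(E, C, S, regime, params, boundary = FALSE) {
  J <- jacobian_matrix(params, C, S, E, regime)
  ev <- sort(Mod(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
  data.frame(E = E, C_star = C, S_star = S, regime = regime,
             eig1 = ev[1], eig2 = ev[2],
             stable = all(ev < 1 - 1e-9),
             boundary = boundary,
             stringsAsFactors = FALSE)
}

#' Regime-specific Jacobian of the one-week map
#'
#' Linearizes the deterministic map at a point using the branch of each
#' `min`/`max` that the given regime selects: abstinent takes `A` identically
#' 0, saturated takes `A` identically `q`, interior takes `A = q (C - S - E)`.
#' The restoration term uses its active branch (`S <= S_plus`), the side from
#' which the dynamics approach the ceiling.
#'
#' @param params a [model_params()] object
#' @param C,S,E point of linearization
#' @param regime one of `"abstinent"`, `"interior"`, `"saturated"`
#' @return a 2x2 matrix, rows/columns ordered (C, S)
#' @export
jacobian_matrix <- function(params, C, S, E, regime) {
  d <- params$d; b <- params$b; q <- params$q
  p <- params$p; h <- params$h; k <- params$k
  switch(regime,
    abstinent = matrix(c(1 - d, 0,
                         -h, 1 - p), 2, 2, byrow = TRUE),
    saturated = matrix(c(1 - b * q - d, 0,
                         -h, 1 - p), 2, 2, byrow = TRUE),
    interior  = {
      A <- q * (C - S - E)
      matrix(c(1 - d - b * A + b * q * (1 - C), -b * q * (1 - C),
               -h - k * q, 1 - p + k * q), 2, 2, byrow = TRUE)
    },
    stop("unknown regime '", regime, "'", call. = FALSE)
  )
}

#' Abstinent fixed point
#'
#' `(C, S) = (0, S_plus)` is a fixed point iff the vulnerability clamp is
#' consistent there: `0 - S_plus - E <= 0`, i.e. `E >= -S_plus`. Below that
#' the abstinent branch ceases to exist — even at zero craving the
#' environment alone drives consumption.
#'
#' @param params a [model_params()] object
#' @param E external control parameter
#' @return a one-row equilibrium data frame, or a zero-row frame if absent
#' @export
abstinent_equilibrium <- function(params, E) {
  if (E < -params$S_plus - .regime_tol) return(.eq_empty())
  boundary <- abs(E + params$S_plus) < .regime_tol
  .eq_row(E, 0, params$S_plus, "abstinent", params, boundary = boundary)
}

#' Saturated (fully addicted) fixed point
#'
#' With `V` clamped at 1 the map is affine with `A = q`; its fixed point is
#' `C* = b q / (d + b q)`, `S* = S_plus - (h C* + k q) / p` (restoration
#' active since `S* < S_plus`). The clamp is self-consistent iff
#' `C* - S* - E >= 1`; within the regime the coordinates do not depend on
#' `E` — only the validity condition does.
#'
#' @inheritParams abstinent_equilibrium
#' @return a one-row equilibrium data frame, or a zero-row frame if absent
#' @export
saturated_equilibrium <- function(params, E) {
  C <- params$b * params$q / (params$d + params$b * params$q)
  S <- params$S_plus - (params$h * C + params$k * params$q) / params$p
  V_raw <- C - S - E
  if (V_raw < 1 - .regime_tol) return(.eq_empty())
  .eq_row(E, C, S, "saturated", params,
          boundary = abs(V_raw - 1) < .regime_tol)
}

# Coefficients of the interior quadratic a2*C^2 + a1*C + a0 = 0, obtained by
# solving the stationary S-balance p(S_plus - S) = hC + kq(C - S - E) for S,
# substituting into the stationary C-balance dC = bq(1 - C)(C - S - E).
.interior_quadratic <- function(params, E) {
  d <- params$d; b <- params$b; q <- params$q
  p <- params$p; h <- params$h; k <- params$k; Sp <- params$S_plus
  denom <- k * q - p
  if (abs(denom) < 1e-10)
    stop("degenerate parameter set: k*q == p; the interior reduction divides ",
         "by k*q - p. Use brute_force_equilibria() instead.", call. = FALSE)
  m <- (h + k * q) / denom            # S = m*C + c0
  c0 <- (-k * q * E - p * Sp) / denom
  alpha <- 1 - m                      # V = alpha*C - beta
  beta <- E + c0
  c(a2 = b * q * alpha,
    a1 = -(b * q * alpha + b * q * beta - d),
    a0 = b * q * beta,
    m = m, c0 = c0)
}

.interior_discriminant <- function(params, E) {
  co <- .interior_quadratic(params, E)
  unname(co["a1"]^2 - 4 * co["a2"] * co["a0"])
}

#' Interior fixed points
#'
#' Fixed points with `0 < V < 1`, where the map is genuinely nonlinear: the
#' stationary self-control balance is linear in `S` given `C`, and
#' substitution into the stationary craving balance yields a quadratic in
#' `C`. Real roots are kept only when the interior regime is self-consistent
#' (`0 < C - S - E < 1`, `0 <= C < 1`); roots landing on a clamp boundary
#' belong to the clamped regimes and are dropped here. For the default
#' parameters at external parameter `E` the quadratic is
#' `3 C^2 - (3.5 + 2E) C + (1 + 2E) = 0`.
#'
#' Signals an error when `k q = p`, where the reduction degenerates; the
#' numeric oracle [brute_force_equilibria()] covers that case.
#'
#' @inheritParams abstinent_equilibrium
#' @return an equilibrium data frame with 0, 1 or 2 rows
#' @export
interior_equilibria <- function(params, E) {
  co <- .interior_quadratic(params, E)
  disc <- co["a1"]^2 - 4 * co["a2"] * co["a0"]
  if (disc < 0 || abs(co["a2"]) < 1e-14) return(.eq_empty())
  roots <- sort((-co["a1"] + c(-1, 1) * sqrt(disc)) / (2 * co["a2"]))
  out <- .eq_empty()
  for (C in roots) {
    S <- co["m"] * C + co["c0"]
    V_raw <- C - S - E
    if (C >= -.regime_tol && C < 1 - .regime_tol &&
        V_raw > .regime_tol && V_raw < 1 - .regime_tol &&
        S < params$S_plus + .regime_tol) {
      out <- rbind(out, .eq_row(E, unname(C), unname(S), "interior", params))
    }
  }
  out
}

.eq_empty <- function() {
  data.frame(E = numeric(0), C_star = numeric(0), S_star = numeric(0),
             regime = character(0), eig1 = numeric(0), eig2 = numeric(0),
             stable = logical(0), boundary = logical(0),
             stringsAsFactors = FALSE)
}

#' All fixed points of the deterministic map at a given E
#'
#' Unions the three regime solvers and deduplicates coincident points
#' (within 1e-9 in both coordinates; a regime-boundary interior root
#' coincides with its clamped counterpart and is reported once, under the
#' clamped regime's label).
#'
#' @inheritParams abstinent_equilibrium
#' @return an equilibrium data frame with 1-3 rows, ordered by `C_star`
#' @export
find_equilibria <- function(params, E) {
  eqs <- rbind(abstinent_equilibrium(params, E),
               saturated_equilibrium(params, E),
               interior_equilibria(params, E))
  if (nrow(eqs) > 1) {
    keep <- rep(TRUE, nrow(eqs))
    for (i in seq_len(nrow(eqs) - 1)) {
      for (j in seq(i + 1, nrow(eqs))) {
        if (keep[j] &&
            abs(eqs$C_star[i] - eqs$C_star[j]) < 1e-9 &&
            abs(eqs$S_star[i] - eqs$S_star[j]) < 1e-9) keep[j] <- FALSE
      }
    }
    eqs <- eqs[keep, , drop = FALSE]
  }
  eqs <- eqs[order(eqs$C_star), , drop = FALSE]
  rownames(eqs) <- NULL
  eqs
}

#' Brute-force fixed-point oracle
#'
#' Independent of the closed-form solvers: Newton iteration with a
#' finite-difference Jacobian on the residual of the one-week deterministic
#' map, started from a dense grid over the invariant region
#' `[0, 1] x [S_lo, S_plus]`. (States with `S > S_plus` are excluded: the
#' restoration term never raises `S` above the ceiling and the depletion
#' terms only lower it, so any such fixed point is an artifact of
#' initialization, not of the dynamics.) Converged roots are filtered by a
#' residual tolerance and deduplicated.
#'
#' @inheritParams abstinent_equilibrium
#' @param n_grid grid points per axis for Newton starts
#' @param tol residual (sup-norm) acceptance tolerance
#' @return matrix with columns `C`, `S`, one row per distinct fixed point
#' @export
brute_force_equilibria <- function(params, E, n_grid = 9L, tol = 1e-10) {
  q <- params$q; Sp <- params$S_plus
  f <- function(x) {
    V <- vulnerability(x[1], x[2], E)
    A <- q * V
    c(update_craving(x[1], A, params),
      update_selfcontrol(x[2], x[1], A, params))
  }
  resid <- function(x) f(x) - x
  S_lo <- min(-1, Sp - (params$h + params$k * q) / params$p - 0.25)
  starts <- expand.grid(C = seq(0.001, 0.999, length.out = n_grid),
                        S = seq(S_lo, Sp, length.out = n_grid))
  roots <- matrix(numeric(0), ncol = 2)
  fd <- 1e-7
  for (s in seq_len(nrow(starts))) {
    x <- as.numeric(starts[s, ])
    for (it in 1:60) {
      g <- resid(x)
      if (max(abs(g)) < tol / 10) break
      J <- cbind((resid(x + c(fd, 0)) - resid(x - c(fd, 0))) / (2 * fd),
                 (resid(x + c(0, fd)) - resid(x - c(0, fd))) / (2 * fd))
      step <- tryCatch(solve(J, -g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      x <- x + step
      if (x[1] < -1 || x[1] > 2 || x[2] < S_lo - 2 || x[2] > Sp + 1) break
    }
    if (max(abs(resid(x))) < tol &&
        x[1] > -1e-8 && x[1] < 1 + 1e-8 && x[2] < Sp + 1e-8) {
      if (nrow(roots) == 0 ||
          all(abs(roots[, 1] - x[1]) + abs(roots[, 2] - x[2]) > 1e-7)) {
        roots <- rbind(roots, x)
      }
    }
  }
  roots <- roots[order(roots[, 1]), , drop = FALSE]
  dimnames(roots) <- list(NULL, c("C", "S"))
  roots
}

#' Sweep the external parameter and assemble the branch diagram
#'
#' Runs the three regime solvers on a grid of `E` values, producing the two
#' stable branches (abstinent `C = 0` and addicted `C > 0`) and the unstable
#' branch between them where both stable states coexist (hysteresis). Fold
#' locations — `E` values where the equilibrium count changes — are refined:
#' the disappearance of the interior pair by bisection on the interior
#' quadratic's discriminant (closed form, exact), any other count change by
#' bisection on the count itself.
#'
#' @param params a [model_params()] object
#' @param E_min,E_max sweep window (defaults bracket both branch endpoints
#'   for the default parameters)
#' @param step grid spacing in `E`
#' @return an object of class `branch_diagram`: a list with `branches`
#'   (one equilibrium row per grid point and branch), `folds` (refined `E`
#'   values where the equilibrium count changes) and `params`
#' @export
sweep_branches <- function(params, E_min = -0.6, E_max = 0.35, step = 0.005) {
  if (E_min >= E_max) stop("'E_min' must be below 'E_max'", call. = FALSE)
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  E_grid <- seq(E_min, E_max, by = step)
  rows <- lapply(E_grid, function(E) find_equilibria(params, E))
  counts <- vapply(rows, nrow, integer(1))
  branches <- do.call(rbind, rows)
  rownames(branches) <- NULL

  folds <- numeric(0)
  n_eq <- function(E) nrow(find_equilibria(params, E))
  for (i in which(diff(counts) != 0)) {
    lo <- E_grid[i]; hi <- E_grid[i + 1]
    d_lo <- .interior_discriminant(params, lo)
    d_hi <- .interior_discriminant(params, hi)
    if (sign(d_lo) != sign(d_hi)) {
      folds <- c(folds, stats::uniroot(function(E) .interior_discriminant(params, E),
                                       c(lo, hi), tol = 1e-10)$root)
    } else {
      n_lo <- counts[i]
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (n_eq(mid) == n_lo) lo <- mid else hi <- mid
      }
      folds <- c(folds, (lo + hi) / 2)
    }
  }
  # one structural event can change the count across two adjacent grid
  # intervals (e.g. a branch endpoint meeting an emerging branch); keep one
  if (length(folds) > 1) folds <- folds[c(TRUE, diff(sort(folds)) > 1e-6)]
  structure(list(branches = branches, folds = sort(folds), params = params),
            class = "branch_diagram")
}

#' @export
print.branch_diagram <- function(x, ...) {
  E_rng <- range(x$branches$E)
  cat(sprintf("Branch diagram over E in [%g, %g]: %d equilibrium records\n",
              E_rng[1], E_rng[2], nrow(x$branches)))
  tab <- table(x$branches$regime, ifelse(x$branches$stable, "stable", "unstable"))
  print(tab)
  if (length(x$folds))
    cat("Fold / branch-endpoint locations (E):",
        paste(sprintf("%.6f", x$folds), collapse = ", "), "\n")
  invisible(x)
}
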