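# Shared fixtures: random-but-valid parameter sets for property tests.

# Draws a parameter set satisfying the boundedness condition b*q < 1 and
# staying clear of the degenerate interior reduction k*q == p.
random_params <- function() {
  repeat {
    q <- runif(1, 0.4, 1.2)
    p <- runif(1, 0.15, 0.9)
    k <- runif(1, 0, 0.4)
    if (abs(k * q - p) < 0.05) next
    return(model_params(d = runif(1, 0.05, 0.5),
                        b = runif(1, 0.05, 0.95) / q,
                        q = q, p = p,
                        S_plus = runif(1, 0.1, 0.7),
                        h = runif(1, 0, 0.4), k = k))
  }
}

# Deterministic (lambda = 0) iteration used as an independent path for
# comparing against simulate_trajectory().
iterate_deterministic <- function(params, C0, S0, E, n) {
  C <- C0; S <- S0
  for (i in seq_len(n)) {
    A <- deterministic_consumption(vulnerability(C, S, E), params$q)
    Cn <- update_craving(C, A, params)
    Sn <- update_selfcontrol(S, C, A, params)
    C <- Cn; S <- Sn
  }
  c(C = C, S = S)
}
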