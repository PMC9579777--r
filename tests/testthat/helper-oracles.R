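# Independent oracles used to cross-check the solver paths.

# For p = 2 the first-order conditions are linear and the Nash efforts have
# the closed form e_i = (1 - s) / (2 - a_i) with s = (u + v) / (1 + u + v),
# u = 1/(2 - a1), v = 1/(2 - a2).
closed_form_nash_p2 <- function(a1, a2) {
  u <- 1 / (2 - a1)
  v <- 1 / (2 - a2)
  s <- (u + v) / (1 + u + v)
  list(e1 = (1 - s) / (2 - a1), e2 = (1 - s) / (2 - a2), total = s)
}

# For p = 2 the invasion fitness has a closed form and its mutant-direction
# derivative at the resident value reduces to u^2 / (1 + 2u)^3, u = 1/(2-a).
closed_form_gradient_p2 <- function(a) {
  u <- 1 / (2 - a)
  u^2 / (1 + 2 * u)^3
}

# Brute-force best response: two-stage grid search maximising the payoff,
# independent of the FOC-based solver.
brute_force_best_response <- function(a, e_partner, params, n = 2001) {
  grid <- seq(0, max(1e-9, 1 - min(e_partner, 1)), length.out = n)
  w <- payoff(rep(a, n), grid, rep(e_partner, n), params)
  i <- which.max(w)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n, i + 1)]
  grid2 <- seq(lo, hi, length.out = n)
  w2 <- payoff(rep(a, n), grid2, rep(e_partner, n), params)
  grid2[which.max(w2)]
}

# Brute-force Nash: alternate brute-force best responses to a fixed point.
brute_force_nash <- function(a1, a2, params, sweeps = 200) {
  e1 <- 0.25
  e2 <- 0.25
  for (k in seq_len(sweeps)) {
    e1 <- brute_force_best_response(a1, e2, params)
    e2 <- brute_force_best_response(a2, e1, params)
  }
  list(e1 = e1, e2 = e2)
}
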