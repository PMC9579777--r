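#' Best response to a partner's effort
#'
#' The unique effort maximising [payoff()] for an individual of ability
#' \code{a} facing a fixed partner effort. For \code{e_partner >= 1} the
#' benefit is already saturated and the best response is exactly 0. Otherwise
#' it is the unique root of the first-order condition
#' \deqn{2 - 2 (r + e) = (2 - a) \, p \, r^{p - 1}}
#' on \eqn{(0, 1 - e)}: marginal benefit is strictly decreasing and marginal
#' cost strictly increasing in \eqn{r}, so the root is unique and bracketed.
#' Solved by bisection, which is robust to the infinite slope of
#' \eqn{r^{p-1}} at 0 when \eqn{p < 2}.
#'
#' @param a Ability in \eqn{[0, 1]}. Vectorised (recycled with
#'   \code{e_partner}).
#' @param e_partner Partner effort, nonnegative.
#' @param params An [ability_params()] object.
#' @return Best-response effort(s), in \eqn{[0, 1 - e_{partner})}.
#' @examples
#' best_response(a = 0.5, e_partner = 0, ability_params(p = 2)) # 0.4
#' @export
best_response <- function(a, e_partner, params) {
  params <- as_ability_params(params)
  check_ability(a)
  check_effort(e_partner, "e_partner")
  n <- max(length(a), length(e_partner))
  a <- rep_len(a, n)
  e <- rep_len(e_partner, n)
  r <- numeric(n)
  interior <- e < 1
  if (any(interior)) {
    r[interior] <- br_bisect(a[interior], e[interior], params$p)
  }
  r
}

## vectorised bisection on the FOC  2 - 2(r+e) - (2-a) p r^(p-1) = 0
## over (0, 1-e); the FOC is positive at 0+ and negative at 1-e.
br_bisect <- function(a, e, p, n_iter = 60L) {
  lo <- numeric(length(a))
  hi <- 1 - e
  c2 <- (2 - a) * p
  for (k in seq_len(n_iter)) {
    mid <- 0.5 * (lo + hi)
    g <- 2 - 2 * (mid + e) - c2 * mid^(p - 1)
    pos <- g > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  0.5 * (lo + hi)
}

## FOC residual of effort r against partner effort e (vectorised)
foc_residual <- function(a, r, e, p) {
  benefit_slope(r + e) - (2 - a) * p * r^(p - 1)
}

## Alternating best responses (each a bracketed bisection) from the
## symmetric guess e1 = e2 = 0.25. The best-response map is a contraction
## (|slope| < 1), so plain alternation converges geometrically. Robust but
## slower than the Newton path below; used as its fallback and, in the test
## suite, as an independent cross-check.
nash_alternating <- function(a1, a2, params, tol = 1e-10,
                             max_iter = 10000L) {
  params <- as_ability_params(params)
  n <- max(length(a1), length(a2))
  a1 <- rep_len(a1, n)
  a2 <- rep_len(a2, n)
  e1 <- rep(0.25, n)
  e2 <- rep(0.25, n)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    e1_new <- br_bisect(a1, e2, params$p)
    e2_new <- br_bisect(a2, e1_new, params$p)
    delta <- max(abs(e1_new - e1), abs(e2_new - e2))
    e1 <- e1_new
    e2 <- e2_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  res1 <- foc_residual(a1, e1, e2, params$p)
  res2 <- foc_residual(a2, e2, e1, params$p)
  list(e1 = e1, e2 = e2, iterations = iter,
       converged = converged && max(abs(res1), abs(res2)) < 1e-8,
       foc1 = res1, foc2 = res2)
}

## Vectorised simultaneous Nash solve for ability pairs (a1[i], a2[i]):
## guarded Newton on the joint first-order conditions
##   2 - 2 (e1 + e2) = (2 - a_i) p e_i^(p-1),  i = 1, 2,
## started from the p = 2 closed form. The system's unique root always has
## e_i > 0 and total < 1 (the left side must be positive there), so the
## unsaturated linear branch of the marginal benefit is the correct one
## throughout. Steps that would drive an effort nonpositive are pulled back
## to half the current value. Entries not converged after `newton_iter`
## steps fall back to the alternating bisection path.
solve_nash_pairs <- function(a1, a2, params, tol = 1e-10, max_iter = 10000L,
                             newton_iter = 60L) {
  params <- as_ability_params(params)
  p <- params$p
  n <- max(length(a1), length(a2))
  a1 <- rep_len(a1, n)
  a2 <- rep_len(a2, n)
  c1 <- 2 - a1
  c2 <- 2 - a2
  ## p = 2 closed form as the starting point
  u <- 1 / c1
  v <- 1 / c2
  s <- (u + v) / (1 + u + v)
  e1 <- (1 - s) / c1
  e2 <- (1 - s) / c2
  iter <- 0L
  for (k in seq_len(newton_iter)) {
    iter <- k
    f1 <- 2 - 2 * (e1 + e2) - c1 * p * e1^(p - 1)
    f2 <- 2 - 2 * (e1 + e2) - c2 * p * e2^(p - 1)
    if (max(abs(f1), abs(f2)) < 1e-12) break
    A <- -2 - c1 * p * (p - 1) * e1^(p - 2)
    C <- -2 - c2 * p * (p - 1) * e2^(p - 2)
    det <- A * C - 4
    d1 <- -(C * f1 + 2 * f2) / det
    d2 <- -(2 * f1 + A * f2) / det
    e1 <- pmax(e1 + d1, 0.5 * e1)
    e2 <- pmax(e2 + d2, 0.5 * e2)
  }
  res1 <- foc_residual(a1, e1, e2, p)
  res2 <- foc_residual(a2, e2, e1, p)
  bad <- abs(res1) > 1e-10 | abs(res2) > 1e-10
  if (any(bad)) {
    fb <- nash_alternating(a1[bad], a2[bad], params, tol = tol,
                           max_iter = max_iter)
    e1[bad] <- fb$e1
    e2[bad] <- fb$e2
    res1[bad] <- fb$foc1
    res2[bad] <- fb$foc2
    iter <- iter + fb$iterations
  }
  list(e1 = e1, e2 = e2, iterations = iter,
       converged = max(abs(res1), abs(res2)) < 1e-8,
       foc1 = res1, foc2 = res2)
}

#' Nash equilibrium efforts for an ability pair
#'
#' Finds the effort pair at which each individual's effort is the best
#' response to the other's — the Nash equilibrium of the public goods game
#' between abilities \code{a1} and \code{a2}. Solved by alternating best
#' responses (each a bracketed bisection on the first-order condition) from
#' the symmetric start \eqn{e_1 = e_2 = 0.25}; the best-response map is a
#' contraction so the iteration converges geometrically and the equilibrium
#' is unique. The equilibrium total effort is always strictly inside the
#' unsaturated benefit region (total < 1).
#'
#' @param a1,a2 Abilities in \eqn{[0, 1]} of the focal individual and its
#'   partner.
#' @param params An [ability_params()] object.
#' @param tol Convergence tolerance on the effort change per sweep.
#' @param max_iter Iteration cap for the alternating sweep.
#' @return An object of class \code{"nash_solution"}: list with
#'   \code{a_focal}, \code{a_partner}, \code{efforts} (fields \code{e_focal},
#'   \code{e_partner}, \code{total}), \code{payoff_focal},
#'   \code{payoff_partner}, \code{foc_residuals}, \code{iterations},
#'   \code{converged}.
#' @examples
#' nash_efforts(1, 0, ability_params(p = 2)) # efforts 0.4 / 0.2
#' @export
nash_efforts <- function(a1, a2, params, tol = 1e-10, max_iter = 10000L) {
  params <- as_ability_params(params)
  check_ability(a1, "a1")
  check_ability(a2, "a2")
  stopifnot(length(a1) == 1L, length(a2) == 1L)
  sol <- solve_nash_pairs(a1, a2, params, tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    stop("Nash solver failed to converge for a1 = ", format(a1), ", a2 = ",
         format(a2), ", p = ", format(params$p),
         " (", sol$iterations, " iterations, max FOC residual ",
         format(max(abs(c(sol$foc1, sol$foc2)))), ")", call. = FALSE)
  }
  structure(
    list(
      a_focal = a1, a_partner = a2,
      efforts = list(e_focal = sol$e1, e_partner = sol$e2,
                     total = sol$e1 + sol$e2),
      payoff_focal = payoff(a1, sol$e1, sol$e2, params),
      payoff_partner = payoff(a2, sol$e2, sol$e1, params),
      foc_residuals = c(focal = sol$foc1, partner = sol$foc2),
      iterations = sol$iterations,
      converged = sol$converged,
      params = params
    ),
    class = "nash_solution"
  )
}

#' @export
print.nash_solution <- function(x, ...) {
  cat("Nash equilibrium of the ability game (p =", format(x$params$p), ")\n")
  cat(sprintf("  focal   a = %-6s effort = %.6f  payoff = %.6f\n",
              format(x$a_focal), x$efforts$e_focal, x$payoff_focal))
  cat(sprintf("  partner a = %-6s effort = %.6f  payoff = %.6f\n",
              format(x$a_partner), x$efforts$e_partner, x$payoff_partner))
  cat(sprintf("  total effort %.6f; converged in %d sweeps (max |FOC| %.2e)\n",
              x$efforts$total, x$iterations, max(abs(x$foc_residuals))))
  invisible(x)
}

#' Slope of the best-response function (responsiveness)
#'
#' How strongly an individual adjusts its effort when the partner's effort
#' changes: the derivative of [best_response()] with respect to
#' \code{e_partner}, obtained by implicit differentiation of the first-order
#' condition,
#' \deqn{\frac{dr}{de} = \frac{-2}{2 + (2 - a)\, p (p - 1)\, r^{p - 2}},}
#' always in \eqn{(-1, 0)}: individuals partially — never fully — compensate
#' for a drop in partner effort. The magnitude of this slope is the
#' "responsiveness" that drives selection against ability when costs
#' decelerate slowly (small \eqn{p}).
#'
#' @inheritParams best_response
#' @return The slope, a dimensionless value in \eqn{(-1, 0)}. If the best
#'   response is at the corner \eqn{r = 0} (saturated benefit) the slope is
#'   returned as 0 with attribute \code{corner = TRUE}.
#' @examples
#' response_slope(a = 0.5, e_partner = 0.2, ability_params(p = 2)) # -0.4
#' @export
response_slope <- function(a, e_partner, params) {
  params <- as_ability_params(params)
  check_ability(a)
  check_effort(e_partner, "e_partner")
  r <- best_response(a, e_partner, params)
  p <- params$p
  slope <- ifelse(r > 0, -2 / (2 + (2 - a) * p * (p - 1) * r^(p - 2)), 0)
  if (any(r == 0)) attr(slope, "corner") <- r == 0
  slope
}

#' Optimal effort and payoff in a game against nature
#'
#' The baseline without social feedback: the focal individual best-responds
#' to a fixed environmental effort that does not react back. The resulting
#' payoff is strictly increasing in ability (envelope theorem: its derivative
#' with respect to \eqn{a} equals \eqn{e^{*p} > 0} whenever effort is
#' positive), so in a game against nature selection always favours higher
#' ability — the contrast case for the social game.
#'
#' @param a Ability in \eqn{[0, 1]}.
#' @param e_env Fixed environmental (non-responding partner) effort.
#' @param params An [ability_params()] object.
#' @return A list with \code{effort} and \code{payoff}.
#' @examples
#' solo_optimum(a = 0.5, e_env = 0, ability_params(p = 2)) # effort 0.4, payoff 0.4
#' @export
solo_optimum <- function(a, e_env, params) {
  params <- as_ability_params(params)
  r <- best_response(a, e_env, params)
  list(effort = r, payoff = payoff(a, r, e_env, params))
}
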