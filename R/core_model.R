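#' Common benefit of the public goods game
#'
#' The benefit accruing to both partners as a function of their total effort:
#' \eqn{B(e_{tot}) = 2 e_{tot} - e_{tot}^2} for \eqn{e_{tot} < 1}, saturating
#' at \eqn{B = 1} for \eqn{e_{tot} \ge 1}. Increasing, concave, continuous.
#'
#' @param e_tot Total effort of the pair, nonnegative. Vectorised.
#' @return Benefit in payoff units, in \eqn{[0, 1]}.
#' @examples
#' benefit(c(0, 0.5, 1, 1.5))
#' @export
benefit <- function(e_tot) {
  check_effort(e_tot, "e_tot")
  ifelse(e_tot < 1, 2 * e_tot - e_tot^2, 1)
}

#' Marginal benefit of total effort
#'
#' One-sided derivative of [benefit()]: \eqn{2 - 2 e_{tot}} below the
#' saturation point, 0 at and beyond it (right-derivative convention at the
#' kink \eqn{e_{tot} = 1}; Nash totals are strictly below 1, so the
#' convention never binds at equilibrium).
#'
#' @inheritParams benefit
#' @return Marginal benefit (payoff units per unit effort). Vectorised.
#' @export
benefit_slope <- function(e_tot) {
  check_effort(e_tot, "e_tot")
  ifelse(e_tot < 1, 2 - 2 * e_tot, 0)
}

#' Private cost of effort
#'
#' \eqn{K(a, e) = (2 - a) e^p}: accelerating in effort (\eqn{p > 1}) and
#' decreasing in ability, so high-ability individuals have a comparative
#' advantage — their marginal cost of extra effort is lower.
#'
#' @param a Ability in \eqn{[0, 1]}. Vectorised (recycled against \code{e}).
#' @param e Effort, nonnegative. \code{0^p} is taken as 0 (continuous
#'   extension).
#' @param params An [ability_params()] object.
#' @return Cost in payoff units.
#' @examples
#' cost(a = 1, e = 1, ability_params(p = 2))
#' @export
cost <- function(a, e, params) {
  params <- as_ability_params(params)
  check_ability(a)
  check_effort(e)
  (2 - a) * e^params$p
}

#' Payoff of one player in the public goods game
#'
#' \eqn{W_a(e, e') = B(e + e') - K(a, e)}: the focal individual receives the
#' common benefit of the summed efforts and alone pays the cost of its own
#' effort.
#'
#' @param a_self Focal ability in \eqn{[0, 1]}.
#' @param e_self Focal effort, nonnegative.
#' @param e_partner Partner effort, nonnegative.
#' @param params An [ability_params()] object.
#' @return Payoff in payoff units. Vectorised over the first three arguments.
#' @examples
#' payoff(a_self = 1, e_self = 0.4, e_partner = 0.2, ability_params(p = 2))
#' @export
payoff <- function(a_self, e_self, e_partner, params) {
  params <- as_ability_params(params)
  check_effort(e_partner, "e_partner")
  benefit(e_self + e_partner) - cost(a_self, e_self, params)
}
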