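#' Model parameters for the ability game
#'
#' Bundles the parameters of the two-player public goods game in which a
#' heritable ability trait \eqn{a \in [0, 1]} lowers the marginal cost of
#' effort. The common benefit is \eqn{B(e_{tot}) = 2 e_{tot} - e_{tot}^2} for
#' \eqn{e_{tot} < 1} and saturates at 1 beyond; the private cost is
#' \eqn{K(a, e) = (2 - a) e^p} with cost exponent \eqn{p > 1}.
#'
#' @param p Cost exponent, strictly greater than 1. Values of \code{p} within
#'   \code{1e-6} of 1 are rejected: the cost curvature vanishes there and the
#'   best-response problem becomes ill-conditioned.
#'
#' @return An object of class \code{"ability_params"}: a list with fields
#'   \code{p}, \code{saturation_total} (fixed at 1), \code{ability_min} (0)
#'   and \code{ability_max} (1).
#'
#' @examples
#' par <- ability_params(p = 1.25)
#' par$p
#' @export
ability_params <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p)) {
    stop("`p` must be a single finite number", call. = FALSE)
  }
  if (p < 1 + 1e-6) {
    stop("cost exponent `p` must exceed 1 (got ", format(p),
         "); values within 1e-6 of 1 are rejected as ill-conditioned",
         call. = FALSE)
  }
  structure(
    list(p = p, saturation_total = 1, ability_min = 0, ability_max = 1),
    class = "ability_params"
  )
}

#' @export
print.ability_params <- function(x, ...) {
  cat("Ability-game parameters\n")
  cat("  cost exponent p  :", format(x$p), "\n")
  cat("  benefit saturates at total effort", format(x$saturation_total), "\n")
  cat("  ability bounds   : [", x$ability_min, ",", x$ability_max, "]\n")
  invisible(x)
}

## internal: coerce/validate a params argument
as_ability_params <- function(params) {
  if (inherits(params, "ability_params")) return(params)
  if (is.numeric(params) && length(params) == 1L) return(ability_params(params))
  stop("`params` must be an ability_params object (see ability_params())",
       call. = FALSE)
}

check_ability <- function(a, name = "a") {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("`", name, "` must be finite numeric", call. = FALSE)
  }
  if (any(a < 0 | a > 1)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(a)
}

check_effort <- function(e, name = "e") {
  if (!is.numeric(e) || any(!is.finite(e))) {
    stop("`", name, "` must be finite numeric", call. = FALSE)
  }
  if (any(e < 0)) {
    stop("`", name, "` must be nonnegative", call. = FALSE)
  }
  invisible(e)
}
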