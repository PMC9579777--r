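#' Invasion fitness of a rare mutant
#'
#' The payoff of a rare mutant of ability \code{a_mut} in a resident
#' population of ability \code{a_res}: the mutant almost always pairs with a
#' resident, plays the Nash equilibrium of that pairing, and receives
#' \deqn{V(\tilde a, a) = B(e^*(\tilde a, a) + e^*(a, \tilde a)) -
#'   K(\tilde a, e^*(\tilde a, a)).}
#'
#' @param a_mut Mutant ability in \eqn{[0, 1]}. Vectorised (recycled with
#'   \code{a_res}).
#' @param a_res Resident ability in \eqn{[0, 1]}.
#' @param params An [ability_params()] object.
#' @return Invasion fitness in payoff units.
#' @examples
#' invasion_fitness(1, 0, ability_params(p = 2)) # 0.68
#' @export
invasion_fitness <- function(a_mut, a_res, params) {
  params <- as_ability_params(params)
  check_ability(a_mut, "a_mut")
  check_ability(a_res, "a_res")
  sol <- solve_nash_pairs(a_mut, a_res, params)
  if (!sol$converged) {
    stop("Nash solver failed inside invasion_fitness", call. = FALSE)
  }
  payoff(rep_len(a_mut, length(sol$e1)), sol$e1, sol$e2, params)
}

#' Selection gradient on ability
#'
#' The derivative of invasion fitness in the mutant direction evaluated at
#' the resident value, \eqn{D(a) = \partial V(\tilde a, a) / \partial \tilde
#' a |_{\tilde a = a}}. Its sign gives the direction of evolution of the
#' resident trait under adaptive dynamics. Computed by central finite
#' differences (second-order one-sided stencils at the trait bounds 0 and 1).
#'
#' @param a_res Resident ability (scalar or vector) in \eqn{[0, 1]}.
#' @param params An [ability_params()] object.
#' @param fd_step Finite-difference step for the mutant direction.
#' @return Selection gradient in payoff units per unit ability, same length
#'   as \code{a_res}.
#' @examples
#' selection_gradient(0.5, ability_params(p = 2)) # 12/343, selection upward
#' @export
selection_gradient <- function(a_res, params, fd_step = 1e-5) {
  params <- as_ability_params(params)
  check_ability(a_res, "a_res")
  h <- fd_step
  vapply(a_res, function(a) {
    if (a - h < 0) {
      ## one-sided, second order: (-3 f(a) + 4 f(a+h) - f(a+2h)) / (2h)
      v0 <- invasion_fitness(a, a, params)
      v1 <- invasion_fitness(a + h, a, params)
      v2 <- invasion_fitness(a + 2 * h, a, params)
      (-3 * v0 + 4 * v1 - v2) / (2 * h)
    } else if (a + h > 1) {
      v0 <- invasion_fitness(a, a, params)
      v1 <- invasion_fitness(a - h, a, params)
      v2 <- invasion_fitness(a - 2 * h, a, params)
      (3 * v0 - 4 * v1 + v2) / (2 * h)
    } else {
      vp <- invasion_fitness(a + h, a, params)
      vm <- invasion_fitness(a - h, a, params)
      (vp - vm) / (2 * h)
    }
  }, numeric(1))
}

#' Selection gradient over an ability grid
#'
#' Applies [selection_gradient()] pointwise over a grid of resident
#' abilities; this is the data behind the strength-and-direction-of-selection
#' curves of the invasion analysis.
#'
#' @param grid Strictly ascending ability values in \eqn{[0, 1]}. Defaults to
#'   a uniform 101-point grid.
#' @param params An [ability_params()] object.
#' @param fd_step Finite-difference step passed to [selection_gradient()].
#' @return An object of class \code{"gradient_curve"}: list with
#'   \code{ability_grid}, \code{gradient_values}, \code{fd_step},
#'   \code{params}.
#' @export
gradient_curve <- function(grid = seq(0, 1, length.out = 101), params,
                           fd_step = 1e-5) {
  params <- as_ability_params(params)
  check_ability(grid, "grid")
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly ascending with at least 2 points",
         call. = FALSE)
  }
  structure(
    list(ability_grid = grid,
         gradient_values = selection_gradient(grid, params, fd_step),
         fd_step = fd_step, params = params),
    class = "gradient_curve"
  )
}

#' @export
print.gradient_curve <- function(x, ...) {
  cat("Selection gradient curve (p =", format(x$params$p), ",",
      length(x$ability_grid), "grid points)\n")
  sgn <- sign(x$gradient_values)
  cat("  gradient sign: ", sum(sgn > 0), "positive,", sum(sgn < 0),
      "negative,", sum(sgn == 0), "zero\n")
  cat("  range:", format(range(x$gradient_values), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.gradient_curve <- function(x, ...) {
  graphics::plot(x$ability_grid, x$gradient_values, type = "l",
                 xlab = "resident ability a",
                 ylab = "selection gradient dV/da_mut",
                 main = sprintf("Selection on ability (p = %s)",
                                format(x$params$p)), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Pairwise invasibility plot grid
#'
#' Computes \eqn{\Delta(\tilde a, a) = V(\tilde a, a) - V(a, a)} on a mutant
#' x resident ability grid. Positive entries mean the rare mutant can invade
#' the resident population; the sign map is the pairwise invasibility plot.
#'
#' @param resident_grid,mutant_grid Ascending ability values in
#'   \eqn{[0, 1]}. Default 201-point uniform grids.
#' @param params An [ability_params()] object.
#' @return An object of class \code{"pip_grid"}: list with
#'   \code{resident_grid}, \code{mutant_grid}, \code{delta_matrix} (rows =
#'   mutants, columns = residents), \code{params}. The diagonal (where the
#'   two grids coincide) is zero to solver precision.
#' @export
pip_grid <- function(resident_grid = seq(0, 1, length.out = 201),
                     mutant_grid = seq(0, 1, length.out = 201),
                     params) {
  params <- as_ability_params(params)
  check_ability(resident_grid, "resident_grid")
  check_ability(mutant_grid, "mutant_grid")
  if (any(diff(resident_grid) <= 0) || any(diff(mutant_grid) <= 0)) {
    stop("grids must be strictly ascending", call. = FALSE)
  }
  resident_payoff <- invasion_fitness(resident_grid, resident_grid, params)
  delta <- matrix(NA_real_, nrow = length(mutant_grid),
                  ncol = length(resident_grid))
  for (j in seq_along(resident_grid)) {
    vm <- invasion_fitness(mutant_grid, rep(resident_grid[j],
                                            length(mutant_grid)), params)
    delta[, j] <- vm - resident_payoff[j]
  }
  structure(
    list(resident_grid = resident_grid, mutant_grid = mutant_grid,
         delta_matrix = delta, params = params),
    class = "pip_grid"
  )
}

#' @export
print.pip_grid <- function(x, ...) {
  cat("Pairwise invasibility grid (p =", format(x$params$p), "):",
      length(x$mutant_grid), "mutant x", length(x$resident_grid),
      "resident abilities\n")
  cat("  fraction of (mutant, resident) pairs where the mutant invades:",
      format(mean(x$delta_matrix > 0), digits = 3), "\n")
  invisible(x)
}

#' @export
plot.pip_grid <- function(x, ...) {
  graphics::image(x$resident_grid, x$mutant_grid, t(x$delta_matrix > 0),
                  col = c("white", "grey60"),
                  xlab = "resident ability a", ylab = "mutant ability",
                  main = sprintf("PIP (p = %s); grey = mutant invades",
                                 format(x$params$p)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Classify a singular point of the adaptive dynamics
#'
#' Given an interior singular ability (where the selection gradient
#' vanishes) or a trait boundary, determines
#' \itemize{
#'   \item convergence stability: nearby residents evolve towards the point
#'     (the gradient's slope across the point, estimated from evaluations at
#'     \code{a_star +- delta_conv}, is negative);
#'   \item evolutionary stability: the point is a local fitness maximum in
#'     the mutant direction (\eqn{\partial^2 V / \partial \tilde a^2 < 0},
#'     by a second-order central difference with step \code{fd_step2}).
#' }
#' A convergence-stable point with positive mutant-direction curvature is a
#' branching point: selection drives the population to it and then becomes
#' disruptive, favouring divergence into two trait clusters. The two
#' derivatives are taken in different directions of the \eqn{(\tilde a, a)}
#' plane — conflating them would make branching points impossible.
#'
#' @param a_star The singular ability, in \eqn{[0, 1]}. Interior points must
#'   satisfy \code{|selection_gradient(a_star)| < gradient_tol}.
#' @param params An [ability_params()] object.
#' @param fd_step Step for the gradient evaluations.
#' @param fd_step2 Step for the mutant-direction second difference.
#' @param delta_conv Offset for the convergence-stability slope estimate.
#' @param gradient_tol Tolerance defining "singular" for interior points.
#' @return An object of class \code{"singular_point"}: list with
#'   \code{location}, \code{gradient_at}, \code{second_deriv_invasion},
#'   \code{convergence_stable}, \code{evolutionarily_stable}, \code{label}
#'   (one of \code{boundary_attractor_low}, \code{boundary_attractor_high},
#'   \code{css}, \code{branching_point}, \code{repeller}).
#' @export
classify_singular <- function(a_star, params, fd_step = 1e-5,
                              fd_step2 = 1e-4, delta_conv = 1e-3,
                              gradient_tol = 1e-6) {
  params <- as_ability_params(params)
  check_ability(a_star, "a_star")
  g0 <- selection_gradient(a_star, params, fd_step)
  boundary <- a_star <= 0 || a_star >= 1
  if (!boundary && abs(g0) >= gradient_tol) {
    stop("classify_singular() called on a non-singular interior point: ",
         "|gradient| = ", format(abs(g0)), " at a = ", format(a_star),
         call. = FALSE)
  }
  if (boundary) {
    lab <- if (a_star <= 0) "boundary_attractor_low" else "boundary_attractor_high"
    return(structure(
      list(location = a_star, gradient_at = g0,
           second_deriv_invasion = NA_real_,
           convergence_stable = if (a_star <= 0) g0 < 0 else g0 > 0,
           evolutionarily_stable = NA, label = lab, params = params),
      class = "singular_point"
    ))
  }
  ## convergence stability: resident-direction slope of the gradient
  g_lo <- selection_gradient(max(0, a_star - delta_conv), params, fd_step)
  g_hi <- selection_gradient(min(1, a_star + delta_conv), params, fd_step)
  conv <- (g_hi - g_lo) < 0
  ## evolutionary stability: mutant-direction curvature of V at the point
  h <- fd_step2
  v0 <- invasion_fitness(a_star, a_star, params)
  vp <- invasion_fitness(a_star + h, a_star, params)
  vm <- invasion_fitness(a_star - h, a_star, params)
  d2 <- (vp - 2 * v0 + vm) / h^2
  ess <- d2 < 0
  lab <- if (conv && d2 > 0) "branching_point"
         else if (conv) "css"
         else "repeller"
  structure(
    list(location = a_star, gradient_at = g0, second_deriv_invasion = d2,
         convergence_stable = conv, evolutionarily_stable = ess,
         label = lab, params = params),
    class = "singular_point"
  )
}

#' @export
print.singular_point <- function(x, ...) {
  cat(sprintf("Singular point at a = %.6f [%s]\n", x$location, x$label))
  cat(sprintf("  gradient %.3e; mutant-direction curvature %s\n",
              x$gradient_at,
              if (is.na(x$second_deriv_invasion)) "NA (boundary)"
              else format(x$second_deriv_invasion, digits = 4)))
  cat("  convergence stable:", x$convergence_stable,
      "| evolutionarily stable:",
      if (is.na(x$evolutionarily_stable)) "NA" else x$evolutionarily_stable,
      "\n")
  invisible(x)
}

#' Find the attractors of the adaptive dynamics of ability
#'
#' Scans the selection gradient over \eqn{[0, 1]}, reports the boundaries as
#' attractors when the gradient points into them (negative at 0, positive at
#' 1), refines every interior sign change by bisection to
#' \eqn{|gradient| < 10^{-8}}, and classifies each interior root with
#' [classify_singular()]. Near-zero plateaus of the gradient (all scan values
#' within \code{plateau_tol} of 0 on consecutive points) are reported in a
#' \code{diagnostics} attribute rather than collapsed into roots.
#'
#' @param params An [ability_params()] object.
#' @param grid_resolution Number of scan points over \eqn{[0, 1]}.
#' @param fd_step Finite-difference step for the gradient.
#' @param max_bisect Bisection iteration cap per root.
#' @param plateau_tol Threshold below which scan values count as a plateau.
#' @return A list of \code{"singular_point"} objects (possibly containing
#'   boundary attractors), classed \code{"singular_points"}.
#' @examples
#' \donttest{
#' find_attractors(ability_params(p = 1.5), grid_resolution = 51)
#' }
#' @export
find_attractors <- function(params, grid_resolution = 201, fd_step = 1e-5,
                            max_bisect = 50L, plateau_tol = 1e-12) {
  params <- as_ability_params(params)
  grid <- seq(0, 1, length.out = grid_resolution)
  g <- selection_gradient(grid, params, fd_step)
  out <- list()
  if (g[1] < 0) {
    out <- c(out, list(classify_singular(0, params, fd_step)))
  }
  plateau <- which(abs(g) < plateau_tol)
  ## interior sign changes
  s <- sign(g)
  flip <- which(s[-1] * s[-length(s)] < 0)
  for (i in flip) {
    lo <- grid[i]; hi <- grid[i + 1]
    g_lo <- g[i]
    root <- NA_real_
    for (k in seq_len(max_bisect)) {
      mid <- 0.5 * (lo + hi)
      g_mid <- selection_gradient(mid, params, fd_step)
      if (abs(g_mid) < 1e-8) {
        root <- mid
        break
      }
      if (sign(g_mid) == sign(g_lo)) {
        lo <- mid; g_lo <- g_mid
      } else {
        hi <- mid
      }
    }
    if (is.na(root)) root <- 0.5 * (lo + hi)
    out <- c(out, list(classify_singular(root, params, fd_step,
                                         gradient_tol = 1e-6)))
  }
  if (g[length(g)] > 0) {
    out <- c(out, list(classify_singular(1, params, fd_step)))
  }
  if (length(plateau)) {
    attr(out, "diagnostics") <- paste0(
      "gradient within ", format(plateau_tol), " of zero at ",
      length(plateau), " scan point(s); possible plateau")
  }
  class(out) <- "singular_points"
  out
}

#' @export
print.singular_points <- function(x, ...) {
  cat(length(x), "singular point(s) / attractor(s):\n")
  for (s in x) print(s)
  if (!is.null(attr(x, "diagnostics"))) {
    cat("diagnostics:", attr(x, "diagnostics"), "\n")
  }
  invisible(x)
}
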