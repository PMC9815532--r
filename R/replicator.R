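#' Replicator-dynamics vector field
#'
#' The four replicator differential equations of the game. Each
#' population's mixing probability grows in proportion to the payoff
#' advantage of its first strategy over the population average:
#' \deqn{dx/dt = x(1-x)G(y,z,w), \quad dy/dt = y(1-y)H(x,z,w),}
#' \deqn{dz/dt = z(1-z)P(x,y), \quad dw/dt = w(1-w)(Cm-Cw),}
#' with the incentive differences of
#' \code{\link{incentive_difference}}. Every corner of the unit hypercube
#' is a fixed point, and the field never points out of \eqn{[0,1]^4}.
#'
#' States slightly outside \eqn{[0,1]} (integrator round-off) are
#' evaluated as-is; projection back to the cube is the integrator's job.
#'
#' @param p a \code{\link{game_params}} object.
#' @param s state \code{c(x, y, z, w)}.
#' @return Named numeric vector \code{c(dx, dy, dz, dw)}.
#' @examples
#' replicator_rhs(game_params(), c(0.5, 0.5, 0.5, 0.5))
#' @export
replicator_rhs <- function(p, s) {
  s <- as.numeric(s)
  g <- vapply(.players, function(pl) incentive_difference(p, s, pl), numeric(1))
  stats::setNames(s * (1 - s) * g, c("dx", "dy", "dz", "dw"))
}

#' Own-strategy derivatives of the replicator field
#'
#' The partial derivative of each replicator equation with respect to its
#' own state variable, holding the others fixed:
#' \eqn{(1-2x)G}, \eqn{(1-2y)H}, \eqn{(1-2z)P}, \eqn{(1-2w)(Cm-Cw)}.
#' At a corner these are exactly the diagonal entries (and eigenvalues) of
#' the system Jacobian, which is what Lyapunov first-method classification
#' uses.
#'
#' @inheritParams replicator_rhs
#' @return Named numeric vector of the four own-strategy derivatives.
#' @export
replicator_rhs_derivative <- function(p, s) {
  s <- as.numeric(s)
  g <- vapply(.players, function(pl) incentive_difference(p, s, pl), numeric(1))
  stats::setNames((1 - 2 * s) * g, c("dFx_dx", "dFy_dy", "dFz_dz", "dFw_dw"))
}
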