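#' Exact solution for the quadratic potential
#'
#' For \eqn{W(x) = x^2} in 1D with unit-mass initial data, the velocity is
#' \eqn{u(t,x) = -2(x - \lambda)} with \eqn{\lambda = \int x \rho^0} the
#' (conserved) center of mass, and the method of characteristics gives
#' \deqn{\rho(t, x) = \rho^0\big((x - \lambda) e^{2t} + \lambda\big) e^{2t}:}
#' the profile contracts uniformly toward \eqn{\lambda} at rate
#' \eqn{e^{-2t}}, and the backward Jacobian is the spatial constant
#' \eqn{e^{-2t}}. Mass and center of mass are conserved for all `t`.
#'
#' @param rho0 unit-mass initial density (function with a `support`
#'   attribute). A deviation of the mass from 1 beyond `1e-6` is an error,
#'   since the closed form assumes a probability density.
#' @param t time (`>= 0`).
#' @param x evaluation points (numeric vector).
#' @param lambda optional center of mass; computed by quadrature from `rho0`
#'   when omitted.
#' @return Density values \eqn{\rho(t, x)}.
#' @export
exact_quadratic <- function(rho0, t, x, lambda = NULL) {
  stopifnot(is.function(rho0), is.numeric(t), length(t) == 1, t >= 0)
  support <- attr(rho0, "support")
  if (is.null(support)) stop("rho0 must carry a 'support' attribute")
  mass <- gl_integrate(rho0, support[1], support[2], panels = 400L, nodes = 10L)
  if (abs(mass - 1) > 1e-6) {
    stop(sprintf("exact_quadratic requires unit mass (got %.8g); normalize rho0",
                 mass))
  }
  lambda <- lambda %||% center_of_mass(rho0)
  rho0((x - lambda) * exp(2 * t) + lambda) * exp(2 * t)
}

#' Smooth-particle (fixed-width) density reconstruction
#'
#' The classical SP reconstruction with a uniform particle size
#' \eqn{\varepsilon}:
#' \deqn{\rho_{SP}(x) = \sum_k \omega_k \frac{1}{\varepsilon}
#'       \varphi\!\left(\frac{x - x_k}{\varepsilon}\right).}
#' Positions and weights are shared with the LTP run (the baseline differs
#' only in the reconstruction, which ignores the deformations), isolating
#' the effect of shape transport. Accuracy is sensitive to \eqn{\varepsilon}
#' relative to the inter-particle distance: too small oscillates, too large
#' over-spreads.
#'
#' @param positions particle positions (numeric vector, 1D).
#' @param weights particle weights.
#' @param eps uniform particle width (`> 0`).
#' @param shape an [ltp_shape()].
#' @param points evaluation points.
#' @return Density values at `points`.
#' @export
sp_density <- function(positions, weights, eps, shape = ltp_shape("hat"),
                       points) {
  stopifnot(is.numeric(positions), is.numeric(weights),
            length(positions) == length(weights),
            is.numeric(eps), length(eps) == 1, eps > 0,
            inherits(shape, "ltp_shape"))
  phi <- shape$evaluate1(outer(points, positions, "-") / eps)
  as.vector(phi %*% weights) / eps
}
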