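#' Particle ensembles
#'
#' The LTP state at a discrete time: particle positions \eqn{x_k}, constant
#' weights \eqn{\omega_k}, deformation matrices \eqn{D_k} (approximating the
#' backward flow Jacobian at the particle) and volumes \eqn{h_k}, together
#' with the initial grid spacing `h` and the reference shape. The
#' reconstructed density is
#' \deqn{\rho_h(x) = \sum_k \frac{\omega_k}{h_k}\,
#'       \varphi\!\left(\frac{D_k (x - x_k)}{h}\right).}
#' The identity \eqn{h_k \det(D_k) = h^d} holds at every step (volumes are
#' the reciprocal determinants of the accumulated deformations, scaled by the
#' initial cell volume) and is enforced by [validate_ensemble()].
#'
#' @param x positions: numeric vector (1D) or an N x d matrix.
#' @param w particle weights (constant in time; may be negative under the
#'   dual-kernel weighting).
#' @param D deformation matrices as a `d x d x N` array (1D: a numeric vector
#'   of scalars is accepted). Default: identity for every particle.
#' @param hvol particle volumes. Default `h^d`.
#' @param h initial grid spacing.
#' @param shape an [ltp_shape()].
#' @param dt time step used to evolve the ensemble (`NA` before the first step).
#' @param n time index.
#' @return An object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(x, w, D = NULL, hvol = NULL, h,
                              shape = ltp_shape("hat"), dt = NA_real_, n = 0L) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  N <- nrow(x)
  d <- ncol(x)
  stopifnot(length(w) == N, is.numeric(h), h > 0, inherits(shape, "ltp_shape"))
  if (is.null(D)) {
    D <- array(diag(d), dim = c(d, d, N))
  } else if (!is.array(D) || length(dim(D)) != 3L) {
    stopifnot(d == 1L, length(D) == N)
    D <- array(as.numeric(D), dim = c(1L, 1L, N))
  }
  stopifnot(all(dim(D) == c(d, d, N)))
  if (is.null(hvol)) hvol <- rep_len(h^d, N)
  stopifnot(length(hvol) == N, all(hvol > 0))
  ens <- structure(
    list(x = x, w = as.numeric(w), D = D, hvol = as.numeric(hvol),
         h = h, shape = shape, d = d, n = as.integer(n), dt = dt),
    class = "particle_ensemble"
  )
  validate_ensemble(ens)
  ens
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf(
    "<particle_ensemble>  %d particles (d = %d), h = %g, shape '%s', step n = %d\n",
    n_particles(x), x$d, x$h, x$shape$name, x$n))
  cat(sprintf("  total mass %.6g, volumes in [%.3g, %.3g]\n",
              sum(x$w), min(x$hvol), max(x$hvol)))
  invisible(x)
}

#' Number of particles in an ensemble
#' @param ensemble a [particle_ensemble()].
#' @export
n_particles <- function(ensemble) nrow(ensemble$x)

# det(D_k) for every particle
deformation_dets <- function(ensemble) {
  if (ensemble$d == 1L) {
    ensemble$D[1L, 1L, ]
  } else {
    apply(ensemble$D, 3L, det)
  }
}

#' Validate ensemble invariants
#'
#' Checks positivity of the deformation determinants and the volume identity
#' `hvol * det(D) = h^d` to relative tolerance `tol`.
#'
#' @param ensemble a [particle_ensemble()].
#' @param tol relative tolerance for the volume identity.
#' @return The ensemble, invisibly; errors if an invariant fails.
#' @export
validate_ensemble <- function(ensemble, tol = 1e-10) {
  dets <- deformation_dets(ensemble)
  if (any(dets <= 0)) stop("deformation determinants must be positive")
  rel <- abs(ensemble$hvol * dets - ensemble$h^ensemble$d) / ensemble$h^ensemble$d
  if (any(rel > tol)) {
    stop(sprintf("volume-deformation identity violated (max rel dev %.3g)", max(rel)))
  }
  invisible(ensemble)
}

#' Evaluate the reconstructed LTP density
#'
#' @param ensemble a [particle_ensemble()].
#' @param points numeric vector of 1D evaluation points (or an M x d matrix).
#' @return Density values \eqn{\rho_h} at the points. Only particles whose
#'   deformed support contains a point contribute (the shape vanishes outside
#'   its support).
#' @export
eval_density <- function(ensemble, points) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  if (ensemble$d == 1L) {
    pts <- as.numeric(points)
    xk <- ensemble$x[, 1L]
    Dk <- ensemble$D[1L, 1L, ]
    arg <- outer(pts, xk, "-")
    arg <- sweep(arg, 2L, Dk / ensemble$h, "*")
    phi <- ensemble$shape$evaluate1(arg)
    as.vector(phi %*% (ensemble$w / ensemble$hvol))
  } else {
    if (!is.matrix(points)) points <- matrix(points, ncol = ensemble$d)
    out <- numeric(nrow(points))
    for (k in seq_len(n_particles(ensemble))) {
      z <- sweep(points, 2L, ensemble$x[k, ], "-") %*% t(ensemble$D[, , k]) / ensemble$h
      out <- out + ensemble$w[k] / ensemble$hvol[k] * eval_shape(ensemble$shape, z)
    }
    out
  }
}

#' Per-particle size field
#'
#' In 1D the local particle size is \eqn{h^n(x_k) = h \prod_{m<n} j_k^m},
#' which coincides with the particle volume \eqn{h_k^n}. This is the
#' "particle sizes" diagnostic plotted alongside densities and velocities in
#' the blow-up and steady-state experiments.
#'
#' @param ensemble a 1D [particle_ensemble()].
#' @return Numeric vector of particle sizes.
#' @export
particle_size_field <- function(ensemble) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  if (ensemble$d != 1L) stop("particle_size_field is defined for 1D ensembles")
  ensemble$hvol
}

#' Center of mass
#'
#' \eqn{\sum_k \omega_k x_k / \sum_k \omega_k} for an ensemble, or
#' \eqn{\int x\rho / \int \rho} (by quadrature over the declared support) for
#' a density callable. Conserved exactly by the continuous aggregation flow
#' for even potentials.
#'
#' @param x a [particle_ensemble()] or a 1D density function carrying a
#'   `support` attribute.
#' @param ... unused.
#' @return The center of mass (numeric, length `d`).
#' @export
center_of_mass <- function(x, ...) UseMethod("center_of_mass")

#' @export
center_of_mass.particle_ensemble <- function(x, ...) {
  m <- sum(x$w)
  if (abs(m) < .Machine$double.eps) stop("center of mass undefined: zero total mass")
  as.vector(crossprod(x$x, x$w)) / m
}

#' @export
center_of_mass.function <- function(x, support = attr(x, "support"), ...) {
  if (is.null(support)) stop("density callable must carry a 'support' attribute")
  m <- gl_integrate(x, support[1], support[2], panels = 200L, nodes = 10L)
  if (abs(m) < .Machine$double.eps) stop("center of mass undefined: zero total mass")
  gl_integrate(function(t) t * x(t), support[1], support[2],
               panels = 200L, nodes = 10L) / m
}
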