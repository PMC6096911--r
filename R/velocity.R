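#' Velocity evaluation strategies
#'
#' Each LTP step needs the convolutions \eqn{(\nabla W * \rho_h)(x_k)} (the
#' velocity, with a minus sign) and \eqn{(W'' * \rho_h)(x_k)} (the rate in
#' the Jacobian update) at every particle center. Three strategies are
#' provided:
#' \describe{
#'   \item{`"blob"`}{replace the transformed shapes by a fixed blob
#'     \eqn{\zeta_\varepsilon} and sum the mollified kernel pairwise over
#'     particles: \eqn{u_k = -\sum_{k'} \omega_{k'} \nabla
#'     W_\varepsilon(x_k - x_{k'})}. Cost ~ number of particles squared.}
#'   \item{`"quadrature"`}{tabulate \eqn{\rho_h} on a grid, then apply a
#'     composite-trapezoid quadrature to the convolution integral at each
#'     particle. Cost ~ particles x grid nodes.}
#'   \item{`"grid_fft"`}{same quadrature but evaluated at the grid nodes
#'     themselves, computed as one zero-padded (linear, non-periodic) FFT
#'     convolution, then interpolated linearly to the particles. Cost ~ grid
#'     nodes x log(grid nodes).}
#' }
#' On smooth problems the three agree up to the blob/grid resolution, and
#' they are interchangeable in [ltp_step()].
#'
#' @param strategy `"quadrature"`, `"blob"` or `"grid_fft"`.
#' @param spacing grid spacing for the grid-based strategies; default `h/4`
#'   at evaluation time.
#' @param eps blob width for the blob strategy; default `h`.
#' @param mollifier blob profile for the blob strategy; defaults to the
#'   ensemble's reference shape.
#' @return An object of class `velocity_evaluator`.
#' @export
velocity_evaluator <- function(strategy = c("quadrature", "blob", "grid_fft"),
                               spacing = NULL, eps = NULL, mollifier = NULL) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, spacing = spacing, eps = eps,
                 mollifier = mollifier),
            class = "velocity_evaluator")
}

#' @export
print.velocity_evaluator <- function(x, ...) {
  cat(sprintf("<velocity_evaluator '%s'>\n", x$strategy))
  invisible(x)
}

#' Convolution grid for the grid-based strategies
#'
#' A uniform grid covering the union of all (deformed) particle supports plus
#' one kernel support radius, with composite-trapezoid quadrature weights.
#' Nodes are offset by half a spacing from the particle lattice so that grid
#' nodes do not coincide with particle centers (where singular kernels would
#' be evaluated at 0).
#'
#' @param ensemble a 1D [particle_ensemble()].
#' @param spacing grid spacing; default `h/4`.
#' @return An object of class `eval_grid` with fields `nodes`, `spacing`,
#'   `alpha` (quadrature weights) and `bounds`.
#' @export
velocity_grid <- function(ensemble, spacing = NULL) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  if (ensemble$d != 1L) stop("grid-based velocity strategies are 1D")
  spacing <- spacing %||% (ensemble$h / 4)
  halfw <- ensemble$shape$support_radius * ensemble$h /
    abs(ensemble$D[1L, 1L, ])
  lo <- min(ensemble$x[, 1L] - halfw)
  hi <- max(ensemble$x[, 1L] + halfw)
  pad <- max(halfw)
  nodes <- seq(lo - pad + spacing / 2, hi + pad, by = spacing)
  n <- length(nodes)
  alpha <- rep(spacing, n)
  alpha[c(1L, n)] <- spacing / 2
  structure(list(nodes = nodes, spacing = spacing, alpha = alpha,
                 bounds = c(nodes[1L], nodes[n])),
            class = "eval_grid")
}

# strategy dispatch used by ltp_step(); returns list(u, hess) at particles
evaluate_convolutions <- function(evaluator, ensemble, potential) {
  stopifnot(inherits(evaluator, "velocity_evaluator"))
  switch(evaluator$strategy,
    blob = velocity_blob(ensemble, potential,
                         eps = evaluator$eps %||% ensemble$h,
                         mollifier = evaluator$mollifier,
                         derivatives = TRUE),
    quadrature = velocity_quadrature(ensemble, potential,
                                     grid = velocity_grid(ensemble, evaluator$spacing),
                                     derivatives = TRUE),
    grid_fft = velocity_grid_fft(ensemble, potential,
                                 grid = velocity_grid(ensemble, evaluator$spacing),
                                 derivatives = TRUE)
  )
}

#' Blob (smoothed-kernel) velocity
#'
#' Pairwise particle sum with the mollified kernel:
#' \eqn{u_k = -\sum_{k'} \omega_{k'} \nabla W_\varepsilon(x_k - x_{k'})}
#' with \eqn{W_\varepsilon = W * \zeta_\varepsilon}. The self term uses
#' \eqn{\nabla W_\varepsilon(0) = 0} (odd kernel). With
#' `derivatives = TRUE` the mollified second-derivative convolution is
#' returned as well.
#'
#' @param ensemble a 1D [particle_ensemble()].
#' @param potential an `ltp_potential`.
#' @param eps blob width (default: the ensemble spacing `h`).
#' @param mollifier blob profile shape; default the ensemble's shape.
#' @param derivatives also return the \eqn{W'' * \rho_h} values?
#' @return Velocities at the particle centers (numeric vector), or a list
#'   `list(u, hess)` when `derivatives = TRUE`.
#' @export
velocity_blob <- function(ensemble, potential, eps = NULL, mollifier = NULL,
                          derivatives = FALSE) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(potential, "ltp_potential"))
  if (ensemble$d != 1L) stop("velocity_blob currently supports d = 1")
  eps <- eps %||% ensemble$h
  mollifier <- mollifier %||% ensemble$shape
  xk <- ensemble$x[, 1L]
  DX <- outer(xk, xk, "-")
  gfun <- smoothed_grad(potential, mollifier, eps)
  G <- gfun(DX)
  diag(G) <- 0
  u <- -as.vector(G %*% ensemble$w)
  if (!derivatives) return(u)
  hfun <- smoothed_hess(potential, mollifier, eps)
  H <- hfun(DX)
  list(u = u, hess = as.vector(H %*% ensemble$w))
}

# shared core: convolution sums of grad/hess kernels against alpha * rho on
# a grid, evaluated at arbitrary target points by direct summation
conv_direct <- function(targets, nodes, wts, potential, derivatives) {
  DX <- outer(targets, nodes, "-")
  G <- matrix(potential$gradW(DX), nrow = length(targets))
  G[!is.finite(G)] <- 0
  u <- -as.vector(G %*% wts)
  if (!derivatives) return(list(u = u))
  Hm <- matrix(potential$hessW(DX), nrow = length(targets))
  Hm[!is.finite(Hm)] <- 0
  list(u = u, hess = as.vector(Hm %*% wts))
}

#' Grid-quadrature velocity
#'
#' Tabulates \eqn{\rho_h} on the grid and applies the composite-trapezoid
#' rule to the convolution at each particle center:
#' \eqn{u_k = -\sum_j \alpha_j \nabla W(x_k - \chi_j)\rho_h(\chi_j)}.
#' Grid nodes coinciding with a kernel singularity contribute zero (the
#' `gradW(0) = 0` convention; non-finite second-derivative values are
#' likewise dropped).
#'
#' @inheritParams velocity_blob
#' @param grid an [velocity_grid()] covering all particle supports; built
#'   with default spacing `h/4` when omitted.
#' @return As [velocity_blob()].
#' @export
velocity_quadrature <- function(ensemble, potential, grid = NULL,
                                derivatives = FALSE) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(potential, "ltp_potential"))
  grid <- grid %||% velocity_grid(ensemble)
  rho <- eval_density(ensemble, grid$nodes)
  wts <- grid$alpha * rho
  res <- conv_direct(ensemble$x[, 1L], grid$nodes, wts, potential, derivatives)
  if (derivatives) res else res$u
}

#' FFT grid-convolution velocity
#'
#' Evaluates the same quadrature sums as [velocity_quadrature()] but at the
#' grid nodes, \eqn{u_i = -\sum_j \alpha_j \nabla W(\chi_i - \chi_j)
#' \rho_h(\chi_j)}, computed as a single zero-padded linear convolution of
#' the tabulated kernel (lag-0 entry 0 for the odd gradient kernel; the
#' even second-derivative kernel keeps its finite value at lag 0) with
#' \eqn{\alpha_j \rho_j}, then interpolated linearly to the particle centers.
#'
#' @inheritParams velocity_quadrature
#' @param return_grid also return the grid nodes and the grid velocity field.
#' @return As [velocity_blob()]; with `return_grid = TRUE` a list with
#'   components `u`, (`hess`,) `nodes`, `u_grid` (and `hess_grid`).
#' @export
velocity_grid_fft <- function(ensemble, potential, grid = NULL,
                              derivatives = FALSE, return_grid = FALSE) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(potential, "ltp_potential"))
  grid <- grid %||% velocity_grid(ensemble)
  nodes <- grid$nodes
  n <- length(nodes)
  rho <- eval_density(ensemble, nodes)
  wts <- grid$alpha * rho
  m <- seq.int(-(n - 1L), n - 1L)
  g <- potential$gradW(m * grid$spacing)
  g[m == 0L] <- 0
  g[!is.finite(g)] <- 0
  # linear convolution; index i + n - 1 gives sum_j g[i-j] wts[j]
  zg <- stats::convolve(g, rev(wts), type = "open")
  u_grid <- -zg[n:(2L * n - 1L)]
  xk <- ensemble$x[, 1L]
  u <- stats::approx(nodes, u_grid, xout = xk, rule = 2)$y
  out <- list(u = u)
  if (derivatives) {
    hkern <- potential$hessW(m * grid$spacing)
    h0 <- potential$hessW(0)
    hkern[m == 0L] <- if (is.finite(h0)) h0 else 0
    hkern[!is.finite(hkern)] <- 0
    zh <- stats::convolve(hkern, rev(wts), type = "open")
    hess_grid <- zh[n:(2L * n - 1L)]
    out$hess <- stats::approx(nodes, hess_grid, xout = xk, rule = 2)$y
    if (return_grid) out$hess_grid <- hess_grid
  }
  if (return_grid) {
    out$nodes <- nodes
    out$u_grid <- u_grid
    return(out)
  }
  if (derivatives) out else out$u
}
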