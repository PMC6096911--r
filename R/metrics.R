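#' Discrete Lp error between gridded densities
#'
#' Composite-trapezoid discrete \eqn{L^p} norm of `f - g` on a shared
#' evaluation grid; the maximum absolute difference for `p = Inf`.
#'
#' @param f,g density values on the grid nodes.
#' @param p norm order (finite `>= 1`, or `Inf`).
#' @param grid numeric vector of sorted grid nodes.
#' @return The error (non-negative scalar).
#' @export
lp_error <- function(f, g, p = 1, grid) {
  stopifnot(is.numeric(f), is.numeric(g), is.numeric(grid))
  if (length(f) != length(g) || length(f) != length(grid)) {
    stop("f, g and grid must have matching lengths")
  }
  diffs <- abs(f - g)
  if (is.infinite(p)) return(max(diffs))
  stopifnot(p >= 1)
  w <- trapz_weights(grid)
  sum(w * diffs^p)^(1 / p)
}

trapz_weights <- function(grid) {
  n <- length(grid)
  if (n < 2L) stop("grid needs at least two nodes")
  d <- diff(grid)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

# cumulative trapezoid primitive with F(grid[1]) = 0
cumtrapz_vals <- function(f, grid) {
  c(0, cumsum((f[-1L] + f[-length(f)]) / 2 * diff(grid)))
}

#' Bounded-Lipschitz distance between 1D densities
#'
#' For densities on the line the bounded-Lipschitz (flat) distance reduces to
#' the \eqn{L^1} norm of the difference of cumulative distribution functions,
#' \deqn{d_{BL}(\rho_1, \rho_2) = \|F_1 - F_2\|_{L^1}, \qquad
#'       F_i(x) = \int_{-\infty}^x \rho_i.}
#' CDFs are computed by cumulative trapezoid on the grid (assumed to contain
#' the supports of both densities); densities are not renormalized first.
#'
#' @inheritParams lp_error
#' @return The distance (non-negative scalar).
#' @export
d_bl_1d <- function(f, g, grid) {
  stopifnot(length(f) == length(g), length(f) == length(grid))
  F1 <- cumtrapz_vals(f, grid)
  F2 <- cumtrapz_vals(g, grid)
  lp_error(F1, F2, p = 1, grid = grid)
}

#' Fit an empirical convergence order
#'
#' Least-squares slope of `log(error)` against `log(h)` across a sequence of
#' resolutions, as read off a log-log convergence plot.
#'
#' @param hs resolutions (positive, at least 3).
#' @param errors corresponding errors (positive).
#' @return A list with `order` (the slope), `intercept`, and the underlying
#'   `stats::lm` fit.
#' @export
convergence_order <- function(hs, errors) {
  stopifnot(is.numeric(hs), is.numeric(errors), length(hs) == length(errors))
  if (length(hs) < 3L) stop("need >= 3 resolutions to fit a convergence order")
  if (any(hs <= 0) || any(errors <= 0)) {
    stop("resolutions and errors must be positive")
  }
  fit <- stats::lm(log(errors) ~ log(hs))
  co <- stats::coef(fit)
  list(order = unname(co[2L]), intercept = unname(co[1L]), fit = fit)
}

#' Error report between an approximate and a reference density
#'
#' Convenience wrapper computing \eqn{L^1}, \eqn{L^p}, \eqn{L^\infty} and
#' bounded-Lipschitz errors on a shared grid.
#'
#' @inheritParams lp_error
#' @param approx_vals,ref_vals density values on the grid nodes.
#' @return A one-row `data.frame` with columns `l1`, `lp`, `p`, `linf`, `dbl`.
#' @export
density_errors <- function(approx_vals, ref_vals, grid, p = 2) {
  data.frame(
    l1 = lp_error(approx_vals, ref_vals, 1, grid),
    lp = lp_error(approx_vals, ref_vals, p, grid),
    p = p,
    linf = lp_error(approx_vals, ref_vals, Inf, grid),
    dbl = d_bl_1d(approx_vals, ref_vals, grid)
  )
}
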