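#' Interaction potentials
#'
#' An interaction potential `W` drives the aggregation velocity
#' \eqn{u = -\nabla W * \rho}. A potential object bundles `W`, its gradient
#' `gradW`, second derivative `hessW` and Laplacian `laplW` (identical to
#' `hessW` in 1D), plus a singularity classification: a potential is *smooth*
#' when \eqn{\nabla W} is Lipschitz (bounded `hessW`), and *singular* with
#' exponent `alpha` when \eqn{|\nabla W| \lesssim |x|^{-\alpha}} near the
#' origin. By the odd-symmetry convention `gradW(0) = 0` for every radial
#' potential, which removes the particle self-interaction term.
#'
#' @name potentials
#' @details
#' For the power-law family \eqn{W(x) = |x|^a/a} (1D, `a > 1`):
#' `gradW(x) = sign(x)|x|^{a-1}`, `hessW(x) = (a-1)|x|^{a-2}`. The potential
#' is smooth iff `a >= 2`; for `1 < a < 2` it is singular with
#' `alpha = 1 - a` (negative: the gradient is bounded but not Lipschitz, and
#' `hessW` blows up like \eqn{|x|^{-(1+\alpha)}}). `hessW(0)` is the `Inf`
#' sentinel in the singular range; convolution evaluators treat such
#' non-finite kernel values as absent (they arise only on a measure-zero set).
NULL

new_potential <- function(name, W, gradW, hessW, alpha, is_smooth, params = list()) {
  structure(
    list(name = name, W = W, gradW = gradW, hessW = hessW, laplW = hessW,
         alpha = alpha, is_smooth = is_smooth, params = params),
    class = "ltp_potential"
  )
}

#' @export
print.ltp_potential <- function(x, ...) {
  cls <- if (x$is_smooth) "smooth" else
    sprintf("singular (alpha = %g)", x$alpha)
  cat(sprintf("<ltp_potential '%s'>  %s\n", x$name, cls))
  invisible(x)
}

#' @describeIn potentials Quadratic potential \eqn{W(x) = x^2} (1D). Its
#'   aggregation flow contracts uniformly at rate \eqn{e^{-2t}} for unit-mass
#'   data, and admits a closed-form solution (see [exact_quadratic()]).
#' @return An object of class `ltp_potential`.
#' @export
potential_quadratic <- function() {
  new_potential(
    "quadratic",
    W = function(x) x^2,
    gradW = function(x) 2 * x,
    hessW = function(x) rep_len(2, length(x)),
    alpha = NA_real_, is_smooth = TRUE
  )
}

#' @describeIn potentials Attractive power law \eqn{W(x) = |x|^a/a}, `a > 1`.
#' @param a attraction exponent (`a > 1`).
#' @export
potential_power_law <- function(a) {
  if (!is.numeric(a) || length(a) != 1 || a <= 1) {
    stop("power-law exponent must satisfy a > 1")
  }
  new_potential(
    sprintf("power:%g", a),
    W = function(x) abs(x)^a / a,
    gradW = function(x) sign(x) * abs(x)^(a - 1),
    hessW = function(x) (a - 1) * abs(x)^(a - 2),
    alpha = if (a < 2) 1 - a else NA_real_,
    is_smooth = a >= 2,
    params = list(a = a)
  )
}

#' @describeIn potentials Attractive-repulsive potential
#'   \eqn{W(x) = |x|^a/a - |x|^b/b} with `1 < b < a`: long-range attraction,
#'   short-range repulsion. Smooth iff `b >= 2`; for `1 < b < 2` it is
#'   singular with `alpha = 1 - b` (inherited from the more singular term).
#' @param b repulsion exponent (`1 < b < a`).
#' @export
potential_attractive_repulsive <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1 || length(b) != 1 ||
      !(1 < b && b < a)) {
    stop("attractive-repulsive exponents must satisfy 1 < b < a")
  }
  new_potential(
    sprintf("attrep:%g,%g", a, b),
    W = function(x) abs(x)^a / a - abs(x)^b / b,
    gradW = function(x) sign(x) * (abs(x)^(a - 1) - abs(x)^(b - 1)),
    hessW = function(x) (a - 1) * abs(x)^(a - 2) - (b - 1) * abs(x)^(b - 2),
    alpha = if (b < 2) 1 - b else NA_real_,
    is_smooth = b >= 2,
    params = list(a = a, b = b)
  )
}

#' @describeIn potentials Wrap user-supplied callables into a potential
#'   object. `gradW` and `hessW` must be vectorized; `is_smooth` and `alpha`
#'   document the singularity class.
#' @param W,gradW,hessW vectorized callables (see Details).
#' @param alpha singularity exponent or `NA`.
#' @param is_smooth logical.
#' @param name identifier used in printing and manifests.
#' @export
potential_custom <- function(W, gradW, hessW, alpha = NA_real_,
                             is_smooth = TRUE, name = "custom") {
  stopifnot(is.function(W), is.function(gradW), is.function(hessW))
  new_potential(name, W, gradW, hessW, alpha = alpha, is_smooth = is_smooth)
}

#' Parse a potential specification string
#'
#' Accepts `"quadratic"`, `"power:a"` or `"attrep:a,b"` (the forms used in
#' scenario configurations and by the command-line driver), or passes an
#' existing potential object through.
#'
#' @param spec character specification or `ltp_potential`.
#' @return An `ltp_potential`.
#' @export
parse_potential <- function(spec) {
  if (inherits(spec, "ltp_potential")) return(spec)
  stopifnot(is.character(spec), length(spec) == 1)
  if (spec == "quadratic") return(potential_quadratic())
  if (startsWith(spec, "power:")) {
    return(potential_power_law(as.numeric(sub("^power:", "", spec))))
  }
  if (startsWith(spec, "attrep:")) {
    ab <- as.numeric(strsplit(sub("^attrep:", "", spec), ",")[[1]])
    if (length(ab) != 2 || anyNA(ab)) stop("attrep spec must be 'attrep:a,b'")
    return(potential_attractive_repulsive(ab[1], ab[2]))
  }
  stop("unknown potential specification: ", spec)
}

# Shared machinery for mollified derivatives g_eps = g * zeta_eps with
# zeta = a reference shape. Nodes/coefficients of the composite GL rule on the
# mollifier support are precomputed once per returned closure.
smoothed_kernel_fun <- function(g, mollifier, eps, odd) {
  stopifnot(inherits(mollifier, "ltp_shape"))
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) {
    stop("mollifier width eps must be positive")
  }
  R <- mollifier$support_radius
  r <- gl_rule(5L)
  panels <- 8L * ceiling(R)
  breaks <- seq(-R, R, length.out = panels + 1L)
  a <- breaks[-length(breaks)]; b <- breaks[-1L]
  half <- (b - a) / 2; mid <- (a + b) / 2
  s <- as.vector(outer(half, r$x) + mid)            # quadrature nodes in [-R, R]
  coef <- as.vector(outer(half, r$w)) * mollifier$evaluate1(s)
  force(g); force(odd)
  function(x) {
    dims <- dim(x)
    xv <- as.vector(x)
    vals <- matrix(g(outer(xv, eps * s, "-")), nrow = length(xv))
    vals[!is.finite(vals)] <- 0
    out <- as.vector(vals %*% coef)
    if (odd) out[as.vector(x) == 0] <- 0   # odd * even vanishes at 0 exactly
    dim(out) <- dims
    out
  }
}

#' Mollified potential derivatives
#'
#' Returns a callable evaluating \eqn{\nabla W_\varepsilon = \nabla W *
#' \zeta_\varepsilon} (or the mollified second derivative, for
#' [smoothed_hess()]), where \eqn{\zeta_\varepsilon(x) =
#' \varepsilon^{-1}\zeta(x/\varepsilon)} is a symmetric unit-mass blob built
#' from a reference shape. Evaluation is by composite Gauss-Legendre
#' quadrature on the mollifier support; for a symmetric mollifier and odd
#' \eqn{\nabla W} the value at 0 is exactly 0. These are the kernels used by
#' the blob velocity strategy.
#'
#' @param potential an `ltp_potential`.
#' @param mollifier an [ltp_shape()] used as the blob profile \eqn{\zeta}.
#' @param eps blob width \eqn{\varepsilon > 0} (same length unit as `x`).
#' @return A vectorized function of position.
#' @export
smoothed_grad <- function(potential, mollifier = ltp_shape("hat"), eps) {
  stopifnot(inherits(potential, "ltp_potential"))
  smoothed_kernel_fun(potential$gradW, mollifier, eps, odd = TRUE)
}

#' @rdname smoothed_grad
#' @export
smoothed_hess <- function(potential, mollifier = ltp_shape("hat"), eps) {
  stopifnot(inherits(potential, "ltp_potential"))
  smoothed_kernel_fun(potential$hessW, mollifier, eps, odd = FALSE)
}
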