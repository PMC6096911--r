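#' Reference particle shapes
#'
#' A reference shape \eqn{\varphi} is a compactly supported, Lipschitz,
#' non-negative function with unit integral that forms a partition of unity
#' over the integer lattice, \eqn{\sum_k \varphi(x-k) = 1}. Particles are
#' scaled, translated and (as the simulation evolves) linearly deformed copies
#' of the reference shape. Two shapes are built in:
#' \describe{
#'   \item{`"hat"`}{the tensor-product hat function
#'     \eqn{\varphi(x) = \prod_i \max(1-|x_i|, 0)}, support radius 1;}
#'   \item{`"b3"`}{the cubic B-spline
#'     \eqn{\varphi(x) = \frac{1}{6}\{(2-|x|)^3}  on \eqn{1\le|x|<2},
#'     \eqn{4-6x^2+3|x|^3} on \eqn{|x|<1}, 0 otherwise\}, support radius 2,
#'     extended to several dimensions as a tensor product of 1D factors.}
#' }
#'
#' @param name `"hat"` or `"b3"`.
#' @return An object of class `ltp_shape` with fields `name`, `evaluate1`
#'   (the 1D factor), `support_radius`, `lipschitz_const`.
#' @examples
#' sh <- ltp_shape("b3")
#' eval_shape(sh, 0)  # 4/6
#' @export
ltp_shape <- function(name = c("hat", "b3")) {
  name <- match.arg(name)
  if (name == "hat") {
    f1 <- function(t) pmax(1 - abs(t), 0)
    R <- 1
    lip <- 1
  } else {
    f1 <- function(t) {
      a <- abs(t)
      ((2 - a)^3 * (a >= 1 & a < 2) + (4 - 6 * t^2 + 3 * a^3) * (a < 1)) / 6
    }
    R <- 2
    lip <- 2 / 3   # max |phi'| attained at |x| = 2/3
  }
  structure(
    list(name = name, evaluate1 = f1, support_radius = R, lipschitz_const = lip),
    class = "ltp_shape"
  )
}

#' @export
print.ltp_shape <- function(x, ...) {
  cat(sprintf("<ltp_shape '%s'>  support radius %g, Lipschitz constant %.4g\n",
              x$name, x$support_radius, x$lipschitz_const))
  invisible(x)
}

#' Evaluate a reference shape
#'
#' @param shape an [ltp_shape()].
#' @param x a numeric vector of 1D points, or a matrix with one point per row
#'   for dimension `d = ncol(x)` (tensor-product construction).
#' @return Numeric vector of shape values; exactly 0 outside the support.
#' @export
eval_shape <- function(shape, x) {
  stopifnot(inherits(shape, "ltp_shape"))
  if (is.matrix(x)) {
    vals <- shape$evaluate1(x)
    apply(vals, 1L, prod)
  } else {
    shape$evaluate1(x)
  }
}

#' Bi-orthogonal dual kernel of the hat shape
#'
#' The integration kernel \eqn{\tilde\varphi} bi-orthogonal to the hat shape,
#' i.e. \eqn{\int \varphi(x-j)\,\tilde\varphi(x-j') dx = \delta_{jj'}}. It is
#' piecewise constant: 3/2 on \eqn{[-1/2, 1/2]}, -1/2 on
#' \eqn{[-1,-1/2]\cup[1/2,1]}, 0 outside \eqn{[-1,1]}. Used for the
#' second-order dual weighting scheme (which may produce negative weights).
#' No dual kernel is provided for the B3 spline.
#'
#' @param shape an [ltp_shape()]; must be the hat shape.
#' @return An object of class `ltp_dual_kernel` with fields `evaluate`,
#'   `support_radius` and `pieces` (the piecewise-constant description).
#' @export
dual_kernel <- function(shape = ltp_shape("hat")) {
  stopifnot(inherits(shape, "ltp_shape"))
  if (shape$name != "hat") {
    stop("a bi-orthogonal dual kernel is only available for the hat shape")
  }
  pieces <- data.frame(
    lo = c(-1, -0.5, 0.5),
    hi = c(-0.5, 0.5, 1),
    value = c(-0.5, 1.5, -0.5)
  )
  ev <- function(x) {
    a <- abs(x)
    1.5 * (a <= 0.5) - 0.5 * (a > 0.5 & a <= 1)
  }
  structure(
    list(evaluate = ev, support_radius = 1, pieces = pieces),
    class = "ltp_dual_kernel"
  )
}

#' Evaluate the dual kernel
#'
#' @param kernel a [dual_kernel()].
#' @param x numeric vector.
#' @return Piecewise-constant kernel values (3/2, -1/2 or 0).
#' @export
eval_dual_kernel <- function(kernel, x) {
  stopifnot(inherits(kernel, "ltp_dual_kernel"))
  kernel$evaluate(x)
}

#' Check the partition-of-unity property of a shape
#'
#' Evaluates \eqn{\sum_{k} \varphi(x - k)} over the integer shifts covering
#' the sample points and returns the maximum absolute deviation from 1.
#' Both built-in shapes satisfy the identity to rounding error.
#'
#' @param shape an [ltp_shape()].
#' @param sample_points numeric vector of 1D evaluation points.
#' @return Maximum absolute deviation of the lattice sum from 1.
#' @export
check_partition_of_unity <- function(shape, sample_points) {
  stopifnot(inherits(shape, "ltp_shape"), is.numeric(sample_points),
            length(sample_points) > 0)
  R <- shape$support_radius
  ks <- seq(floor(min(sample_points)) - ceiling(R),
            ceiling(max(sample_points)) + ceiling(R))
  s <- rowSums(shape$evaluate1(outer(sample_points, ks, "-")))
  max(abs(s - 1))
}
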