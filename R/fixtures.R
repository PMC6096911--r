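#' Built-in initial densities
#'
#' Four closed-form 1D initial profiles, all supported in \eqn{[-1,1]}:
#' \describe{
#'   \item{`rho1`}{\eqn{(e^{-30(x-0.5)^2} + 2e^{-50(x+0.3)^2})\,1_{[-1,1]}}
#'     -- asymmetric double bump;}
#'   \item{`rho2`}{\eqn{1_{[-1,1]}} -- discontinuous plateau;}
#'   \item{`rho3`}{\eqn{(1-x^2)^{20}\,1_{[-1,1]}} -- smooth polynomial bump;}
#'   \item{`rho4`}{\eqn{e^{1/(x^2-1)}\,1_{(-1,1)}} -- \eqn{C^\infty} bump with
#'     compact support.}
#' }
#' Fixtures are stored as printed (unnormalized); pass `normalize = TRUE` (or
#' use the initializer's default) to rescale to unit mass, the normalization
#' the theory assumes.
#'
#' @param name one of `"rho1"`, `"rho2"`, `"rho3"`, `"rho4"`.
#' @param normalize rescale to unit mass?
#' @return A vectorized density function with attributes `support` (interval),
#'   `name`, `normalized`.
#' @export
fixture_density <- function(name = c("rho1", "rho2", "rho3", "rho4"),
                            normalize = FALSE) {
  name <- match.arg(name)
  f <- switch(
    name,
    rho1 = function(x) {
      (exp(-30 * (x - 0.5)^2) + 2 * exp(-50 * (x + 0.3)^2)) * (abs(x) <= 1)
    },
    rho2 = function(x) as.numeric(abs(x) <= 1),
    rho3 = function(x) ifelse(abs(x) <= 1, (1 - x^2)^20, 0),
    rho4 = function(x) ifelse(abs(x) < 1, exp(1 / (x^2 - 1)), 0)
  )
  attr(f, "support") <- c(-1, 1)
  attr(f, "name") <- name
  attr(f, "normalized") <- FALSE
  if (normalize) f <- normalize_density(f) else f
}

#' Rescale a density to unit mass
#'
#' Divides a compactly supported density by its mass, computed by fine
#' composite Gauss-Legendre quadrature over the declared support.
#'
#' @param rho0 a density function with a `support` attribute.
#' @param support override for the support interval.
#' @return The normalized density, with attributes preserved and
#'   `normalized = TRUE`.
#' @export
normalize_density <- function(rho0, support = attr(rho0, "support")) {
  stopifnot(is.function(rho0))
  if (is.null(support)) stop("density must carry a 'support' attribute")
  mass <- gl_integrate(rho0, support[1], support[2], panels = 400L, nodes = 10L)
  if (mass <= 0) stop("cannot normalize a density with non-positive mass")
  g <- function(x) rho0(x) / mass
  attr(g, "support") <- support
  attr(g, "name") <- attr(rho0, "name")
  attr(g, "normalized") <- TRUE
  g
}
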