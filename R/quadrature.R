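# Composite Gauss-Legendre quadrature (internal helpers).
#
# All integrands in the package are piecewise smooth (piecewise polynomial
# shapes, Gaussians, power-law kernels away from 0), so composite GL with a
# handful of nodes per panel is far more accurate than the h^2-scale errors
# being measured.

.gl_cache <- new.env(parent = emptyenv())

# nodes/weights on [-1, 1]
gl_rule <- function(n) {
  key <- as.character(n)
  rule <- .gl_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- rule
  }
  rule
}

# Integrate a vectorized function over [lower, upper].
gl_integrate <- function(f, lower, upper, panels = 8L, nodes = 5L) {
  if (!is.finite(lower) || !is.finite(upper)) stop("integration bounds must be finite")
  if (upper <= lower) return(0)
  r <- gl_rule(nodes)
  breaks <- seq(lower, upper, length.out = panels + 1L)
  a <- breaks[-length(breaks)]
  b <- breaks[-1L]
  half <- (b - a) / 2
  mid <- (a + b) / 2
  xs <- outer(half, r$x) + mid   # panels x nodes
  ws <- outer(half, r$w)
  vals <- matrix(f(as.vector(xs)), nrow = length(a))
  sum(ws * vals)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
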