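# Shared builders for tests. Everything is generated in code; no stored data.

unit_particle <- function(h = 0.1, shape = ltp_shape("hat")) {
  particle_ensemble(x = 0, w = 1, h = h, shape = shape)
}

fixture_ensemble <- function(name = "rho1", h = 1 / 25,
                             shape = ltp_shape("hat"),
                             scheme = "cell_integral", normalize = TRUE) {
  build_initial_ensemble(fixture_density(name), init_grid(h, c(-1, 1)),
                         shape = shape, scheme = scheme,
                         normalize = normalize)
}

# composite-trapezoid integral on a uniform grid (independent of package
# quadrature helpers)
trapz <- function(y, x) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# total variation of a gridded profile
total_variation <- function(v) sum(abs(diff(v)))
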