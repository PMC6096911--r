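test_that("cell-integral weights tile a plateau density exactly", {
  f <- function(x) 0.5 * (abs(x) <= 1)
  attr(f, "support") <- c(-1, 1)
  g <- init_grid(0.5, c(-1, 1))
  w <- weights_cell_integral(f, g)
  expect_equal(g$x, c(-1, -0.5, 0, 0.5, 1))
  interior <- abs(g$x) < 1
  expect_equal(w[interior], rep(0.25, 3))          # full cells of height 1/2
  expect_equal(w[!interior], rep(0.125, 2))        # half-covered boundary cells
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # zero density -> zero weights
  z <- function(x) 0 * x
  attr(z, "support") <- c(-1, 1)
  expect_equal(weights_cell_integral(z, g), rep(0, 5))
  # support exceeding the bounds is a coverage error
  wide <- function(x) exp(-x^2)
  attr(wide, "support") <- c(-5, 5)
  expect_error(weights_cell_integral(wide, g), "exceeds")
})

test_that("cell weights satisfy the mass and size bounds", {
  for (nm in c("rho1", "rho3")) {
    rho <- fixture_density(nm, normalize = TRUE)
    g <- init_grid(0.1, c(-1, 1))
    w <- weights_cell_integral(rho, g)
    expect_true(all(w >= 0))
    expect_equal(sum(abs(w)), 1, tolerance = 1e-10)  # equality for rho >= 0
    # sup_k |w_k| <= h * sup rho
    expect_lte(max(abs(w)), 0.1 * max(rho(seq(-1, 1, by = 1e-3))) + 1e-12)
  }
})

test_that("dual-kernel weights match their defining integrals", {
  g <- init_grid(1, c(-10, 10))
  # constant density: w_k = c * h since the dual kernel has unit integral
  cst <- function(x) 3 * (abs(x) <= 10)
  attr(cst, "support") <- c(-10, 10)
  expect_equal(weights_dual_kernel(cst, g)[g$k == 0], 3, tolerance = 1e-12)
  # odd density against the even kernel
  odd <- function(x) x * (abs(x) <= 10)
  attr(odd, "support") <- c(-10, 10)
  expect_equal(weights_dual_kernel(odd, g)[g$k == 0], 0, tolerance = 1e-12)
  # zero density
  z <- function(x) 0 * x
  attr(z, "support") <- c(-10, 10)
  expect_equal(weights_dual_kernel(z, g), rep(0, length(g$k)))
  # quadrature oracle on a generic smooth density, generic node
  rho <- function(x) exp(-x^2 / 2) * (abs(x) <= 10)
  attr(rho, "support") <- c(-10, 10)
  h <- 0.5
  g2 <- init_grid(h, c(-10, 10))
  dk <- dual_kernel()
  k0 <- which(g2$k == 3)
  oracle <- integrate(function(x) eval_dual_kernel(dk, (x - g2$x[k0]) / h) * rho(x),
                      g2$x[k0] - h, g2$x[k0] + h,
                      subdivisions = 800, rel.tol = 1e-12)$value
  expect_equal(weights_dual_kernel(rho, g2)[k0], oracle, tolerance = 1e-9)
})

test_that("initial ensembles start with identity deformations and cell volumes", {
  ens <- fixture_ensemble("rho2", h = 0.5)
  expect_equal(as.vector(ens$D[1, 1, ]), rep(1, n_particles(ens)))
  expect_equal(ens$hvol, rep(0.5, n_particles(ens)))
  expect_equal(ens$x[, 1], c(-1, -0.5, 0, 0.5, 1))
  expect_equal(sum(ens$w), 1, tolerance = 1e-12)
  expect_error(
    build_initial_ensemble(fixture_density("rho2"), init_grid(0.5, c(-1, 1)),
                           shape = ltp_shape("b3"), scheme = "dual_kernel"),
    "hat")
})

test_that("dual-weight reconstruction is exact for affine densities on the interior", {
  aff <- function(x) (2 + 0.5 * x) * (abs(x) <= 4)
  attr(aff, "support") <- c(-4, 4)
  h <- 0.25
  ens <- build_initial_ensemble(aff, init_grid(h, c(-4, 4)),
                                shape = ltp_shape("hat"),
                                scheme = "dual_kernel", normalize = FALSE)
  interior <- seq(-2, 2, by = h / 8)
  expect_equal(eval_density(ens, interior), aff(interior), tolerance = 1e-10)
  # and initialization_error is zero when a density is compared with itself
  expect_equal(lp_error(aff(interior), aff(interior), 1, interior), 0)
})

test_that("dual weights pair with smooth test functions at second order", {
  rho <- fixture_density("rho1", normalize = TRUE)
  v <- function(x) cos(1.3 * x) + 0.5 * x
  hs <- c(0.2, 0.1, 0.05)
  errs <- sapply(hs, function(h) {
    ens <- build_initial_ensemble(rho, init_grid(h, c(-1, 1)),
                                  shape = ltp_shape("hat"),
                                  scheme = "dual_kernel")
    grid <- seq(-1.5, 1.5, by = h / 16)
    vals <- (rho(grid) - eval_density(ens, grid)) * v(grid)
    abs(trapz(vals, grid))
  })
  expect_true(all(errs <= 0.05 * hs^2))
})

test_that("cell-weight initialization error shrinks at second order for a smooth bump", {
  rho <- fixture_density("rho4", normalize = TRUE)
  hs <- c(0.2, 0.1, 0.05)
  grid <- seq(-1.3, 1.3, by = min(hs) / 8)
  errs <- sapply(hs, function(h) {
    ens <- build_initial_ensemble(rho, init_grid(h, c(-1, 1)),
                                  shape = ltp_shape("hat"))
    initialization_error(rho, ens, p = 1, eval_grid = grid)
  })
  expect_true(all(diff(errs) < 0))
  expect_equal(convergence_order(hs, errs)$order, 2, tolerance = 0.2)
})
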