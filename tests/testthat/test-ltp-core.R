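test_that("density reconstruction matches the particle formula", {
  h <- 0.1
  ens <- unit_particle(h)
  expect_equal(eval_density(ens, 0), 1 / h)      # phi(0)/h_vol
  expect_identical(eval_density(ens, 5), 0)      # outside every support
  # quadrature of rho_h over a covering box equals the sum of weights
  ens2 <- fixture_ensemble("rho1", h = 0.05, shape = ltp_shape("b3"))
  grid <- seq(-1.5, 1.5, by = 0.05 / 16)
  expect_equal(trapz(eval_density(ens2, grid), grid), sum(ens2$w),
               tolerance = 1e-6)
})

test_that("ensemble invariants are enforced", {
  expect_error(particle_ensemble(x = 0, w = 1, D = -1, h = 0.1),
               "positive")
  expect_error(particle_ensemble(x = 0, w = 1, D = 2, hvol = 0.1, h = 0.1),
               "identity")
  # h_vol * det(D) = h^d survives stepping
  ens <- fixture_ensemble("rho1", h = 0.1)
  pot <- potential_power_law(2.5)
  st <- ltp_step(ens, pot, velocity_evaluator("quadrature"), dt = 0.01)
  dets <- st$ensemble$D[1, 1, ]
  expect_equal(st$ensemble$hvol * dets, rep(0.1, n_particles(ens)),
               tolerance = 1e-12)
  expect_true(all(st$record$j > 0))
})

test_that("a single symmetric particle under W = x^2 contracts in place", {
  dt <- 0.02
  h <- 0.1
  ens <- unit_particle(h)
  pot <- potential_quadratic()
  st <- ltp_step(ens, pot, velocity_evaluator("blob"), dt = dt)
  expect_equal(st$ensemble$x[1, 1], 0, tolerance = 1e-14)   # symmetric velocity
  expect_equal(st$record$j, exp(-2 * dt), tolerance = 1e-14) # W'' * rho = 2
  expect_equal(st$ensemble$hvol, exp(-2 * dt) * h, tolerance = 1e-14)
  # linearized mode: j = 1 - 2 dt
  stl <- ltp_step(ens, pot, velocity_evaluator("blob"), dt = dt,
                  jacobian_mode = "linearized")
  expect_equal(stl$record$j, 1 - 2 * dt, tolerance = 1e-14)
  # degenerate linearized Jacobian is a hard error (1 - 2 dt <= 0)
  expect_error(ltp_step(ens, pot, velocity_evaluator("blob"), dt = 0.6,
                        jacobian_mode = "linearized"),
               "non-positive")
  # exponential mode stays positive even there
  stb <- ltp_step(ens, pot, velocity_evaluator("blob"), dt = 0.6)
  expect_true(all(stb$record$j > 0))
})

test_that("runs conserve mass exactly and volumes follow the quadratic law", {
  h <- 1 / 25
  dt <- 0.01
  N <- 20
  ens <- fixture_ensemble("rho1", h = h)
  run <- ltp_run(ens, potential_quadratic(), velocity_evaluator("blob"),
                 dt = dt, t_end = N * dt)
  expect_identical(run$final$w, ens$w)                       # bitwise constant
  expect_true(all(run$log$mass == sum(ens$w)))
  # unit mass: every volume is h * e^{-2 N dt}
  expect_equal(run$final$hvol, rep(h * exp(-2 * N * dt), n_particles(ens)),
               tolerance = 1e-10)
  expect_equal(particle_size_field(run$final),
               rep(h * exp(-2 * N * dt), n_particles(ens)), tolerance = 1e-10)
  # center of mass conserved (pairwise cancellation in the blob sums)
  expect_equal(center_of_mass(run$final), center_of_mass(ens),
               tolerance = 1e-12)
  # zero steps returns the initial ensemble unchanged
  run0 <- ltp_run(ens, potential_quadratic(), velocity_evaluator("blob"),
                  dt = dt, t_end = 0)
  expect_identical(run0$final, ens)
  expect_equal(particle_size_field(ens), rep(h, n_particles(ens)))
})

test_that("exponential vs linearized Jacobian gap scales like dt^2", {
  ens <- fixture_ensemble("rho1", h = 0.1)   # ~20 particles
  pot <- potential_power_law(2.5)
  vel <- velocity_evaluator("quadrature")
  expect_equal(jacobian_mode_gap(ens, pot, vel, 0), 0)
  g1 <- jacobian_mode_gap(ens, pot, vel, 1e-2)
  g2 <- jacobian_mode_gap(ens, pot, vel, 5e-3)
  expect_gt(g1 / g2, 3.5)
  expect_lt(g1 / g2, 4.5)
  # scalar Taylor remainder bound |e^{-c dt} - (1 - c dt)| <= (c dt)^2/2 e^{c dt}
  conv <- ltpagg:::evaluate_convolutions(vel, ens, pot)
  cmax <- max(abs(conv$hess))
  expect_lte(g1, (cmax * 1e-2)^2 / 2 * exp(cmax * 1e-2) + 1e-15)
})

test_that("the concentration guard stops collapsing runs", {
  ens <- fixture_ensemble("rho2", h = 0.05, shape = ltp_shape("b3"))
  run <- ltp_run(ens, potential_power_law(1.5),
                 velocity_evaluator("quadrature"), dt = 0.01, t_end = 5,
                 blowup_ceiling = 1e4)
  expect_true(run$guard_triggered)
  expect_lt(run$completed_steps, 500)
  expect_true(all(diff(run$log$min_hvol) < 0))
})
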