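test_that("quadratic potential has the printed derivatives", {
  pot <- potential_quadratic()
  expect_equal(pot$gradW(1), 2)
  expect_equal(pot$gradW(0), 0)
  expect_equal(pot$hessW(0.7), 2)
  expect_equal(pot$laplW(-3), 2)
  expect_true(pot$is_smooth)
})

test_that("power-law potentials: derivatives, classification, conventions", {
  p25 <- potential_power_law(2.5)
  expect_equal(p25$gradW(4), 8)          # 4^{1.5}
  expect_true(p25$is_smooth)
  expect_true(is.na(p25$alpha))

  p15 <- potential_power_law(1.5)
  expect_equal(p15$alpha, -0.5)
  expect_false(p15$is_smooth)
  expect_identical(p15$gradW(0), 0)      # odd-symmetry convention
  expect_identical(p15$hessW(0), Inf)    # singular sentinel
  expect_error(potential_power_law(1), "a > 1")
  expect_error(potential_power_law(0.5), "a > 1")

  # exact singular bounds: |W'| = |x|^{a-1} = |x|^{-alpha},
  # |W''| = (a-1)|x|^{a-2} = (a-1)|x|^{-(1+alpha)} on a dyadic grid near 0
  x <- 2^-(1:12)
  expect_equal(abs(p15$gradW(x)), x^-p15$alpha)
  expect_equal(abs(p15$hessW(x)), 0.5 * x^-(1 + p15$alpha))
})

test_that("attractive-repulsive potentials combine the two power terms", {
  ar <- potential_attractive_repulsive(3, 2.5)
  expect_equal(ar$gradW(1), 0)           # |x|^{a-1} - |x|^{b-1} at 1
  expect_true(ar$is_smooth)
  ar2 <- potential_attractive_repulsive(3, 1.5)
  expect_false(ar2$is_smooth)
  expect_equal(ar2$alpha, -0.5)
  expect_identical(potential_attractive_repulsive(4, 2.5)$gradW(0), 0)
  expect_error(potential_attractive_repulsive(2, 3), "1 < b < a")
  expect_error(potential_attractive_repulsive(3, 1), "1 < b < a")
})

test_that("radial potentials have odd gradients and even second derivatives", {
  xs <- c(0.1, 0.37, 1.2, 2)
  for (pot in list(potential_quadratic(), potential_power_law(1.5),
                   potential_attractive_repulsive(3, 1.5))) {
    expect_equal(pot$gradW(-xs), -pot$gradW(xs))
    expect_equal(pot$hessW(-xs), pot$hessW(xs))
  }
})

test_that("gradient increments of singular power laws obey the local Lipschitz bound", {
  # |W'(x) - W'(y)| <= C |x-y| / min(|x|,|y|)^{alpha+1} away from 0
  a <- 1.5
  pot <- potential_power_law(a)
  set.seed(3)
  x <- runif(200, -2, 2)
  y <- runif(200, -2, 2)
  keep <- pmin(abs(x), abs(y)) > 1e-3
  x <- x[keep]; y <- y[keep]
  lhs <- abs(pot$gradW(x) - pot$gradW(y))
  rhs <- abs(x - y) / pmin(abs(x), abs(y))^(pot$alpha + 1)
  expect_true(all(lhs <= 2 * rhs + 1e-12))
})

test_that("mollified gradients behave like the exact gradient where it is smooth", {
  # linear gradient is reproduced exactly by any symmetric unit-mass blob
  gq <- smoothed_grad(potential_quadratic(), ltp_shape("hat"), eps = 0.3)
  expect_equal(gq(1), 2, tolerance = 1e-12)
  expect_equal(gq(c(-2, 0.5)), c(-4, 1), tolerance = 1e-12)
  # odd * even vanishes at the origin, exactly
  g15 <- smoothed_grad(potential_power_law(1.5), ltp_shape("b3"), eps = 0.1)
  expect_identical(g15(0), 0)
  # quadrature oracle for a singular potential at one off-origin point
  pot <- potential_power_law(1.5)
  eps <- 0.1
  sh <- ltp_shape("hat")
  oracle <- integrate(function(s) pot$gradW(0.5 - eps * s) * eval_shape(sh, s),
                      -1, 1, subdivisions = 800, rel.tol = 1e-10)$value
  g <- smoothed_grad(pot, sh, eps)
  expect_equal(g(0.5), oracle, tolerance = 1e-7)
  # eps -> 0 recovers the raw gradient at fixed x
  errs <- sapply(c(0.1, 0.05, 0.025), function(e) {
    abs(smoothed_grad(pot, sh, e)(0.5) - sqrt(0.5))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
  expect_error(smoothed_grad(pot, sh, 0), "positive")
})

test_that("potential specification strings parse", {
  expect_equal(parse_potential("quadratic")$name, "quadratic")
  expect_equal(parse_potential("power:1.5")$params$a, 1.5)
  ar <- parse_potential("attrep:3,1.5")
  expect_equal(unlist(ar$params), c(a = 3, b = 1.5))
  expect_error(parse_potential("newtonian"), "unknown")
  expect_error(parse_potential("attrep:3"), "a,b")
})
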