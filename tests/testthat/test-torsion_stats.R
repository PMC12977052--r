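RT310 <- GAS_CONSTANT_KJ * 310

test_that("score weights follow the min-shifted softmax contract", {
  expect_equal(score_weights(c(5, 5, 5, 5)), rep(0.25, 4))
  expect_equal(score_weights(c(-3, 10, 42), tau = Inf), rep(1 / 3, 3))
  # two models one tau apart: weight ratio e : 1
  w <- score_weights(c(-10, -10 + 2.5), tau = 2.5)
  expect_equal(w, c(0.7310586, 0.2689414), tolerance = 1e-6)
  expect_equal(sum(w), 1)
  expect_error(score_weights(c(1, NA)), "finite")
  expect_error(score_weights(c(1, 2), tau = -1), "positive")
})

test_that("bandwidth follows the Silverman-rate law with clamps", {
  expect_equal(kde_bandwidth(10000), 5)
  expect_equal(kde_bandwidth(100), 5 * 100^(1 / 5), tolerance = 1e-6)
  expect_equal(kde_bandwidth(100), 5 * 2.5119, tolerance = 1e-4)
  expect_equal(kde_bandwidth(1), 30)      # clamped at h_max
  expect_equal(kde_bandwidth(1e9), 2)     # clamped at h_min
  expect_error(kde_bandwidth(0), ">= 1")
})

test_that("weighted circular density is symmetric, periodic and normalized", {
  one <- torsion_sample(2, "phi", 0)
  d <- weighted_circular_density(one, bandwidth = 10)
  expect_equal(d$grid[which.max(d$density)], 0)
  i_pos <- match(30, d$grid); i_neg <- match(-30, d$grid)
  expect_equal(d$density[i_pos], d$density[i_neg], tolerance = 1e-12)

  two <- torsion_sample(2, "phi", c(90, -90))
  d2 <- weighted_circular_density(two, bandwidth = 10)
  expect_equal(d2$density[match(90, d2$grid)],
               d2$density[match(-90, d2$grid)], tolerance = 1e-9)

  # periodic endpoint duplication
  expect_equal(d2$density[1], d2$density[length(d2$grid)], tolerance = 1e-9)
  expect_error(weighted_circular_density(one, bandwidth = 0), "positive")
})

test_that("wrapping at the boundary matches a brute-force multi-image sum", {
  s <- torsion_sample(3, "psi", 179)
  d <- weighted_circular_density(s, bandwidth = 10)
  oracle <- oracle_wrapped_density(179, 1, 10)
  expect_equal(d$density, oracle, tolerance = 1e-9)
  # mass wraps across the boundary: -179 is 2 degrees from the sample
  expect_equal(d$density[match(-179, d$grid)],
               d$density[match(177, d$grid)], tolerance = 1e-12)

  # random weighted samples agree with the oracle too, and normalize
  set.seed(42)
  for (rep in 1:4) {
    ang <- runif(12, -180, 180)
    w <- score_weights(rnorm(12), tau = 1)
    smp <- torsion_sample(1, "psi", ang, w)
    dd <- weighted_circular_density(smp, bandwidth = runif(1, 3, 25))
    expect_equal(sum(dd$density[-length(dd$density)]) * 1, 1,
                 tolerance = 1e-6)
    expect_equal(dd$density,
                 oracle_wrapped_density(smp$angles, smp$weights,
                                        dd$bandwidth),
                 tolerance = 1e-9)
  }
})

test_that("Boltzmann inversion implements PEF = -RT ln P with min-0 gauge", {
  # uniform density: constant unshifted PEF of RT ln(360) at 310 K
  s <- torsion_sample(1, "phi", seq(-179, 180, by = 1))
  d <- weighted_circular_density(s, bandwidth = 30)
  d$density <- rep(1 / 360, length(d$grid))  # exact uniform
  pt <- boltzmann_invert(d, 310)
  expect_equal(pt$pef, rep(0, length(pt$grid)), tolerance = 1e-12)
  expect_equal(pt$pef_offset, RT310 * log(360), tolerance = 1e-12)
  expect_equal(pt$pef_offset, 15.17, tolerance = 1e-3)

  # argmax density == argmin pef; floored density keeps barriers finite
  set.seed(5)
  smp <- torsion_sample(1, "phi", rvonmises(200, 40, 8))
  dd <- weighted_circular_density(smp, bandwidth = 8)
  pp <- boltzmann_invert(dd, 310)
  expect_equal(which.min(pp$pef), which.max(dd$density))
  expect_true(all(is.finite(pp$pef)))
  expect_error(boltzmann_invert(dd, -5), "positive")
})

test_that("force column equals -dPEF/dalpha on closed-form potentials", {
  grid <- seq(-180, 180, by = 1)
  a_amp <- 1; mu <- 35
  pt <- structure(list(grid = grid,
                       pef = a_amp * (1 - cos((grid - mu) * pi / 180)),
                       force = NULL, temperature = 310, rt = RT310,
                       torsion_id = c(residue_index = 1, kind = "phi"),
                       density = NULL, grid_step = 1),
                  class = "potential_table")
  pt <- potential_force(pt)
  closed <- -a_amp * sin((grid - mu) * pi / 180) * pi / 180
  expect_lt(max(abs(pt$force - closed)), 1e-6)
  expect_equal(pt$force[1], pt$force[length(grid)], tolerance = 1e-9)

  # constant pef -> zero force
  flat <- pt; flat$pef <- rep(2, length(grid)); flat$force <- NULL
  expect_equal(potential_force(flat)$force, rep(0, length(grid)))

  # analytic (kernel chain-rule) and numeric differentiation agree O(step^2)
  set.seed(8)
  smp <- torsion_sample(1, "psi", rvonmises(100, -70, 6))
  tab <- boltzmann_invert(weighted_circular_density(smp, bandwidth = 10))
  fa <- potential_force(tab, method = "analytic")$force
  fn <- potential_force(tab, method = "numeric")$force
  expect_lt(max(abs(fa - fn)), 0.02 * max(abs(fa)))
  # conservative periodic potential: zero circulation
  expect_lt(abs(sum(fa[-length(fa)]) * 1), 1e-6)
  # force near zero at the minimum
  imin <- which.min(tab$pef)
  expect_lt(abs(fa[imin]), max(abs(diff(tab$pef))))
})

test_that("duplicating a model at half weight changes nothing", {
  ang <- c(-60, 10, 130)
  w <- c(0.5, 0.3, 0.2)
  s1 <- torsion_sample(1, "phi", ang, w)
  s2 <- torsion_sample(1, "phi", c(ang, -60), c(0.25, 0.3, 0.2, 0.25))
  d1 <- weighted_circular_density(s1, 12)
  d2 <- weighted_circular_density(s2, 12)
  expect_equal(d1$density, d2$density, tolerance = 1e-9)
  p1 <- potential_force(boltzmann_invert(d1))
  p2 <- potential_force(boltzmann_invert(d2))
  expect_equal(p1$pef, p2$pef, tolerance = 1e-9)
  expect_equal(p1$force, p2$force, tolerance = 1e-9)
})

test_that("von Mises ensembles are recovered: mode within 3 deg, curvature ~ RT kappa", {
  mu <- -60; kappa <- 8
  set.seed(21)
  smp <- torsion_sample(1, "phi", rvonmises(2000, mu, kappa))
  pt <- boltzmann_invert(weighted_circular_density(smp, bandwidth = 5), 310)
  imin <- which.min(pt$pef)
  expect_lt(circ_diff(pt$grid[imin], mu), 3)
  # quadratic curvature at the minimum, per radian^2; fit window ~1.5
  # circular sd of a kappa = 8 von Mises (sigma ~ 20 deg)
  expect_equal(pef_curvature(pt, window_deg = 30), RT310 * kappa,
               tolerance = 0.2)
})

test_that("a 70/30 two-state density gives Delta-PEF = RT ln(7/3)", {
  expected <- RT310 * log(7 / 3)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 2000
    n1 <- round(0.7 * n)  # exact 70/30 composition
    ang <- c(rvonmises(n1, -60, 20), rvonmises(n - n1, 120, 20))
    smp <- torsion_sample(1, "phi", ang)
    pt <- boltzmann_invert(weighted_circular_density(smp,
                                                     kde_bandwidth(n)), 310)
    near <- function(mu) {
      sel <- circ_diff(pt$grid, mu) <= 45
      min(pt$pef[sel])
    }
    dpef <- near(120) - near(-60)
    expect_equal(dpef, expected, tolerance = 0.1)
  }
})

test_that("potentials scale linearly with temperature (same density)", {
  set.seed(3)
  smp <- torsion_sample(1, "psi", rvonmises(500, 80, 5))
  d <- weighted_circular_density(smp, 8)
  p310 <- boltzmann_invert(d, 310)
  p350 <- boltzmann_invert(d, 350)
  expect_equal(p350$pef, p310$pef * 350 / 310, tolerance = 1e-12)
  expect_equal(p350$pef_offset, p310$pef_offset * 350 / 310,
               tolerance = 1e-12)
})
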