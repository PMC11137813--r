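test_that("LJ energy hits its landmarks in both conventions", {
  p <- lj_pair(-1, 1)
  expect_equal(lj_energy(p, 1), 0)
  expect_equal(lj_energy(p, 2^(1/6)), -1)
  # deep coordination pair: printed well depth at the analytic minimum
  expect_equal(lj_energy(pair_fecco(), 2^(1/6) * 1.79), -21.49)
  # rmin convention places the minimum at sigma itself
  pr <- lj_pair(-6.55, 1.90, convention = "rmin")
  expect_equal(lj_energy(pr, 1.90), -6.55)
  expect_equal(optimize(function(r) lj_energy(pr, r), c(1.2, 4))$minimum,
               1.90, tolerance = 1e-5)
  # decay to zero at long range
  expect_lt(abs(lj_energy(p, 50)), 1e-9)
})

test_that("LJ force is the exact derivative and vanishes at the minimum", {
  p <- lj_pair(-1, 1)
  expect_equal(lj_force(p, 2^(1/6)), 0, tolerance = 1e-12)
  expect_equal(lj_force(p, 1), 24)
  # maximal attraction at (26/7)^(1/6) sigma
  mx <- lj_max_attraction(pair_fecco())
  expect_equal(mx$r_max, (26/7)^(1/6) * 1.79)
  expect_equal(optimize(function(r) lj_force(pair_fecco(), r),
                        c(1.8, 3.5))$minimum, mx$r_max, tolerance = 1e-5)
  # property: analytic force matches central differences for random pairs
  set.seed(42)
  for (i in 1:20) {
    pp <- lj_pair(-runif(1, 0.5, 25), runif(1, 1.2, 3.2))
    r <- runif(5, 0.8 * pp$sigma, 3 * pp$sigma)
    expect_equal(lj_force(pp, r),
                 numeric_force(function(x) lj_energy(pp, x), r),
                 tolerance = 1e-6)
  }
})

test_that("inputs outside the physical domain are rejected", {
  expect_error(lj_pair(-1, -2), "sigma")
  expect_error(lj_energy(lj_pair(-1, 1), 0), "positive")
  expect_error(lj_force(lj_pair(-1, 1), -0.5), "positive")
  expect_error(switching_factor(5, r_on = 10, r_off = 8), "r_on")
  expect_error(bias_spec("moving-harmonic", kappa = 10), "rate")
  expect_error(bias_spec("harmonic", kappa = -1), "kappa")
  expect_error(bias_energy_force(bias_spec("harmonic", kappa = 1), 1, t = -1),
               "non-negative")
})

test_that("finite differencing follows the adjacent-difference rule", {
  # linear energy -> constant force equal to minus the slope
  lin <- potential_curve(seq(1, 3, 0.1), U = 3 * seq(1, 3, 0.1))
  f <- finite_difference_force(lin)
  expect_equal(f$F[-nrow(f)], rep(-3, nrow(f) - 1))
  expect_true(is.na(f$F[nrow(f)]))

  # LJ sampled at 0.1 A reproduces the analytic force outside the wall
  cv <- synthesize_ground_truth_curve(lj_pair(-1, 1),
                                      r = seq(1.0, 3.0, 0.1))
  fd <- finite_difference_force(cv)
  sel <- !is.na(fd$F) & fd$r >= 1.2
  expect_lt(max(abs(fd$F[sel] - lj_force(lj_pair(-1, 1), fd$r[sel] + 0.05))),
            0.05 * max(abs(lj_force(lj_pair(-1, 1), fd$r[sel]))))

  # an interval with an outsized energy jump leaves a local spike in F
  r <- seq(1.75, 2.95, 0.1)
  u <- -2 - 0.1 * r
  u[8] <- u[8] - 0.5    # one bumped interval (between nodes 7 and 8)
  sp <- finite_difference_force(potential_curve(r, U = u))
  expect_gt(sp$F[7], max(sp$F[c(1:6, 9:12)]))
  expect_lt(sp$F[8], min(sp$F[c(1:6, 9:12)]))

  expect_error(finite_difference_force(potential_curve(c(1, 1.1, 1.3),
                                                       U = c(0, 0, 0))),
               "uniform")
  expect_error(finite_difference_force(potential_curve(1, U = 0)), "2 grid")
})

test_that("switching factor is a smooth bridge from 1 to 0", {
  expect_equal(switching_factor(5), 1)
  expect_equal(switching_factor(11), 0)
  s9 <- switching_factor(9)
  expect_gt(s9, 0); expect_lt(s9, 1)
  rr <- seq(8.01, 9.99, 0.01)
  expect_true(all(diff(switching_factor(rr)) < 0))
  # switched energy and force continuous at both ends of the window
  p <- lj_pair(-1, 3)
  for (edge in c(8, 10)) {
    lo <- hemeforge:::lj_switched(p, edge - 1e-7)
    hi <- hemeforge:::lj_switched(p, edge + 1e-7)
    expect_lt(abs(lo$U - hi$U), 1e-8)
    expect_lt(abs(lo$F - hi$F), 1e-8)
  }
  # switched force consistent with the numerical derivative of switched U
  r <- c(8.3, 8.9, 9.5)
  num <- numeric_force(function(x) hemeforge:::lj_switched(p, x)$U, r)
  expect_equal(hemeforge:::lj_switched(p, r)$F, num, tolerance = 1e-6)
})

test_that("bias terms follow their closed forms", {
  h <- bias_energy_force(bias_spec("harmonic", kappa = 3, r0 = 0), 2.8)
  expect_equal(h$energy, 11.76)
  expect_equal(abs(h$force), 8.4)
  w <- bias_energy_force(bias_spec("upper-wall", kappa = 150, ceiling = 1.89), 1.5)
  expect_equal(w$energy, 0); expect_equal(w$force, 0)
  w2 <- bias_energy_force(bias_spec("upper-wall", kappa = 150, ceiling = 1.89), 2.0)
  expect_equal(w2$energy, 0.5 * 150 * 0.11^2)
  mv <- bias_energy_force(bias_spec("moving-harmonic", kappa = 10, r0 = 1.9,
                                    rate = 1), x = 1.9, t = 1)
  expect_equal(mv$reference, 2.9)   # original length grown by 1 A after 1 ns
  # energy-force consistency across all kinds
  for (spec in list(bias_spec("harmonic", kappa = 7, r0 = 2),
                    bias_spec("lower-wall", kappa = 150, ceiling = 1.5))) {
    x <- seq(0.52, 3, 0.25)   # avoid differencing across the wall kink
    num <- numeric_force(function(v) bias_energy_force(spec, v)$energy, x)
    expect_equal(bias_energy_force(spec, x)$force, num, tolerance = 1e-6)
  }
})
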