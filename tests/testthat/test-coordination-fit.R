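test_that("coordination force extraction is exact subtraction", {
  r <- seq(1.75, 2.95, 0.1)
  truth <- potential_curve(r, F = lj_force(pair_fecco(), r) + smooth_background(r))
  zero <- potential_curve(r, F = rep(0, length(r)), label = "baseline")
  base <- potential_curve(r, F = smooth_background(r), label = "baseline")

  expect_equal(extract_coordination_force(truth, zero)$F, truth$F)
  expect_equal(extract_coordination_force(truth, truth)$F, rep(0, length(r)))
  crd <- extract_coordination_force(truth, base)
  expect_equal(crd$F, lj_force(pair_fecco(), r), tolerance = 1e-10)
  expect_identical(attr(crd, "curve_label"), "coordination")

  # disjoint grids: refuse without interpolation, resample with it
  shifted <- potential_curve(r + 0.05, F = smooth_background(r + 0.05))
  expect_error(extract_coordination_force(truth, shifted), "grids")
  crd2 <- extract_coordination_force(truth[2:12, ] |>
                                       (\(d) potential_curve(d$r, F = d$F))(),
                                     shifted, interpolate = TRUE)
  expect_equal(nrow(crd2), 11)
})

test_that("generate-then-fit recovers LJ parameters exactly", {
  # finite-difference path: the shipped Fe-C(CO) entry on the 0.1 A grid
  curve <- synthesize_ground_truth_curve(pair_fecco())
  fit <- fit_lj_to_force(finite_difference_force(curve))
  expect_true(fit$converged)
  expect_equal(fit$epsilon, -21.49, tolerance = 1e-4)
  expect_equal(fit$sigma, 1.79, tolerance = 1e-4)

  # analytic-force path with a clean two-parameter curve
  r <- seq(1.75, 2.95, 0.1)
  fc <- potential_curve(r, F = lj_force(lj_pair(-1, 2), r))
  fit2 <- fit_lj_to_force(fc)
  expect_equal(fit2$epsilon, -1, tolerance = 1e-6)
  expect_equal(fit2$sigma, 2, tolerance = 1e-6)

  # rmin-convention roundtrip is self-consistent
  fit3 <- fit_lj_to_force(fc, convention = "rmin")
  expect_equal(fit3$sigma, 2 * 2^(1/6), tolerance = 1e-6)

  # tidy/glance expose the estimates and the residual floor
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "sigma"], 1.79, tolerance = 1e-4)
  expect_lt(glance(fit)$residual_norm, 1e-8)
})

test_that("noisy fits are unbiased within their sampling band", {
  r <- seq(1.75, 2.95, 0.1)
  set.seed(7)
  eps_hat <- replicate(50, {
    f <- lj_force(pair_fecco(), r) + rnorm(length(r), sd = 0.5)
    fit_lj_to_force(potential_curve(r, F = f))$epsilon
  })
  # mean recovered well depth within the empirical 95% band around truth
  se <- sd(eps_hat) / sqrt(length(eps_hat))
  expect_lt(abs(mean(eps_hat) - (-21.49)), 2 * se + 0.02)
})

test_that("the fitting window is respected and degenerate input rejected", {
  r_in <- seq(1.75, 2.95, 0.1)
  r_wide <- seq(1.15, 3.95, 0.1)
  f_in <- fit_lj_to_force(potential_curve(r_in, F = lj_force(lj_pair(-5, 2.1), r_in)))
  f_wide <- fit_lj_to_force(potential_curve(
    r_wide, F = lj_force(lj_pair(-5, 2.1), r_wide) +
      ifelse(r_wide < 1.75 | r_wide > 2.95, 37, 0)))  # garbage outside window
  expect_equal(f_in$epsilon, f_wide$epsilon, tolerance = 1e-6)
  expect_equal(f_in$sigma, f_wide$sigma, tolerance = 1e-6)

  expect_error(fit_lj_to_force(potential_curve(c(2, 2.1, 2.2),
                                               F = c(-1, -1, -1))), "4 usable")
  # the residual of a non-LJ curve is reported, not hidden
  bad <- fit_lj_to_force(potential_curve(r_in, F = sin(4 * r_in)))
  expect_gt(bad$residual_norm, 0.1)

  # masking drops points: fit with a poisoned point + mask matches clean fit
  f_poison <- lj_force(lj_pair(-5, 2.1), r_in); f_poison[7] <- f_poison[7] - 25
  masked <- fit_lj_to_force(potential_curve(r_in, F = f_poison), mask = 7L)
  expect_equal(masked$epsilon, f_in$epsilon, tolerance = 1e-6)
})

test_that("effective single-LJ features behave like the underlying fit", {
  # degenerate two-site model (distal pair disabled) returns the active pair
  curve <- synthesize_ground_truth_curve(
    coordination_params(fe_cco = NULL, fe_o1 = NULL, fe_o2 = pair_feo2()))
  eff <- fit_effective_lj(finite_difference_force(curve))
  expect_equal(eff$epsilon_f, -6.55, tolerance = 1e-3)
  expect_equal(eff$sigma_f, 1.90, tolerance = 1e-3)

  # symmetric two-site curve: effective depth brackets the site depths
  two <- synthesize_ground_truth_curve(
    coordination_params(fe_cco = NULL, fe_o1 = pair_feo1(), fe_o2 = pair_feo2()))
  eff2 <- fit_effective_lj(finite_difference_force(two))
  expect_gt(abs(eff2$epsilon_f), 0.8 * 6.55)
  expect_lt(abs(eff2$epsilon_f), 6.55 + 4.37)

  # determinism for a fixed input curve
  eff3 <- fit_effective_lj(finite_difference_force(two))
  expect_identical(eff2$epsilon_f, eff3$epsilon_f)
})
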