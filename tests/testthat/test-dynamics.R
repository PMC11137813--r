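test_that("static energy scans match closed-form pair sums", {
  ps <- coordination_params()
  novdw <- generic_vdw_params(FALSE)

  # single coordination pair: scan equals the pair energy exactly
  co <- build_complex("CO")
  sc <- energy_scan(co, coordination_params(fe_o1 = NULL, fe_o2 = NULL),
                    vdw = novdw)
  expect_equal(sc$U, lj_energy(pair_fecco(), sc$r), tolerance = 1e-12)

  # two-site O2 scan: sum of proximal and distal terms at implied distances
  o2 <- build_complex("O2")
  sc2 <- energy_scan(o2, ps, vdw = novdw)
  d1 <- sqrt(sc2$r^2 + 1.21^2 - 2 * sc2$r * 1.21 * cos(120 * pi / 180))
  expect_equal(sc2$U, lj_energy(pair_feo2(), sc2$r) + lj_energy(pair_feo1(), d1),
               tolerance = 1e-9)

  # rigid rotation of the whole complex leaves the scan unchanged
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos <- as.matrix(o2[, c("x", "y", "z")]) %*% R
  o2r <- hemeforge:::with_positions(o2, pos)
  attr(o2r, "plane_normal") <- c(0, 0, 1)  # axis unchanged by z-rotation
  expect_equal(energy_scan(o2r, ps, vdw = novdw)$U, sc2$U, tolerance = 1e-9)

  # overlapping grid points are flagged, not silently returned
  tight <- energy_scan(co, ps, r = c(0.3, 2.0))
  expect_true(tight$flagged[1]); expect_false(tight$flagged[2])
})

test_that("the thermostat holds the target temperature", {
  ps <- coordination_params()
  co <- build_complex("CO")
  run <- run_langevin(co, ps, duration_ps = 300, seed = 5,
                      record_positions = FALSE)
  expect_lt(abs(mean(run$samples$temperature) - 300) / 300, 0.05)
  # free rigid rotor far from the scaffold: pure thermostat check
  far <- build_complex("O2", complex_geometry(fe_o2_start = 60))
  rot <- run_langevin(far, coordination_params(NULL, NULL, NULL),
                      duration_ps = 400, seed = 5,
                      vdw = generic_vdw_params(FALSE), record_positions = FALSE)
  expect_lt(abs(mean(rot$samples$temperature) - 300) / 300, 0.05)
})

test_that("dynamics is deterministic, conserves constraints, and stays put at 0 K", {
  ps <- coordination_params()
  o2 <- build_complex("O2")
  r1 <- run_langevin(o2, ps, duration_ps = 10, seed = 11)
  r2 <- run_langevin(o2, ps, duration_ps = 10, seed = 11)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$positions, r2$positions)

  # rigid O-O bond length drift below 1e-8 A on every recorded frame
  bond <- vapply(seq_len(nrow(r1$positions)), function(k) {
    p <- matrix(r1$positions[k, ], ncol = 3, byrow = TRUE)
    i <- match(c("o2", "o1"), o2$role)
    sqrt(sum((p[i[1], ] - p[i[2], ])^2))
  }, numeric(1))
  expect_lt(max(abs(bond - 1.21)), 1e-8)

  # zero temperature, start at the single-pair minimum: forces balance
  g <- complex_geometry(fe_c_start = 2^(1/6) * 1.79)
  co <- build_complex("CO", g)
  frozen <- run_langevin(co, coordination_params(fe_o1 = NULL, fe_o2 = NULL),
                         duration_ps = 4, temperature = 0, friction = 0,
                         vdw = generic_vdw_params(FALSE))
  drift <- hemeforge:::site_distance_series(frozen, "fe", "cco")
  expect_lt(max(abs(drift - 2^(1/6) * 1.79)), 1e-4)
})

test_that("equilibrium runs report stable observable statistics", {
  ps <- coordination_params()
  o2 <- build_complex("O2")
  run <- run_langevin(o2, ps, duration_ps = 22, seed = 31)
  g <- glance(run)
  expect_equal(g$frames, 110)
  expect_true(g$mean_angle > 90 && g$mean_angle < 160)
  # same seed, same angle statistics; different seed differs
  g2 <- glance(run_langevin(o2, ps, duration_ps = 22, seed = 31))
  expect_identical(g$mean_angle, g2$mean_angle)
  g3 <- glance(run_langevin(o2, ps, duration_ps = 22, seed = 32))
  expect_false(identical(g$mean_angle, g3$mean_angle))
})

test_that("a single particle in a harmonic well satisfies equipartition", {
  r <- simulate_cv_model("harmonic", par = list(k = 3), duration_ps = 1500,
                         seed = 13, mass = 16)
  keep <- r$samples$t_ps > 20
  expect_lt(abs(var(r$samples$x[keep]) - kB * 300 / 3) / (kB * 300 / 3), 0.1)
})
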