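ps_all <- coordination_params()

test_that("relaxation keeps CO walled and frees an unrestrained O2", {
  cx <- build_complex("CO+O2")
  st <- relax_system(cx, ps_all, o2_kappa = 3, duration_ps = 100, seed = 2,
                     record_positions = FALSE)
  # Fe-C never exceeds the wall ceiling by more than a few thermal
  # penetration depths sqrt(2 kT / kappa_wall)
  depth <- sqrt(2 * kB * 300 / 150)
  expect_lt(max(st$samples$cv_fe_cco), 1.89 + 4 * depth)
  # identical seeds give identical relaxed states
  st2 <- relax_system(cx, ps_all, o2_kappa = 3, duration_ps = 100, seed = 2,
                      record_positions = FALSE)
  expect_identical(st$complex, st2$complex)

  # with no restraint and the coordination pull to Fe blocked by CO, O2
  # eventually diffuses beyond 5 A
  g <- complex_geometry()
  g$fe_o2_start <- 4.0
  free <- relax_system(build_complex("CO+O2", g), ps_all, o2_kappa = 0,
                       duration_ps = 400, seed = 6)
  d <- hemeforge:::site_distance_series(free, "fe", "o2")
  expect_gt(max(d), 5)

  expect_error(relax_system(build_complex("O2"), ps_all), "CO")
})

test_that("quasi-static zero-temperature pulling reaches the analytic peak force", {
  # bare Fe-C pair, stiff spring, cold and slow: peak equals the maximal
  # attractive LJ force within 2%
  g <- complex_geometry(fe_c_start = 2^(1/6) * 1.79)
  co <- build_complex("CO", g)
  psc <- coordination_params(fe_o1 = NULL, fe_o2 = NULL)
  st <- run_langevin(co, psc, duration_ps = 5, temperature = 0, friction = 5,
                     vdw = generic_vdw_params(FALSE), record_positions = FALSE)
  fe <- run_smd(st, psc, kappa_pull = 200, rate = 100, max_extension = 2,
                temperature = 0, friction = 20,
                vdw = generic_vdw_params(FALSE), record_positions = FALSE)
  f_max <- lj_max_attraction(pair_fecco())$f_max
  expect_lt(abs(attr(fe, "peak_force") - f_max) / f_max, 0.02)
  expect_true(attr(fe, "ruptured"))
})

test_that("peak force weakens monotonically with the O2 restraint stiffness", {
  cx <- build_complex("CO+O2")
  sw <- run_smd_sweep(cx, ps_all, o2_kappas = c(0, 1, 3, 10), n_rep = 3,
                      seed = 17, relax_ps = 150, rate = 20)
  peaks <- sw$summary$mean_peak_force[order(sw$summary$o2_kappa)]
  sds <- sw$summary$sd_peak_force[order(sw$summary$o2_kappa)]
  # non-increasing within replicate error
  expect_true(all(diff(peaks) < sds[-length(sds)] + 1e-9))
  # the restrained O2 sits closer as the restraint stiffens
  d <- sw$summary$mean_fe_o2[order(sw$summary$o2_kappa)][-1]
  expect_true(all(diff(d) < 0.2))
  expect_true(all(diff(d) < 0))
})

test_that("rupture is brittle: no comparable second peak after failure", {
  co <- build_complex("CO")
  st <- relax_system(co, ps_all, duration_ps = 200, seed = 3,
                     record_positions = FALSE)
  fe <- run_smd(st, ps_all, rate = 20, record_positions = FALSE)
  expect_true(attr(fe, "ruptured"))
  rupt <- attr(fe, "rupture_index")
  # smoothed post-rupture force relaxes toward the free-spring baseline
  post <- fe$force[seq(min(rupt + 20, nrow(fe)), nrow(fe))]
  smooth_max <- max(stats::filter(post, rep(1 / 25, 25), sides = 2), na.rm = TRUE)
  expect_lt(smooth_max, 0.5 * attr(fe, "peak_force"))
})

test_that("well-tempered hills start at 8 kcal/mol and decay on revisits", {
  cx <- build_complex("CO+O2")
  md <- run_wt_metad(cx, ps_all, duration_ps = 60, seed = 9,
                     record_positions = FALSE)
  expect_equal(md$hills$height[1], 8, tolerance = 1e-6)
  expect_equal(nrow(md$hills), 60)   # 1 hill per ps
  # every height obeys the well-tempered schedule
  # h_k = h0 exp(-V(s_k) / ((gamma - 1) kT)), with V(s_k) the bias
  # accumulated at the deposit point from all earlier hills
  h <- md$hills
  for (k in c(5, 20, 40, 60)) {
    prev <- seq_len(k - 1)
    v <- sum(h$height[prev] *
               exp(-0.5 * ((h$d_fe_c[k] - h$d_fe_c[prev])^2 +
                           (h$d_fe_o2[k] - h$d_fe_o2[prev])^2) / 0.2^2))
    expect_equal(h$height[k], 8 * exp(-v / ((10 - 1) * kB * 300)),
                 tolerance = 0.05)
  }
  # heights can never grow back above the initial height
  expect_true(all(h$height <= 8 + 1e-9))
})

test_that("flat and double-well landscapes are reconstructed within tolerance", {
  # flat landscape: long-run bias is flat within tolerance
  fl <- simulate_cv_model("flat", duration_ps = 1500, seed = 23, x0 = 0,
                          walls = c(-2, 2), wall_kappa = 20,
                          metad = list(height = 0.5, sigma = 0.25, every_ps = 1,
                                       bias_factor = 10, grid_min = -3.5,
                                       grid_max = 3.5))
  fes_fl <- reconstruct_fes(fl$hills, bias_factor = 10, hill_sigma = 0.25,
                            grid = seq(-1.5, 1.5, 0.05))
  expect_lt(max(fes_fl$free_energy) - min(fes_fl$free_energy), 0.6)

  # analytic double well, barrier 3 kcal/mol at x = 0, minima at +/- 1
  dw <- simulate_cv_model("double-well", par = list(h = 3, a = 1),
                          duration_ps = 4000, seed = 29, x0 = -1,
                          walls = c(-2.2, 2.2), wall_kappa = 50,
                          metad = list(height = 0.5, sigma = 0.15, every_ps = 0.5,
                                       bias_factor = 8, grid_min = -3,
                                       grid_max = 3))
  fes_dw <- reconstruct_fes(dw$hills, bias_factor = 8, hill_sigma = 0.15,
                            grid = seq(-1.4, 1.4, 0.02))
  est <- fes_dw$free_energy
  barrier <- est[which.min(abs(fes_dw$cv))] -
    (est[which.min(abs(fes_dw$cv + 1))] + est[which.min(abs(fes_dw$cv - 1))]) / 2
  expect_lt(abs(barrier - 3), 0.5)
  # RMS agreement with the analytic landscape over the sampled region
  truth <- 3 * (fes_dw$cv^2 - 1)^2
  resid <- (est - mean(est)) - (truth - mean(truth))
  expect_lt(sqrt(mean(resid^2)), 0.5)
})

test_that("a single deposited hill reconstructs as one scaled Gaussian well", {
  hills <- tibble::tibble(t_ps = 1, d_fe_c = 2.0, d_fe_o2 = 2.5, height = 8)
  fes <- reconstruct_fes(hills, bias_factor = 10, hill_sigma = 0.2,
                         grid = seq(1.5, 3, 0.05))
  expect_equal(min(fes$free_energy), 0)
  expect_equal(max(fes$free_energy), (10 / 9) * 8, tolerance = 1e-3)
  i <- which.min(fes$free_energy)
  expect_equal(fes$d_fe_c[i], 2.0); expect_equal(fes$d_fe_o2[i], 2.5)
  expect_error(reconstruct_fes(hills, bias_factor = 1), "bias_factor")
  expect_error(reconstruct_fes(hills[0, ], bias_factor = 10, hill_sigma = 0.2),
               "empty")
})

test_that("effective bond energy slices behave like barrier heights", {
  # surface built from a pure LJ free energy along Fe-C (no barrier beyond
  # the well): effective bond energy equals the well depth
  grid <- seq(1.5, 5.0, 0.05)
  gg <- tidyr::expand_grid(d_fe_c = grid, d_fe_o2 = grid)
  gg$free_energy <- lj_energy(pair_fecco(), gg$d_fe_c)
  gg$free_energy <- gg$free_energy - min(gg$free_energy)
  fes <- structure(gg, class = c("fes", class(tibble::tibble())),
                   bias_factor = 10, hill_sigma = 0.2, two_d = TRUE)
  sl <- slice_effective_bond_energy(fes, 3.0)
  expect_equal(sl$effective_bond_energy, 21.49, tolerance = 0.05)
  expect_equal(sl$r_min, 2^(1/6) * 1.79, tolerance = 0.05)
  expect_false(sl$flagged)

  # gauge invariance: adding a constant changes nothing
  fes2 <- fes; fes2$free_energy <- fes2$free_energy + 7
  expect_equal(slice_effective_bond_energy(fes2, 3.0)$effective_bond_energy,
               sl$effective_bond_energy)

  # a monotone slice (no interior minimum) is flagged
  fes3 <- fes; fes3$free_energy <- fes3$d_fe_c
  expect_true(slice_effective_bond_energy(fes3, 3.0)$flagged)
})

test_that("approach-pattern geometry separates axial from peripheral O2", {
  cx <- build_complex("CO+O2")
  i <- match(c("o2", "o1"), cx$role)
  pos <- as.matrix(cx[, c("x", "y", "z")])
  mk_run <- function(o2_xyz) {
    p <- pos
    p[i[1], ] <- o2_xyz
    p[i[2], ] <- o2_xyz + c(0, 0, 1.21)
    frames <- matrix(as.vector(t(p)), nrow = 1)
    structure(list(complex = hemeforge:::with_positions(cx, p),
                   positions = frames,
                   samples = tibble::tibble(t_ps = 1)), class = "md_run")
  }
  # directly above Fe: Fe is the nearest partner
  ax <- approach_pattern(mk_run(c(0, 0, 2.5)))
  expect_lt(ax$d_fe, ax$d_nheme)
  # above a pyrrole nitrogen: that nitrogen is nearer than Fe
  pe <- approach_pattern(mk_run(c(2, 0, 1.2)))
  expect_lt(pe$d_nheme, pe$d_fe)

  # synthetic slide from the periphery to the axial site flips the
  # criterion exactly once
  xs <- seq(2.8, 0, length.out = 40)
  frames <- t(vapply(xs, function(x) {
    p <- pos
    p[i[1], ] <- c(x, 0, 1.2 + (2.8 - x) / 2.8 * 1.3)
    p[i[2], ] <- p[i[1], ] + c(0, 0, 1.21)
    as.vector(t(p))
  }, numeric(3 * nrow(pos))))
  run <- structure(list(complex = cx, positions = frames,
                        samples = tibble::tibble(t_ps = seq_along(xs))),
                   class = "md_run")
  ap <- approach_pattern(run)
  flips <- sum(diff(ap$d_fe < ap$d_nheme) != 0)
  expect_equal(flips, 1)
  expect_true(attr(ap, "direct_fraction") > 0)
})
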