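#' Sample the two-site parameter database
#'
#' Draws candidate (epsilon1, sigma1, epsilon2, sigma2) quadruples for the
#' two-site Fe-O2 model uniformly over the admissible region: well depths
#' as magnitudes in kcal/mol with 8 < eps1 + eps2 < 12 and
#' 0.3 < eps1/eps2 < 0.6, lengths 2.5 < sigma1 < 3 and 1.8 < sigma2 < 2.05
#' Angstrom. Sampling is uniform over the bounding box with rejection on
#' the sum/ratio constraints.
#'
#' @param n_total Number of records (default 12000).
#' @param seed Optional seed.
#' @return A tibble `record`, `epsilon1`, `sigma1`, `epsilon2`, `sigma2`
#'   (epsilons as positive magnitudes; the physics boundary converts to
#'   the signed convention).
#' @export
sample_param_database <- function(n_total = 12000, seed = NULL) {
  stopifnot(n_total > 0)
  if (!is.null(seed)) set.seed(seed)
  eps1 <- numeric(0); eps2 <- numeric(0)
  while (length(eps1) < n_total) {
    m <- 2L * (n_total - length(eps1)) + 64L
    c1 <- runif(m, 1.8, 4.6)
    c2 <- runif(m, 4.9, 9.3)
    ok <- (c1 + c2 > 8) & (c1 + c2 < 12) & (c1 / c2 > 0.3) & (c1 / c2 < 0.6)
    eps1 <- c(eps1, c1[ok]); eps2 <- c(eps2, c2[ok])
  }
  tibble::tibble(record = seq_len(n_total),
                 epsilon1 = eps1[seq_len(n_total)],
                 sigma1 = runif(n_total, 2.5, 3.0),
                 epsilon2 = eps2[seq_len(n_total)],
                 sigma2 = runif(n_total, 1.8, 2.05))
}

#' Validate database records against the sampling ranges
#'
#' @param db A parameter tibble as from [sample_param_database()].
#' @return Logical vector: does each record satisfy all four constraints?
#' @export
validate_param_record <- function(db) {
  s <- db$epsilon1 + db$epsilon2
  q <- db$epsilon1 / db$epsilon2
  s > 8 & s < 12 & q > 0.3 & q < 0.6 &
    db$sigma1 > 2.5 & db$sigma1 < 3.0 &
    db$sigma2 > 1.8 & db$sigma2 < 2.05
}

#' Split a database into training and testing partitions
#'
#' Seeded random split; an 80/20 split of 12,000 records gives exactly
#' 9,600 training and 2,400 testing records.
#'
#' @param db Database tibble.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Optional seed.
#' @return The tibble with a `partition` factor column (train/test).
#' @export
partition_database <- function(db, train_frac = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(db)
  n_train <- round(train_frac * n)
  idx <- sample.int(n, n_train)
  db$partition <- factor(ifelse(seq_len(n) %in% idx, "train", "test"),
                         levels = c("train", "test"))
  db
}

# equilibrium (r, theta) of the two-site ligand over the coordination terms
optimize_o2_pose <- function(p1, p2, o2_bond = 1.21) {
  obj <- function(par) {
    r <- par[1]; th <- par[2]
    if (r < 1.2 || r > 4 || th < 95 || th > 180) return(1e6)
    d1 <- sqrt(r^2 + o2_bond^2 - 2 * r * o2_bond * cos(th * pi / 180))
    lj_energy(p2, r) + lj_energy(p1, d1)
  }
  fit <- stats::optim(c(2.1, 120), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  list(r = fit$par[1], theta = min(180, max(95, fit$par[2])))
}

#' Compute the three inverse-design features of one parameter record
#'
#' For a two-site parameter quadruple, runs the same reduced-model
#' procedures used for the reference data: (1) a static energy scan along
#' the Fe-O2 axis at the record's relaxed tilt pose, finite-differenced
#' and fitted with a single effective LJ force law, giving
#' (epsilon_f, sigma_f); (2) an equilibrium Langevin run of the
#' heme-imidazole-O2 complex, giving the mean Fe-O2-O1 angle over
#' `n_snapshots` samples spanning `angle_ps`.
#'
#' @param epsilon1,sigma1,epsilon2,sigma2 Record parameters (epsilon as
#'   positive magnitudes, kcal/mol; sigma in Angstrom).
#' @param seed Seed for the equilibrium run.
#' @param angle_ps Sampled equilibrium time, ps (default 20).
#' @param n_snapshots Snapshots for the angle mean (default 100).
#' @param equil_ps Discarded equilibration, ps.
#' @param geometry A [complex_geometry()].
#' @param vdw Generic vdW table.
#' @return A one-row tibble `mean_angle` (deg), `epsilon_f` (kcal/mol,
#'   signed negative), `sigma_f` (Angstrom), `converged`.
#' @export
featurize_record <- function(epsilon1, sigma1, epsilon2, sigma2, seed = NULL,
                             angle_ps = 20, n_snapshots = 100, equil_ps = 2,
                             geometry = complex_geometry(),
                             vdw = generic_vdw_params()) {
  p1 <- lj_pair(-abs(epsilon1), sigma1)
  p2 <- lj_pair(-abs(epsilon2), sigma2)
  params <- coordination_params(fe_cco = NULL, fe_o1 = p1, fe_o2 = p2)

  pose <- optimize_o2_pose(p1, p2, geometry$o2_bond)
  g <- geometry
  g$fe_o2_start <- pose$r
  g$o2_tilt <- pose$theta
  cx <- build_complex("O2", g)

  # effective-LJ features from the scan of the full complex energy
  scan <- energy_scan(cx, params, r = seq(1.75, 2.95, by = 0.1),
                      vdw = vdw, ligand = "O2")
  fcurve <- finite_difference_force(scan)
  eff <- tryCatch({
    v <- which(!is.na(fcurve$F))
    cross <- which(diff(sign(fcurve$F[v])) != 0)[1]
    s0 <- if (is.na(cross)) sigma2
          else max(1.2, min(3.8, fcurve$r[v][cross] / 2^(1/6)))
    fit_effective_lj(fcurve, model = "fd", start_sigma = s0)
  }, error = function(e) NULL)

  # equilibrium angle from dynamics
  stride <- angle_ps / n_snapshots
  run <- run_langevin(cx, params, duration_ps = angle_ps + equil_ps,
                      seed = seed, sample_every_ps = stride, vdw = vdw,
                      record_positions = TRUE)
  ang <- measure_angle(run)
  keep <- run$samples$t_ps > equil_ps
  mean_angle <- mean(tail(ang[keep], n_snapshots))

  if (is.null(eff) || !eff$fit$converged) {
    tibble::tibble(mean_angle = mean_angle, epsilon_f = NA_real_,
                   sigma_f = NA_real_, converged = FALSE)
  } else {
    tibble::tibble(mean_angle = mean_angle, epsilon_f = eff$epsilon_f,
                   sigma_f = eff$sigma_f, converged = TRUE)
  }
}

#' Featurize a whole parameter database
#'
#' Maps [featurize_record()] over the database rows with per-record seeds
#' `seed + record`. Records whose effective fit does not converge are
#' flagged (`converged = FALSE`) and the count is reported; training
#' excludes them.
#'
#' @param db Tibble from [sample_param_database()].
#' @param seed Base seed.
#' @param ... Passed to [featurize_record()] (`angle_ps`, `n_snapshots`,
#'   `geometry`, ... — reduced-cost runs shorten `angle_ps`).
#' @param progress Print a progress note every 2000 records.
#' @return `db` with feature columns appended.
#' @export
featurize_database <- function(db, seed = 1, ..., progress = FALSE) {
  feats <- purrr::pmap(
    list(db$epsilon1, db$sigma1, db$epsilon2, db$sigma2, db$record),
    function(e1, s1, e2, s2, id) {
      if (progress && id %% 2000 == 0) message("featurized ", id, " records")
      featurize_record(e1, s1, e2, s2, seed = seed + id, ...)
    })
  out <- dplyr::bind_cols(db, dplyr::bind_rows(feats))
  n_bad <- sum(!out$converged)
  if (n_bad > 0)
    message(n_bad, " record(s) flagged: effective-LJ fit did not converge")
  out
}
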