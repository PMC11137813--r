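#' Static energy scan along the out-of-plane axis
#'
#' Rigidly translates the gas ligand along the heme plane normal so that
#' the Fe-to-bond-forming-atom distance takes each requested value, and
#' records the total potential energy of the displaced configuration (a
#' step-0 energy evaluation; no dynamics). Grid points that push any site
#' pair below a hard floor of 0.5 Angstrom are flagged.
#'
#' @param complex A [build_complex()] result with one ligand.
#' @param params A [coordination_params()] set.
#' @param r Distance grid, Angstrom (> 0).
#' @param vdw Generic vdW table ([generic_vdw_params()]); pass
#'   `generic_vdw_params(FALSE)` to scan the coordination terms alone.
#' @param ligand Which ligand to translate when both are present
#'   (`"auto"`, `"CO"` or `"O2"`).
#' @return A [potential_curve()] labelled `"model"` with a `flagged`
#'   column.
#' @export
energy_scan <- function(complex, params, r = seq(1.75, 2.95, by = 0.1),
                        vdw = generic_vdw_params(), ligand = "auto") {
  stopifnot(inherits(complex, "reduced_complex"))
  if (any(r <= 0)) stop("scan grid must be positive", call. = FALSE)
  roles <- complex$role
  has_co <- "c_co" %in% roles; has_o2 <- "o2" %in% roles
  if (!has_co && !has_o2) stop("complex has no ligand to scan", call. = FALSE)
  if (ligand == "auto") ligand <- if (has_co) "CO" else "O2"
  anchor_role <- if (ligand == "CO") "c_co" else "o2"
  move_roles <- if (ligand == "CO") c("c_co", "o_co") else c("o2", "o1")
  if (!anchor_role %in% roles) stop("requested ligand not in complex", call. = FALSE)

  pos0 <- complex_positions(complex)
  fe <- pos0[match("fe", roles), ]
  anchor <- match(anchor_role, roles)
  movers <- which(roles %in% move_roles)
  nrm <- attr(complex, "plane_normal")
  pairs <- pair_table(complex, params, vdw)

  d0 <- pos0[anchor, ] - fe
  a_par <- sum(d0 * nrm)                     # axial component
  a_perp2 <- sum(d0^2) - a_par^2             # squared off-axis component
  u <- numeric(length(r)); flag <- logical(length(r))
  for (k in seq_along(r)) {
    if (r[k]^2 < a_perp2) { u[k] <- NA_real_; flag[k] <- TRUE; next }
    shift <- (sqrt(r[k]^2 - a_perp2) - a_par) * nrm
    pos <- pos0
    pos[movers, ] <- sweep(pos0[movers, , drop = FALSE], 2, shift, `+`)
    d2 <- rowSums((pos[pairs[, 1], , drop = FALSE] - pos[pairs[, 2], , drop = FALSE])^2)
    flag[k] <- length(d2) > 0 && min(d2) < 0.25
    u[k] <- pair_energy_cpp(pos, pairs, 8, 10)
  }
  out <- tibble::tibble(r = r, U = u, flagged = flag)
  new_potential_curve(out, label = "model")
}

#' Run Langevin dynamics on a reduced complex
#'
#' Integrates the mobile sites (the gas ligands; the heme scaffold is held
#' fixed) with a BAOAB Langevin integrator, rigid diatomic bonds enforced
#' by SHAKE/RATTLE, switched pair interactions, and any number of distance
#' biases. All randomness flows from R's RNG, so `set.seed()` (or the
#' `seed` argument) makes runs bitwise reproducible.
#'
#' @param complex A [build_complex()] result (or the `complex` of a
#'   previous run to continue from its positions).
#' @param params A [coordination_params()] set.
#' @param biases List of `list(spec = bias_spec(...), cv = c(site_i,
#'   site_j))` distance biases (site names as in the complex).
#' @param duration_ps Simulated time, ps.
#' @param dt_fs Time step, fs (default 2).
#' @param temperature Thermostat target, K (default 300).
#' @param friction Langevin friction, 1/ps.
#' @param seed Optional integer seed.
#' @param sample_every_ps Observable sampling interval, ps.
#' @param vdw Generic vdW table.
#' @param metad Optional metadynamics spec (internal; see
#'   [run_wt_metad()]).
#' @param velocities Optional starting velocities (matrix), e.g. from a
#'   previous run's `$velocities`.
#' @param record_positions Keep strided position frames (default TRUE).
#' @return An object of class `md_run`: updated `complex`, `velocities`,
#'   a `samples` tibble (time, kinetic temperature, per-bias CV value and
#'   spring force), raw `positions` frames, and any hills/bias grids.
#' @export
run_langevin <- function(complex, params, biases = list(), duration_ps,
                         dt_fs = 2, temperature = 300, friction = 5,
                         seed = NULL, sample_every_ps = 0.2,
                         vdw = generic_vdw_params(), metad = NULL,
                         velocities = NULL, record_positions = TRUE) {
  stopifnot(inherits(complex, "reduced_complex"))
  if (!is.null(seed)) set.seed(seed)
  pos <- complex_positions(complex)
  n <- nrow(pos)
  mass <- ELEMENT_MASS[complex$element]
  vel <- if (is.null(velocities)) matrix(0, n, 3) else velocities
  cmat <- attr(complex, "constraints")
  pairs <- pair_table(complex, params, vdw)
  bm <- if (length(biases)) {
    bias_matrix(lapply(biases, function(b) {
      list(spec = b$spec, i = site_index(complex, b$cv[1]),
           j = site_index(complex, b$cv[2]))
    }))
  } else matrix(numeric(0), ncol = 7)
  stride <- max(1L, as.integer(round(sample_every_ps * 1000 / dt_fs)))
  nsteps <- max(stride, as.integer(round(duration_ps * 1000 / dt_fs)))

  res <- run_md_cpp(pos, vel, mass, as.integer(complex$mobile), pairs,
                    cmat, bm, nsteps, dt_fs, temperature, friction,
                    8, 10, stride, record_positions, metad)
  if (res$diverged_at >= 0)
    stop(sprintf("dynamics diverged (site overlap/instability) at step %d",
                 as.integer(res$diverged_at)), call. = FALSE)

  samples <- tibble::tibble(t_ps = res$t_ps, temperature = res$temperature)
  if (length(biases)) {
    for (k in seq_along(biases)) {
      lbl <- paste(biases[[k]]$cv, collapse = "_")
      samples[[paste0("cv_", lbl)]] <- res$cv[, k]
      samples[[paste0("force_", lbl)]] <- res$bias_force[, k]
    }
  }
  hills <- if (!is.null(res$hills) && length(res$hills) > 0)
    tibble::as_tibble(res$hills) else NULL
  structure(list(
    complex = with_positions(complex, res$pos),
    velocities = res$vel,
    samples = samples,
    positions = if (record_positions) res$positions else NULL,
    metad_cv = if (!is.null(metad)) res$metad_cv else NULL,
    hills = hills,
    bias_grid = res$bias_grid,
    config = list(duration_ps = duration_ps, dt_fs = dt_fs,
                  temperature = temperature, friction = friction,
                  seed = seed, sample_every_ps = sample_every_ps,
                  biases = biases)
  ), class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  cat(sprintf("<md_run> %g ps, %d samples, mean T = %.1f K\n",
              x$config$duration_ps, nrow(x$samples), mean(x$samples$temperature)))
  invisible(x)
}

#' Summary statistics of a dynamics run
#'
#' One-row tibble: frames sampled, mean/sd of the tracked distance CVs,
#' the Fe-O2-O1 angle when an O2 ligand is present, and the mean kinetic
#' temperature.
#'
#' @param x An `md_run`.
#' @param ... Unused.
#' @method glance md_run
#' @export
glance.md_run <- function(x, ...) {
  out <- tibble::tibble(frames = nrow(x$samples),
                        mean_temperature = mean(x$samples$temperature))
  cvcols <- grep("^cv_", names(x$samples), value = TRUE)
  for (cc in cvcols) {
    out[[paste0("mean_", sub("^cv_", "", cc))]] <- mean(x$samples[[cc]])
    out[[paste0("sd_", sub("^cv_", "", cc))]] <- sd(x$samples[[cc]])
  }
  if (all(c("o1", "o2") %in% x$complex$role) && !is.null(x$positions)) {
    ang <- measure_angle(x)
    out$mean_angle <- mean(ang)
    out$sd_angle <- sd(ang)
  }
  out
}

# distance between two named sites on every recorded frame
site_distance_series <- function(run, site_a, site_b) {
  cx <- run$complex
  i <- site_index(cx, site_a); j <- site_index(cx, site_b)
  frames <- run$positions
  d <- frames[, (3 * (i - 1) + 1):(3 * i), drop = FALSE] -
       frames[, (3 * (j - 1) + 1):(3 * j), drop = FALSE]
  sqrt(rowSums(d^2))
}
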