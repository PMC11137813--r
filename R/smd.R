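#' Relax a complex under the pre-pull bias protocol
#'
#' Equilibrates the system before steered pulling or metadynamics: an
#' upper wall on the Fe-C(CO) distance (ceiling 1.89 Angstrom, stiffness
#' 150 kcal/mol/A^2) keeps CO coordinated, and, when an O2 ligand is
#' present with `o2_kappa > 0`, a harmonic restraint with reference length
#' zero on the Fe-O2(proximal) distance emulates the O2-rich environment.
#'
#' @param complex A [build_complex()] result containing CO.
#' @param params A [coordination_params()] set.
#' @param o2_kappa O2 restraint stiffness, kcal/mol/A^2 (0 disables).
#' @param duration_ps Relaxation length, ps (default 1000 = 1 ns).
#' @param wall_ceiling,wall_kappa Fe-C wall position and stiffness.
#' @param ... Passed to [run_langevin()] (`seed`, `temperature`, ...).
#' @return An `md_run`; its `$complex`/`$velocities` are the relaxed state.
#' @export
relax_system <- function(complex, params, o2_kappa = 0, duration_ps = 1000,
                         wall_ceiling = 1.89, wall_kappa = 150, ...) {
  roles <- complex$role
  if (!"c_co" %in% roles) stop("relaxation protocol expects a CO ligand", call. = FALSE)
  if (o2_kappa > 0 && !"o2" %in% roles)
    stop("`o2_kappa` > 0 requires an O2 ligand", call. = FALSE)
  biases <- list(list(spec = bias_spec("upper-wall", kappa = wall_kappa,
                                       ceiling = wall_ceiling),
                      cv = c("fe", "cco")))
  if (o2_kappa > 0)
    biases <- c(biases, list(list(spec = bias_spec("harmonic", kappa = o2_kappa, r0 = 0),
                                  cv = c("fe", "o2"))))
  run_langevin(complex, params, biases = biases, duration_ps = duration_ps, ...)
}

#' Steered pull of the Fe-CO bond
#'
#' Pulls the Fe-C(CO) distance with a moving harmonic restraint whose
#' reference length grows at a constant rate from its starting value,
#' while an optional fixed harmonic restraint holds O2 near the iron.
#' Returns the force-extension trace of the pulling spring and the peak
#' rupture force.
#'
#' @param state A relaxed `md_run` from [relax_system()].
#' @param params A [coordination_params()] set.
#' @param kappa_pull Pulling-spring stiffness, kcal/mol/A^2 (default 10).
#' @param rate Reference-length velocity, Angstrom/ns (default 1; desk
#'   runs may scale this up, and the value used is recorded with the
#'   result).
#' @param o2_kappa O2 restraint stiffness during the pull, kcal/mol/A^2.
#' @param max_extension Pull distance, Angstrom (default 4).
#' @param replicate Replicate id stored with the trace.
#' @param rupture_cut Fe-C distance marking bond rupture, Angstrom
#'   (default 3.5, well past the attractive range of the pair). The peak
#'   force is taken over the trace up to the first crossing: after
#'   rupture the spring force is pure thermal noise of the freed ligand,
#'   whose running maximum would grow without bound and says nothing
#'   about the bond.
#' @param ... Passed to [run_langevin()].
#' @return A tibble of class `force_extension`: `t_ps`, `extension` (A),
#'   `force` (kcal/mol/A), `fe_c`, `fe_o2` (A, if O2 present),
#'   `replicate`; attributes `peak_force`, `peak_index`,
#'   `rupture_index`, `rate`, `ruptured` (a replicate that never
#'   ruptures is flagged `ruptured = FALSE` and its peak is the whole-
#'   trace maximum).
#' @export
run_smd <- function(state, params, kappa_pull = 10, rate = 1, o2_kappa = 0,
                    max_extension = 4, replicate = 1L, rupture_cut = 3.5, ...) {
  stopifnot(inherits(state, "md_run"))
  cx <- state$complex
  start <- sqrt(sum((complex_positions(cx)[site_index(cx, "fe"), ] -
                     complex_positions(cx)[site_index(cx, "cco"), ])^2))
  biases <- list(list(spec = bias_spec("moving-harmonic", kappa = kappa_pull,
                                       r0 = start, rate = rate),
                      cv = c("fe", "cco")))
  if (o2_kappa > 0)
    biases <- c(biases, list(list(spec = bias_spec("harmonic", kappa = o2_kappa, r0 = 0),
                                  cv = c("fe", "o2"))))
  duration_ps <- max_extension / rate * 1000
  run <- run_langevin(cx, params, biases = biases, duration_ps = duration_ps,
                      velocities = state$velocities, ...)
  s <- run$samples
  has_o2 <- "o2" %in% cx$role
  out <- tibble::tibble(
    t_ps = s$t_ps,
    extension = rate * s$t_ps / 1000,
    force = s$force_fe_cco,
    fe_c = s$cv_fe_cco,
    fe_o2 = if (has_o2 && o2_kappa > 0) s$cv_fe_o2
            else if (has_o2) site_distance_series(run, "fe", "o2")
            else NA_real_,
    replicate = as.integer(replicate))
  rupt_i <- which(out$fe_c > rupture_cut)[1]
  ruptured <- !is.na(rupt_i)
  window <- seq_len(if (ruptured) rupt_i else nrow(out))
  peak_i <- window[which.max(out$force[window])]
  structure(out, class = c("force_extension", class(tibble::tibble())),
            peak_force = out$force[peak_i], peak_index = peak_i,
            rupture_index = if (ruptured) rupt_i else NA_integer_,
            rate = rate, kappa_pull = kappa_pull, o2_kappa = o2_kappa,
            ruptured = ruptured)
}

#' Peak-force sweep over the O2 restraint stiffness
#'
#' The full rupture assay: for each O2 restraint stiffness, relax the
#' CO+O2 complex under the wall/restraint protocol and steer the Fe-CO
#' bond to rupture, with `n_rep` seeded replicates (seeds `seed`,
#' `seed+1`, ...). The control arm `o2_kappa = 0` runs without an O2
#' molecule near the iron. Reported per stiffness: mean and sd of the
#' peak force and the time-mean restrained Fe-O2 distance over the pull.
#'
#' @param complex A CO+O2 [build_complex()] result (the control arm uses a
#'   CO-only complex built with the same geometry).
#' @param params A [coordination_params()] set.
#' @param o2_kappas Stiffness values to sweep, kcal/mol/A^2.
#' @param n_rep Replicates per stiffness (default 5).
#' @param seed Base seed; replicate j of arm k uses `seed + (k-1)*n_rep +
#'   (j-1)`.
#' @param relax_ps Relaxation length per replicate, ps.
#' @param rate Pulling rate, Angstrom/ns (recorded with the result).
#' @param kappa_pull Pulling-spring stiffness.
#' @param max_extension Pull distance, Angstrom.
#' @param ... Passed to the underlying runs.
#' @return An object of class `smd_sweep`: `$curves` (all traces),
#'   `$replicates` (per-replicate peaks), `$summary` (per-stiffness mean
#'   +/- sd peak force and mean restrained Fe-O2 distance).
#' @export
run_smd_sweep <- function(complex, params, o2_kappas = c(0, 1, 3, 5, 10),
                          n_rep = 5, seed = 1, relax_ps = 1000, rate = 1,
                          kappa_pull = 10, max_extension = 4, ...) {
  stopifnot(inherits(complex, "reduced_complex"))
  geometry <- attr(complex, "geometry")
  cx_co <- build_complex("CO", geometry)
  arms <- purrr::imap(o2_kappas, function(kap, k) {
    cx <- if (kap > 0) complex else cx_co
    purrr::map(seq_len(n_rep), function(j) {
      sd_j <- seed + (k - 1L) * n_rep + (j - 1L)
      st <- relax_system(cx, params, o2_kappa = kap, duration_ps = relax_ps,
                         seed = sd_j, record_positions = FALSE, ...)
      fe <- run_smd(st, params, kappa_pull = kappa_pull, rate = rate,
                    o2_kappa = kap, max_extension = max_extension,
                    replicate = j, record_positions = FALSE, ...)
      fe$o2_kappa <- kap
      fe
    })
  })
  all_curves <- purrr::map(arms, function(a) {
    dplyr::bind_rows(lapply(a, tibble::as_tibble))
  })
  reps <- dplyr::bind_rows(purrr::imap(arms, function(a, k) {
    tibble::tibble(
      o2_kappa = o2_kappas[k],
      replicate = seq_along(a),
      peak_force = vapply(a, function(fe) attr(fe, "peak_force"), numeric(1)),
      ruptured = vapply(a, function(fe) attr(fe, "ruptured"), logical(1)),
      mean_fe_o2 = vapply(a, function(fe) {
        if (all(is.na(fe$fe_o2))) NA_real_ else mean(fe$fe_o2)
      }, numeric(1)))
  }))
  summary <- reps |>
    dplyr::group_by(.data$o2_kappa) |>
    dplyr::summarise(mean_peak_force = mean(.data$peak_force),
                     sd_peak_force = sd(.data$peak_force),
                     sd_fe_o2 = sd(.data$mean_fe_o2),
                     mean_fe_o2 = mean(.data$mean_fe_o2),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("mean_fe_o2", .before = "sd_fe_o2")
  structure(list(curves = dplyr::bind_rows(all_curves), replicates = reps,
                 summary = summary,
                 config = list(rate = rate, kappa_pull = kappa_pull,
                               n_rep = n_rep, seed = seed, relax_ps = relax_ps)),
            class = "smd_sweep")
}

#' @export
print.smd_sweep <- function(x, ...) {
  cat(sprintf("<smd_sweep> rate = %g A/ns, kappa_pull = %g, n = %d replicates\n",
              x$config$rate, x$config$kappa_pull, x$config$n_rep))
  print(x$summary)
  invisible(x)
}

#' @method autoplot force_extension
#' @export
autoplot.force_extension <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$extension, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "extension (Å)", y = "pulling force (kcal/mol/Å)") +
    ggplot2::theme_minimal()
}

#' @method autoplot smd_sweep
#' @export
autoplot.smd_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$o2_kappa, y = .data$mean_peak_force)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_peak_force - .data$sd_peak_force,
      ymax = .data$mean_peak_force + .data$sd_peak_force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(O[2]~restraint~stiffness~(kcal/mol/ring(A)^2)),
                  y = "mean peak force (kcal/mol/Å)") +
    ggplot2::theme_minimal()
}
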