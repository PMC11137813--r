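#' Well-tempered metadynamics over the two bond-length CVs
#'
#' Deposits Gaussian hills on the Fe-C(CO) and Fe-O2(proximal) distance
#' collective variables at a fixed stride, with the well-tempered height
#' schedule \eqn{h(t) = h_0 \exp[-V(s,t) / ((\gamma - 1) k_B T)]}. Upper
#' walls on both CVs (default ceiling 5 Angstrom, stiffness 150
#' kcal/mol/A^2) keep the ligands in the rebinding region. Defaults follow
#' the standard competitive-binding protocol: initial hill height 8
#' kcal/mol, hill width 0.2 Angstrom, one hill per ps.
#'
#' The bias factor gamma is a free choice of the protocol (default 10)
#' and is recorded with every output.
#'
#' @param complex A CO+O2 [build_complex()] result (or a relaxed state's
#'   `$complex`).
#' @param params A [coordination_params()] set.
#' @param duration_ps Simulated time, ps.
#' @param hill_height Initial hill height, kcal/mol (default 8).
#' @param hill_sigma Hill width, Angstrom (default 0.2).
#' @param hill_every_ps Deposition stride, ps (default 1).
#' @param bias_factor Well-tempered gamma (> 1, default 10).
#' @param wall_ceiling,wall_kappa Upper-wall position/stiffness on both
#'   CVs.
#' @param grid_min,grid_max,grid_n Bias grid for the CVs.
#' @param ... Passed to [run_langevin()] (`seed`, `temperature`, ...).
#' @return An object of class `metad_run`: `$hills` (tibble of deposit
#'   time, centers, height), `$run` (the underlying `md_run`, with
#'   per-sample CV values), and the protocol config.
#' @export
run_wt_metad <- function(complex, params, duration_ps,
                         hill_height = 8, hill_sigma = 0.2, hill_every_ps = 1,
                         bias_factor = 10, wall_ceiling = 5, wall_kappa = 150,
                         grid_min = 0.8, grid_max = 6.5, grid_n = 286, ...) {
  stopifnot(inherits(complex, "reduced_complex"))
  if (bias_factor <= 1) stop("well-tempered bias factor must exceed 1", call. = FALSE)
  roles <- complex$role
  if (!all(c("c_co", "o2") %in% roles))
    stop("metadynamics protocol needs both CO and O2 ligands", call. = FALSE)
  dots <- list(...)
  dt_fs <- dots$dt_fs %||% 2
  stride_steps <- max(1L, as.integer(round(hill_every_ps * 1000 / dt_fs)))
  metad <- list(cv = rbind(c(site_index(complex, "fe"), site_index(complex, "cco")),
                           c(site_index(complex, "fe"), site_index(complex, "o2"))),
                height = hill_height, sigma = hill_sigma,
                bias_factor = bias_factor, stride_steps = stride_steps,
                grid_min = grid_min, grid_max = grid_max, grid_n = as.integer(grid_n))
  biases <- list(
    list(spec = bias_spec("upper-wall", kappa = wall_kappa, ceiling = wall_ceiling),
         cv = c("fe", "cco")),
    list(spec = bias_spec("upper-wall", kappa = wall_kappa, ceiling = wall_ceiling),
         cv = c("fe", "o2")))
  run <- run_langevin(complex, params, biases = biases,
                      duration_ps = duration_ps, metad = metad, ...)
  hills <- run$hills
  names(hills) <- c("t_ps", "d_fe_c", "d_fe_o2", "height")
  structure(list(hills = hills, run = run,
                 config = list(hill_height = hill_height, hill_sigma = hill_sigma,
                               hill_every_ps = hill_every_ps,
                               bias_factor = bias_factor,
                               wall_ceiling = wall_ceiling, wall_kappa = wall_kappa,
                               temperature = dots$temperature %||% 300,
                               duration_ps = duration_ps)),
            class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf("<metad_run> %d hills over %g ps (h0 = %g kcal/mol, sigma = %g A, gamma = %g)\n",
              nrow(x$hills), x$config$duration_ps, x$config$hill_height,
              x$config$hill_sigma, x$config$bias_factor))
  invisible(x)
}

#' Reconstruct the free-energy surface from a hills log
#'
#' Sums the deposited Gaussians on a regular CV grid and applies the
#' well-tempered rescaling \eqn{F(s) = -\gamma/(\gamma - 1)\, V(s)},
#' shifting the minimum to zero. This reconstruction is independent of the
#' engine's internal bias grid.
#'
#' @param x A `metad_run`, or a hills tibble with columns `d_fe_c`,
#'   `d_fe_o2` (may be all-`NA` for a 1-CV log), `height` and attribute-
#'   free deposit data.
#' @param bias_factor Well-tempered gamma (taken from a `metad_run`
#'   automatically; > 1).
#' @param hill_sigma Hill width, Angstrom.
#' @param grid Numeric vector of grid points per CV.
#' @return For 2 CVs: a tibble of class `fes` with columns `d_fe_c`,
#'   `d_fe_o2`, `free_energy` (kcal/mol, min 0). For 1 CV: columns `cv`,
#'   `free_energy`.
#' @export
reconstruct_fes <- function(x, bias_factor = NULL, hill_sigma = NULL,
                            grid = seq(1.2, 5.2, by = 0.05)) {
  if (inherits(x, "metad_run")) {
    hills <- x$hills
    bias_factor <- bias_factor %||% x$config$bias_factor
    hill_sigma <- hill_sigma %||% x$config$hill_sigma
  } else {
    hills <- x
  }
  if (is.null(bias_factor) || bias_factor <= 1)
    stop("`bias_factor` must be > 1", call. = FALSE)
  if (is.null(hill_sigma) || hill_sigma <= 0)
    stop("`hill_sigma` must be positive", call. = FALSE)
  if (nrow(hills) == 0L) stop("empty hills log", call. = FALSE)
  scale <- bias_factor / (bias_factor - 1)
  two_d <- !all(is.na(hills$d_fe_o2))
  if (two_d) {
    gg <- tidyr::expand_grid(d_fe_c = grid, d_fe_o2 = grid)
    v <- numeric(nrow(gg))
    for (k in seq_len(nrow(hills))) {
      v <- v + hills$height[k] *
        exp(-0.5 * ((gg$d_fe_c - hills$d_fe_c[k])^2 +
                    (gg$d_fe_o2 - hills$d_fe_o2[k])^2) / hill_sigma^2)
    }
    fes <- gg
    fes$free_energy <- -scale * v
    fes$free_energy <- fes$free_energy - min(fes$free_energy)
  } else {
    v <- vapply(grid, function(s) {
      sum(hills$height * exp(-0.5 * (s - hills$d_fe_c)^2 / hill_sigma^2))
    }, numeric(1))
    fes <- tibble::tibble(cv = grid, free_energy = -scale * v)
    fes$free_energy <- fes$free_energy - min(fes$free_energy)
  }
  structure(fes, class = c("fes", class(tibble::tibble())),
            bias_factor = bias_factor, hill_sigma = hill_sigma, two_d = two_d)
}

#' Effective CO bond energy along a constant Fe-O2 slice
#'
#' On the slice of the free-energy surface at a fixed Fe-O2 distance,
#' the effective bond energy is the maximum free energy encountered from
#' the slice's bond-length minimum outward (toward large Fe-C), relative
#' to that minimum - the barrier that must be crossed to break the Fe-CO
#' bond in that O2 environment. Invariant under constant shifts of the
#' surface. A slice whose minimum sits on the grid edge (no interior
#' minimum) is flagged.
#'
#' @param fes A 2-CV [reconstruct_fes()] result.
#' @param d_fe_o2 Fixed Fe-O2 distance(s), Angstrom (nearest grid row is
#'   used).
#' @return A tibble: `d_fe_o2` (grid value used), `effective_bond_energy`
#'   (kcal/mol), `r_min` (slice minimum location), `flagged`.
#' @export
slice_effective_bond_energy <- function(fes, d_fe_o2) {
  stopifnot(inherits(fes, "fes"), isTRUE(attr(fes, "two_d")))
  grid_o2 <- sort(unique(fes$d_fe_o2))
  purrr::map_dfr(d_fe_o2, function(target) {
    g <- grid_o2[which.min(abs(grid_o2 - target))]
    sl <- dplyr::arrange(dplyr::filter(fes, .data$d_fe_o2 == g), .data$d_fe_c)
    i_min <- which.min(sl$free_energy)
    flagged <- i_min == 1L || i_min == nrow(sl)
    outer <- sl$free_energy[i_min:nrow(sl)]
    tibble::tibble(d_fe_o2 = g,
                   effective_bond_energy = max(outer) - sl$free_energy[i_min],
                   r_min = sl$d_fe_c[i_min], flagged = flagged)
  })
}

#' O2 approach pattern relative to iron and the heme nitrogens
#'
#' For every recorded frame, the distance from the proximal oxygen to the
#' iron and the shortest distance from it to any heme nitrogen. The
#' direct-approach fraction summarizes how often, among frames with the
#' proximal oxygen within `within` of the iron, the iron is the nearer
#' partner (approach down the axial funnel rather than across the
#' porphyrin surface).
#'
#' @param run An `md_run` (or `metad_run`) with recorded positions and an
#'   O2 ligand.
#' @param within Closeness threshold for the fraction, Angstrom (default
#'   3.5).
#' @return A tibble `t_ps`, `d_fe` (Fe-O2 distance), `d_nheme` (min
#'   O2-N distance); attribute `direct_fraction`.
#' @export
approach_pattern <- function(run, within = 3.5) {
  if (inherits(run, "metad_run")) run <- run$run
  stopifnot(inherits(run, "md_run"))
  cx <- run$complex
  if (!"o2" %in% cx$role) stop("run has no O2 ligand", call. = FALSE)
  if (is.null(run$positions)) stop("run has no recorded positions", call. = FALSE)
  io2 <- match("o2", cx$role)
  ife <- match("fe", cx$role)
  in_ <- which(cx$role == "n_heme")
  frames <- run$positions
  col3 <- function(i) frames[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  po2 <- col3(io2)
  d_fe <- sqrt(rowSums((po2 - col3(ife))^2))
  d_n <- do.call(pmin, lapply(in_, function(i) sqrt(rowSums((po2 - col3(i))^2))))
  res <- tibble::tibble(t_ps = run$samples$t_ps[seq_along(d_fe)],
                        d_fe = d_fe, d_nheme = d_n)
  close <- res$d_fe < within
  frac <- if (any(close)) mean(res$d_fe[close] < res$d_nheme[close]) else NA_real_
  structure(res, direct_fraction = frac, within = within,
            class = c("approach_pattern", class(tibble::tibble())))
}

#' @method autoplot fes
#' @export
autoplot.fes <- function(object, ...) {
  if (isTRUE(attr(object, "two_d"))) {
    ggplot2::ggplot(tibble::as_tibble(object),
                    ggplot2::aes(x = .data$d_fe_c, y = .data$d_fe_o2,
                                 fill = .data$free_energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
      ggplot2::labs(x = "Fe–C distance (Å)", y = "Fe–O₂ distance (Å)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tibble::as_tibble(object),
                    ggplot2::aes(x = .data$cv, y = .data$free_energy)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "CV (Å)", y = "free energy (kcal/mol)") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot approach_pattern
#' @export
autoplot.approach_pattern <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$d_nheme, y = .data$d_fe)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "min O₂–N(heme) distance (Å)", y = "O₂–Fe distance (Å)") +
    ggplot2::theme_minimal()
}

#' One-dimensional Langevin particle on an analytic landscape
#'
#' Validation harness for the thermostat and the well-tempered bias
#' machinery: a single particle on a flat, harmonic or quartic double-well
#' landscape, optionally with harmonic walls and 1-CV well-tempered
#' metadynamics. Used to check equipartition and free-energy
#' reconstruction against closed forms.
#'
#' @param potential `"flat"`, `"harmonic"` (0.5 k (x-x0)^2) or
#'   `"double-well"` (h ((x/a)^2 - 1)^2: minima at +/- a, barrier h).
#' @param par Named parameters: `k`, `x0` (harmonic); `h`, `a`
#'   (double-well).
#' @param duration_ps,dt_fs,temperature,friction Integrator settings.
#' @param x0,v0,mass Initial state and particle mass (amu).
#' @param walls `c(lo, hi)` harmonic wall positions (with `wall_kappa`),
#'   or `NULL`.
#' @param wall_kappa Wall stiffness, kcal/mol/A^2.
#' @param metad Optional list(`height`, `sigma`, `every_ps`,
#'   `bias_factor`, `grid_min`, `grid_max`, `grid_n`).
#' @param seed Optional seed.
#' @param sample_every_ps Sampling stride.
#' @return A list with `samples` (tibble `t_ps`, `x`, `temperature`) and,
#'   when biased, a `hills` tibble (`t_ps`, `d_fe_c` = center, `height`).
#' @export
simulate_cv_model <- function(potential = c("flat", "harmonic", "double-well"),
                              par = list(), duration_ps, dt_fs = 2,
                              temperature = 300, friction = 5,
                              x0 = 0, v0 = 0, mass = 16,
                              walls = NULL, wall_kappa = 150,
                              metad = NULL, seed = NULL,
                              sample_every_ps = 0.1) {
  potential <- match.arg(potential)
  if (!is.null(seed)) set.seed(seed)
  kind <- match(potential, c("flat", "harmonic", "double-well")) - 1L
  pp <- switch(potential,
               "flat" = c(0, 0),
               "harmonic" = c(par$k, par$x0 %||% 0),
               "double-well" = c(par$h, par$a %||% 1))
  ms <- NULL
  if (!is.null(metad)) {
    ms <- list(height = metad$height, sigma = metad$sigma,
               bias_factor = metad$bias_factor,
               stride_steps = max(1L, as.integer(round((metad$every_ps %||% 1) * 1000 / dt_fs))),
               grid_min = metad$grid_min, grid_max = metad$grid_max,
               grid_n = as.integer(metad$grid_n %||% 401))
  }
  stride <- max(1L, as.integer(round(sample_every_ps * 1000 / dt_fs)))
  nsteps <- max(stride, as.integer(round(duration_ps * 1000 / dt_fs)))
  res <- run_cv1d_cpp(x0, v0, mass, kind, pp, nsteps, dt_fs, temperature,
                      friction, stride,
                      if (is.null(walls)) -Inf else walls[1],
                      if (is.null(walls)) Inf else walls[2],
                      if (is.null(walls)) 0 else wall_kappa, ms)
  out <- list(samples = tibble::tibble(t_ps = res$t_ps, x = res$x,
                                       temperature = res$temperature),
              x_final = res$x_final)
  if (!is.null(res$hills) && length(res$hills) > 0) {
    h <- tibble::as_tibble(res$hills)
    out$hills <- tibble::tibble(t_ps = h$t_ps, d_fe_c = h$center1,
                                d_fe_o2 = NA_real_, height = h$height)
  }
  out
}
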