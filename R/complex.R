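#' Geometry configuration for the reduced complex
#'
#' Defaults describe a coarse heme-imidazole scaffold: four pyrrole
#' nitrogens in the porphyrin plane, an axial imidazole nitrogen below it,
#' and gas ligands above. These internal coordinates are plausible
#' placeholders for the optimized quantum-chemistry geometry (which is not
#' reproduced here); every value is configurable.
#'
#' @param n_ring_radius Fe-N(pyrrole) in-plane distance, Angstrom.
#' @param c_alpha_radius Fe-C(alpha) in-plane distance, Angstrom (8 sites,
#'   idealized porphine).
#' @param c_meso_radius Fe-C(meso) in-plane distance, Angstrom (4 sites,
#'   on the diagonals between the nitrogens).
#' @param imidazole_offset Fe-N(imidazole) axial distance, Angstrom.
#' @param co_bond C-O bond length of CO, Angstrom (rigid).
#' @param o2_bond O-O bond length of O2, Angstrom (rigid).
#' @param fe_c_start Initial Fe-C(CO) distance, Angstrom.
#' @param fe_o2_start Initial Fe-O2(proximal) distance, Angstrom.
#' @param o2_tilt Initial Fe-O2-O1 angle, degrees (end-on binding pose).
#' @param o2_side_offset When CO and O2 coexist, O2 starts displaced this
#'   far from the axis (same side of the plane as CO), Angstrom.
#' @return A list of class `complex_geometry`.
#' @export
complex_geometry <- function(n_ring_radius = 2.0, c_alpha_radius = 3.05,
                             c_meso_radius = 3.42, imidazole_offset = 2.1,
                             co_bond = 1.128, o2_bond = 1.21,
                             fe_c_start = 1.85, fe_o2_start = 2.13,
                             o2_tilt = 120, o2_side_offset = 2.7) {
  out <- as.list(environment())
  stopifnot(all(vapply(out, function(v) is.numeric(v) && v > 0, logical(1))))
  structure(out, class = "complex_geometry")
}

ELEMENT_MASS <- c(Fe = 55.845, N = 14.007, C = 12.011, O = 15.999, H = 1.008)

# place the distal O1 so that the angle fe--o2--o1 equals theta (degrees),
# bending in the plane spanned by the o2->fe axis and an outward reference
place_distal_o <- function(fe, o2, bond, theta) {
  u <- fe - o2
  u <- u / sqrt(sum(u^2))
  ref <- c(o2[1], o2[2], 0)
  if (sqrt(sum(ref^2)) < 1e-8) ref <- c(1, 0, 0)
  p <- ref - sum(ref * u) * u
  if (sqrt(sum(p^2)) < 1e-8) p <- c(1, 0, 0) - u[1] * u
  p <- p / sqrt(sum(p^2))
  th <- theta * pi / 180
  o2 + bond * (cos(th) * u + sin(th) * p)
}

#' Build the reduced heme-imidazole-ligand complex
#'
#' Constructs the coarse stand-in for the six-coordinate heme complex: Fe
#' at the origin, four in-plane heme nitrogens, an imidazole nitrogen
#' anchor below the plane, and the requested gas ligand(s) above it. When
#' CO and O2 are both present they sit on the same side of the heme plane.
#' The proximal (bond-forming) oxygen is tagged `o2`, the distal one `o1`,
#' and that identity is preserved through every downstream operation.
#' Construction is fully deterministic given the geometry config.
#'
#' @param ligand `"CO"`, `"O2"` or `"CO+O2"`.
#' @param geometry A [complex_geometry()].
#' @return A tibble of class `reduced_complex` with columns `site`, `role`,
#'   `element`, `x`, `y`, `z`, `mobile`, plus attributes for the rigid-bond
#'   constraints and the plane normal. Only ligand sites are mobile.
#' @examples
#' cx <- build_complex("O2")
#' measure_angle(cx)  # equals the configured tilt at construction
#' @export
build_complex <- function(ligand = c("CO", "O2", "CO+O2"),
                          geometry = complex_geometry()) {
  ligand <- match.arg(ligand)
  g <- geometry
  rows <- list(
    list("fe", "fe", "Fe", 0, 0, 0, FALSE),
    list("n1", "n_heme", "N", g$n_ring_radius, 0, 0, FALSE),
    list("n2", "n_heme", "N", 0, g$n_ring_radius, 0, FALSE),
    list("n3", "n_heme", "N", -g$n_ring_radius, 0, 0, FALSE),
    list("n4", "n_heme", "N", 0, -g$n_ring_radius, 0, FALSE),
    list("nim", "n_im", "N", 0, 0, -g$imidazole_offset, FALSE))
  # porphine ring carbons: 8 alpha (+/- 22.5 deg off each N) and 4 meso
  # (on the diagonals); they give the ring a smooth steric surface
  kring <- 0L
  for (a_deg in seq(0, 270, by = 90)) {
    for (off in c(-22.5, 22.5)) {
      kring <- kring + 1L
      th <- (a_deg + off) * pi / 180
      rows[[length(rows) + 1]] <- list(paste0("ca", kring), "c_ring", "C",
                                       g$c_alpha_radius * cos(th),
                                       g$c_alpha_radius * sin(th), 0, FALSE)
    }
  }
  for (k in 1:4) {
    th <- (45 + 90 * (k - 1)) * pi / 180
    rows[[length(rows) + 1]] <- list(paste0("cm", k), "c_ring", "C",
                                     g$c_meso_radius * cos(th),
                                     g$c_meso_radius * sin(th), 0, FALSE)
  }
  constraints <- list()
  add <- function(site, role, element, p, mobile = TRUE) {
    rows[[length(rows) + 1]] <<- list(site, role, element, p[1], p[2], p[3], mobile)
  }
  if (ligand %in% c("CO", "CO+O2")) {
    c_pos <- c(0, 0, g$fe_c_start)
    add("cco", "c_co", "C", c_pos)
    add("oco", "o_co", "O", c_pos + c(0, 0, g$co_bond))
    constraints[[length(constraints) + 1]] <- c("cco", "oco", g$co_bond)
  }
  if (ligand %in% c("O2", "CO+O2")) {
    if (ligand == "O2") {
      o2_pos <- c(0, 0, g$fe_o2_start)
    } else {
      # same side of the plane as CO, displaced off-axis
      o2_pos <- c(g$o2_side_offset, 0, 2.0)
    }
    o1_pos <- place_distal_o(c(0, 0, 0), o2_pos, g$o2_bond, g$o2_tilt)
    add("o2", "o2", "O", o2_pos)
    add("o1", "o1", "O", o1_pos)
    constraints[[length(constraints) + 1]] <- c("o2", "o1", g$o2_bond)
  }
  df <- tibble::tibble(
    site = vapply(rows, `[[`, character(1), 1),
    role = vapply(rows, `[[`, character(1), 2),
    element = vapply(rows, `[[`, character(1), 3),
    x = vapply(rows, function(r) as.numeric(r[[4]]), numeric(1)),
    y = vapply(rows, function(r) as.numeric(r[[5]]), numeric(1)),
    z = vapply(rows, function(r) as.numeric(r[[6]]), numeric(1)),
    mobile = vapply(rows, `[[`, logical(1), 7))
  cmat <- if (length(constraints)) {
    t(vapply(constraints, function(cc) {
      c(match(cc[1], df$site), match(cc[2], df$site), as.numeric(cc[3]))
    }, numeric(3)))
  } else matrix(numeric(0), ncol = 3)
  structure(df,
            class = c("reduced_complex", class(tibble::tibble())),
            ligand = ligand, geometry = g, constraints = cmat,
            plane_normal = c(0, 0, 1))
}

complex_positions <- function(complex) {
  as.matrix(complex[, c("x", "y", "z")])
}

site_index <- function(complex, site) {
  i <- match(site, complex$site)
  if (any(is.na(i))) stop("unknown site(s): ", paste(site[is.na(i)], collapse = ", "),
                          call. = FALSE)
  i
}

with_positions <- function(complex, pos) {
  complex$x <- pos[, 1]; complex$y <- pos[, 2]; complex$z <- pos[, 3]
  complex
}

#' @export
print.reduced_complex <- function(x, ...) {
  cat(sprintf("<reduced_complex: %s> %d sites (%d mobile)\n",
              attr(x, "ligand"), nrow(x), sum(x$mobile)))
  NextMethod()
}

#' Fe-O2-O1 angle of a configuration
#'
#' Angle at the proximal oxygen between the vectors to Fe and to the
#' distal oxygen, in degrees. For an [md_run][run_langevin()] the angle is
#' evaluated on every recorded frame.
#'
#' @param x A `reduced_complex` with an O2 ligand, or an `md_run`.
#' @param ... Unused.
#' @return Degrees in \[0, 180\]; a vector over frames for a run.
#' @export
measure_angle <- function(x, ...) UseMethod("measure_angle")

angle_deg <- function(fe, o2, o1) {
  v1 <- fe - o2; v2 <- o1 - o2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("coincident sites: angle undefined", call. = FALSE)
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' @export
measure_angle.reduced_complex <- function(x, ...) {
  if (!all(c("o1", "o2") %in% x$role)) stop("complex has no O2 ligand", call. = FALSE)
  pos <- complex_positions(x)
  angle_deg(pos[match("fe", x$role), ], pos[match("o2", x$role), ],
            pos[match("o1", x$role), ])
}

#' @export
measure_angle.md_run <- function(x, ...) {
  cx <- x$complex
  if (!all(c("o1", "o2") %in% cx$role)) stop("run has no O2 ligand", call. = FALSE)
  idx <- c(match("fe", cx$role), match("o2", cx$role), match("o1", cx$role))
  frames <- x$positions
  if (is.null(frames) || nrow(frames) == 0L)
    stop("run has no recorded positions", call. = FALSE)
  col3 <- function(i) frames[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  v1 <- col3(idx[1]) - col3(idx[2])   # o2 -> fe
  v2 <- col3(idx[3]) - col3(idx[2])   # o2 -> o1
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  if (any(n1 < 1e-9 | n2 < 1e-9)) stop("coincident sites: angle undefined", call. = FALSE)
  acos(pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Coordination parameter set for the heme-gas-ligand pairs
#'
#' Bundles the pair-specific LJ parameters for the three coordination
#' pairs of the two-site model: Fe-C(CO), Fe-O1 (distal) and Fe-O2
#' (proximal). Defaults are the fine-tuned two-site values shipped with
#' the package (well depths in kcal/mol, signed negative; lengths in
#' Angstrom, sigma form).
#'
#' @param fe_cco,fe_o1,fe_o2 [lj_pair()]s, or `NULL` to disable a pair.
#' @return A named list of class `param_set`.
#' @export
coordination_params <- function(fe_cco = lj_pair(-21.49, 1.79),
                                fe_o1 = lj_pair(-4.37, 2.74),
                                fe_o2 = lj_pair(-6.55, 1.90)) {
  ps <- list(fe_cco = fe_cco, fe_o1 = fe_o1, fe_o2 = fe_o2)
  ps <- ps[!vapply(ps, is.null, logical(1))]
  stopifnot(all(vapply(ps, inherits, logical(1), "lj_pair")))
  structure(ps, class = "param_set")
}

#' Generic van der Waals parameters of the reduced model
#'
#' Per-element (epsilon, Rmin/2) pairs combined with Lorentz-Berthelot
#' rules for every non-coordination site pair that spans two molecules.
#' These short-range terms transmit the steric competition between CO and
#' O2 at the iron site. Values are typical protein force-field magnitudes.
#'
#' @param enabled Set `FALSE` to zero all generic terms (coordination
#'   pairs only; useful for analytic oracles).
#' @return A tibble with columns `element`, `eps`, `rmin2`.
#' @export
generic_vdw_params <- function(enabled = TRUE) {
  tb <- tibble::tibble(
    element = c("Fe", "N", "C", "O"),
    eps = c(0.01, 0.20, 0.11, 0.12),
    rmin2 = c(1.3, 1.85, 2.0, 1.7))
  if (!enabled) tb$eps <- 0
  tb
}

# Build the engine pair table: coordination NBFIX pairs plus generic vdW
# for inter-molecular pairs. Scaffold-internal (fixed-fixed) pairs are
# skipped: the scaffold is rigid and its internal energy is a constant.
pair_table <- function(complex, params, vdw = generic_vdw_params()) {
  stopifnot(inherits(complex, "reduced_complex"), inherits(params, "param_set"))
  n <- nrow(complex)
  role <- complex$role
  mol <- dplyr::case_when(role %in% c("c_co", "o_co") ~ "co",
                          role %in% c("o1", "o2") ~ "o2",
                          TRUE ~ "scaffold")
  coord <- list(c("fe", "c_co", "fe_cco"), c("fe", "o2", "fe_o2"),
                c("fe", "o1", "fe_o1"))
  rows <- list()
  covered <- character(0)
  for (cp in coord) {
    i <- match(cp[1], role); j <- match(cp[2], role)
    if (is.na(i) || is.na(j) || is.null(params[[cp[3]]])) next
    p <- params[[cp[3]]]
    rows[[length(rows) + 1]] <- c(i, j, abs(p$epsilon), lj_sigma_internal(p))
    covered <- c(covered, cp[2])
  }
  ncoord <- length(rows)
  vmap_e <- setNames(vdw$eps, vdw$element)
  vmap_r <- setNames(vdw$rmin2, vdw$element)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (mol[i] == mol[j]) next                      # intramolecular: rigid/bonded
    if (role[i] == "fe" && role[j] %in% covered) next  # NBFIX overrides
    eps <- sqrt(vmap_e[[complex$element[i]]] * vmap_e[[complex$element[j]]])
    if (eps <= 0) next
    rmin <- vmap_r[[complex$element[i]]] + vmap_r[[complex$element[j]]]
    rows[[length(rows) + 1]] <- c(i, j, eps, rmin / 2^(1/6))
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), ncol = 4)
  attr(m, "n_coordination") <- ncoord
  m
}
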