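#' Synthesize a ground-truth potential-energy curve
#'
#' Generates a tabulated U(r) curve from known LJ parameters, standing in
#' for quantum-chemistry reference data (which is not deposited with the
#' source study). For a single pair the curve is the closed-form energy;
#' for a two-site O2 ligand the distal-site contribution is added at the
#' distance implied by the rigid O-O bond and tilt angle. An optional
#' smooth background and seeded Gaussian noise emulate the non-coordination
#' residue and numerical scatter of real reference curves.
#'
#' @param params An [lj_pair()] (single site) or a [coordination_params()]
#'   set containing `fe_o2`/`fe_o1` (two-site O2 curve along the Fe-O2
#'   distance).
#' @param r Distance grid, Angstrom (default the 1.75-2.95 window at
#'   0.1 Angstrom, the spacing reference curves are tabulated at).
#' @param noise_sd Gaussian noise on U, kcal/mol (>= 0).
#' @param background Optional function of `r` added to U.
#' @param seed Optional seed; fixed seed gives identical curves.
#' @param o2_tilt,o2_bond Geometry for the two-site case (degrees,
#'   Angstrom).
#' @return A [potential_curve()] labelled `"ground-truth"`.
#' @export
synthesize_ground_truth_curve <- function(params, r = seq(1.75, 2.95, by = 0.1),
                                          noise_sd = 0, background = NULL,
                                          seed = NULL, o2_tilt = 120,
                                          o2_bond = 1.21) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (inherits(params, "lj_pair")) {
    u <- lj_energy(params, r)
  } else if (inherits(params, "param_set")) {
    if (is.null(params$fe_o2)) stop("param set has no `fe_o2` pair", call. = FALSE)
    u <- lj_energy(params$fe_o2, r)
    if (!is.null(params$fe_o1)) {
      d1 <- sqrt(r^2 + o2_bond^2 - 2 * r * o2_bond * cos(o2_tilt * pi / 180))
      u <- u + lj_energy(params$fe_o1, d1)
    }
  } else stop("`params` must be an lj_pair or a param_set", call. = FALSE)
  if (!is.null(background)) u <- u + background(r)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    u <- u + rnorm(length(r), sd = noise_sd)
  }
  potential_curve(r, U = u, label = "ground-truth")
}
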