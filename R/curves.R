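#' Potential / force curve container
#'
#' A tibble with a distance grid `r` (Angstrom, strictly increasing) and
#' optional columns `U` (kcal/mol) and `F` (kcal/mol/Angstrom), tagged with
#' a provenance `label` (`"ground-truth"`, `"baseline"`, `"coordination"`,
#' `"model"`, ...).
#'
#' @param r Distance grid, Angstrom, strictly increasing.
#' @param U Optional energies, kcal/mol (same length as `r`).
#' @param F Optional forces, kcal/mol/Angstrom (same length as `r`).
#' @param label Provenance tag.
#' @return A tibble of class `potential_curve`.
#' @export
potential_curve <- function(r, U = NULL, F = NULL, label = "ground-truth") {
  if (length(r) < 1L || any(!is.finite(r)) || any(diff(r) <= 0))
    stop("`r` must be a finite, strictly increasing grid", call. = FALSE)
  if (!is.null(U) && length(U) != length(r))
    stop("`U` must match the length of `r`", call. = FALSE)
  if (!is.null(F) && length(F) != length(r))
    stop("`F` must match the length of `r`", call. = FALSE)
  out <- tibble::tibble(r = as.numeric(r))
  if (!is.null(U)) out$U <- as.numeric(U)
  if (!is.null(F)) out$F <- as.numeric(F)
  new_potential_curve(out, label = label)
}

new_potential_curve <- function(df, label = "ground-truth", f_method = NA_character_) {
  structure(df,
            class = c("potential_curve", class(tibble::tibble())),
            curve_label = label, f_method = f_method)
}

curve_label <- function(curve) attr(curve, "curve_label") %||% "curve"
curve_f_method <- function(curve) attr(curve, "f_method") %||% NA_character_
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Finite-difference force from an energy curve
#'
#' Converts a tabulated energy curve to a force curve with the adjacent-
#' difference rule \eqn{F_i = -(U_{i+1} - U_i)/\Delta r}, assigned to the
#' left grid point. The rule is first-order: a single grid interval whose
#' energy jump exceeds its neighbours' produces a local spike in `F` at
#' that point (a known artifact of the scheme, not of the data). The last
#' grid point has no right neighbour, so its force is `NA`: the output has
#' one fewer usable point than the energy column.
#'
#' @param curve A [potential_curve()] with a `U` column on a uniform grid
#'   of at least 2 points.
#' @param tol Relative tolerance on grid uniformity.
#' @return The curve with an `F` column (finite-difference convention
#'   recorded, so downstream fits can difference their model identically).
#' @export
finite_difference_force <- function(curve, tol = 1e-6) {
  stopifnot(inherits(curve, "potential_curve"))
  if (!"U" %in% names(curve)) stop("curve has no `U` column", call. = FALSE)
  if (nrow(curve) < 2L) stop("need at least 2 grid points", call. = FALSE)
  dr <- diff(curve$r)
  if (max(abs(dr - dr[1])) > tol * abs(dr[1]))
    stop("finite differencing requires a uniform `r` grid", call. = FALSE)
  f <- c(-diff(curve$U) / dr[1], NA_real_)
  out <- tibble::tibble(r = curve$r, U = curve$U, F = f)
  new_potential_curve(out, label = curve_label(curve), f_method = "fd")
}

#' Extract the coordination-only force curve
#'
#' Subtracts a zeroed-baseline force curve from a ground-truth force
#' curve: what remains is the contribution of the coordination interaction
#' alone, the quantity the pair-specific LJ term is fitted to.
#'
#' @param ground_truth,baseline [potential_curve()]s with `F` columns.
#' @param interpolate If `TRUE`, the baseline is linearly interpolated
#'   onto the ground-truth grid; if `FALSE` (default) the grids must match.
#' @return A `potential_curve` labelled `"coordination"` with
#'   `F = F_truth - F_baseline`.
#' @export
extract_coordination_force <- function(ground_truth, baseline, interpolate = FALSE) {
  stopifnot(inherits(ground_truth, "potential_curve"), inherits(baseline, "potential_curve"))
  if (!"F" %in% names(ground_truth) || !"F" %in% names(baseline))
    stop("both curves need an `F` column", call. = FALSE)
  if (interpolate) {
    fb <- approx(baseline$r, baseline$F, xout = ground_truth$r, rule = 1)$y
    if (any(!is.finite(fb) & is.finite(ground_truth$F)))
      stop("baseline grid does not cover the ground-truth grid", call. = FALSE)
  } else {
    if (nrow(ground_truth) != nrow(baseline) ||
        max(abs(ground_truth$r - baseline$r)) > 1e-9)
      stop("curves are on different grids; set `interpolate = TRUE` to resample",
           call. = FALSE)
    fb <- baseline$F
  }
  out <- tibble::tibble(r = ground_truth$r, F = ground_truth$F - fb)
  if ("U" %in% names(ground_truth))
    out <- tibble::add_column(out, U = ground_truth$U, .after = "r")
  new_potential_curve(out, label = "coordination", f_method = curve_f_method(ground_truth))
}

#' @export
print.potential_curve <- function(x, ...) {
  cat(sprintf("<potential_curve: %s> %d points, r in [%.3g, %.3g] A\n",
              curve_label(x), nrow(x), min(x$r), max(x$r)))
  NextMethod()
}

#' @rdname autoplot.potential_curve
#' @method autoplot potential_curve
#' @export
autoplot.potential_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::any_of(c("U", "F")),
                              names_to = "quantity", values_to = "value")
  labs <- c(U = "U (kcal/mol)", F = "F (kcal/mol/Å)")
  long$quantity <- labs[long$quantity]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "r (Å)", y = NULL, title = curve_label(object)) +
    ggplot2::theme_minimal()
}

#' Plot methods
#'
#' `autoplot()` methods render each result type as a ggplot.
#'
#' @param object The object to plot.
#' @param ... Ignored.
#' @name autoplot.potential_curve
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
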