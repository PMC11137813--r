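#' Pair-specific Lennard-Jones parameters
#'
#' Container for one NBFIX-style atom-pair override. The well depth
#' `epsilon` is stored with the sign convention used in coordination
#' parameter tables (negative for an attractive pair); all energy and force
#' formulas use its magnitude. `epsilon = 0` encodes a zeroed (disabled)
#' pair. Two functional conventions are supported, because parameter tables
#' in the literature print "sigma" for either meaning:
#'
#' * `"sigma"`: \eqn{U(r) = 4|\epsilon| [ (\sigma/r)^{12} - (\sigma/r)^6 ]},
#'   zero-crossing at \eqn{\sigma}, minimum \eqn{-|\epsilon|} at
#'   \eqn{2^{1/6}\sigma}.
#' * `"rmin"`: \eqn{U(r) = |\epsilon| [ (R_{min}/r)^{12} - 2 (R_{min}/r)^6 ]},
#'   the native CHARMM form, minimum at \eqn{R_{min}}.
#'
#' @param epsilon Well depth, kcal/mol. Sign is preserved; magnitude used.
#' @param sigma Length parameter, Angstrom (> 0). Interpreted per
#'   `convention`.
#' @param convention `"sigma"` (default) or `"rmin"`.
#' @return An object of class `lj_pair`.
#' @examples
#' p <- lj_pair(-21.49, 1.79)
#' lj_energy(p, 2^(1/6) * 1.79)  # the well depth
#' @export
lj_pair <- function(epsilon, sigma, convention = c("sigma", "rmin")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive length in Angstrom", call. = FALSE)
  structure(list(epsilon = epsilon, sigma = sigma, convention = convention),
            class = "lj_pair")
}

#' @export
print.lj_pair <- function(x, ...) {
  cat(sprintf("<lj_pair> epsilon = %.4g kcal/mol, sigma = %.4g A (%s form)\n",
              x$epsilon, x$sigma, x$convention))
  invisible(x)
}

# sigma-form sigma regardless of stored convention
lj_sigma_internal <- function(params) {
  if (params$convention == "rmin") params$sigma / 2^(1/6) else params$sigma
}

check_r_positive <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("distances `r` must be positive and finite", call. = FALSE)
}

#' Lennard-Jones pair energy
#'
#' @param params An [lj_pair()].
#' @param r Distance(s), Angstrom (> 0).
#' @return Energy in kcal/mol, vectorized over `r`.
#' @export
lj_energy <- function(params, r) {
  stopifnot(inherits(params, "lj_pair"))
  check_r_positive(r)
  e <- abs(params$epsilon)
  s <- lj_sigma_internal(params)
  x6 <- (s / r)^6
  4 * e * (x6^2 - x6)
}

#' Lennard-Jones pair force
#'
#' The radial force \eqn{F = -dU/dr}; positive values are repulsive.
#' Vanishes at the potential minimum and reaches its maximal attractive
#' magnitude at \eqn{r = (26/7)^{1/6}\sigma}.
#'
#' @inheritParams lj_energy
#' @return Force in kcal/mol/Angstrom, vectorized over `r`.
#' @export
lj_force <- function(params, r) {
  stopifnot(inherits(params, "lj_pair"))
  check_r_positive(r)
  e <- abs(params$epsilon)
  s <- lj_sigma_internal(params)
  x6 <- (s / r)^6
  (24 * e / r) * (2 * x6^2 - x6)
}

#' Maximal attractive force of an LJ pair
#'
#' Magnitude of the strongest restoring force the pair can exert, i.e. the
#' quasi-static rupture force of the bond. Located at
#' \eqn{r = (26/7)^{1/6}\sigma}.
#'
#' @inheritParams lj_energy
#' @return A list with `r_max` (Angstrom) and `f_max` (kcal/mol/Angstrom,
#'   positive magnitude).
#' @export
lj_max_attraction <- function(params) {
  s <- lj_sigma_internal(params)
  r_star <- (26 / 7)^(1 / 6) * s
  list(r_max = r_star, f_max = abs(lj_force(params, r_star)))
}

#' Nonbonded switching factor
#'
#' CHARMM-style cubic-in-\eqn{r^2} switching function: 1 at and below
#' `r_on`, 0 at and beyond `r_off`, continuously differentiable in between.
#' Nonbonded terms are multiplied by this factor so energy and force go
#' smoothly to zero at the cutoff.
#'
#' @param r Distance(s), Angstrom.
#' @param r_on Switch-on distance, Angstrom (default 8).
#' @param r_off Cutoff distance, Angstrom (default 10).
#' @return Unitless factor in \[0, 1\], vectorized over `r`.
#' @export
switching_factor <- function(r, r_on = 8, r_off = 10) {
  if (!(r_on > 0 && r_off > r_on))
    stop("switching requires 0 < r_on < r_off", call. = FALSE)
  r2 <- r^2; ron2 <- r_on^2; roff2 <- r_off^2
  s <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  s[r <= r_on] <- 1
  s[r >= r_off] <- 0
  s
}

# Switched LJ energy and force, single source of truth with the engine
lj_switched <- function(params, r, r_on = 8, r_off = 10) {
  u0 <- lj_energy(params, r)
  f0 <- lj_force(params, r)
  s <- switching_factor(r, r_on, r_off)
  # d(sw)/dr on the interior
  r2 <- r^2; ron2 <- r_on^2; roff2 <- r_off^2
  dsdr <- (2 * (roff2 - r2) * (-2 * r) * (roff2 + 2 * r2 - 3 * ron2) +
             (roff2 - r2)^2 * (4 * r)) / (roff2 - ron2)^3
  dsdr[r <= r_on | r >= r_off] <- 0
  tibble::tibble(r = r, U = u0 * s, F = f0 * s - u0 * dsdr)
}
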