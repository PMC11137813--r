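#' Bias potential specification
#'
#' Describes one bias acting on a distance collective variable, in the
#' vocabulary of common biasing plugins: a fixed harmonic restraint, a
#' moving harmonic restraint (steered pulling), or a one-sided harmonic
#' wall.
#'
#' @param kind One of `"harmonic"`, `"moving-harmonic"`, `"upper-wall"`,
#'   `"lower-wall"`.
#' @param kappa Stiffness, kcal/mol/Angstrom^2 (>= 0).
#' @param r0 Reference length, Angstrom (harmonic kinds).
#' @param rate Reference-length velocity, Angstrom/ns
#'   (`"moving-harmonic"` only).
#' @param ceiling Wall position, Angstrom (wall kinds only).
#' @return An object of class `bias_spec`.
#' @examples
#' bias_spec("upper-wall", kappa = 150, ceiling = 1.89)
#' bias_spec("moving-harmonic", kappa = 10, r0 = 1.9, rate = 1)
#' @export
bias_spec <- function(kind = c("harmonic", "moving-harmonic", "upper-wall", "lower-wall"),
                      kappa, r0 = 0, rate = NULL, ceiling = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("`kappa` must be a single non-negative stiffness", call. = FALSE)
  if (kind == "moving-harmonic") {
    if (is.null(rate)) stop("`rate` is required for a moving-harmonic bias", call. = FALSE)
  } else if (!is.null(rate)) {
    stop("`rate` is only defined for a moving-harmonic bias", call. = FALSE)
  }
  if (kind %in% c("upper-wall", "lower-wall")) {
    if (is.null(ceiling)) stop("walls require a `ceiling` position", call. = FALSE)
  }
  structure(list(kind = kind, kappa = kappa, r0 = r0,
                 rate = if (is.null(rate)) NA_real_ else rate,
                 ceiling = if (is.null(ceiling)) NA_real_ else ceiling),
            class = "bias_spec")
}

#' @export
print.bias_spec <- function(x, ...) {
  cat(sprintf("<bias_spec> %s, kappa = %g kcal/mol/A^2", x$kind, x$kappa))
  if (x$kind %in% c("harmonic", "moving-harmonic")) cat(sprintf(", r0 = %g A", x$r0))
  if (x$kind == "moving-harmonic") cat(sprintf(", rate = %g A/ns", x$rate))
  if (!is.na(x$ceiling)) cat(sprintf(", ceiling = %g A", x$ceiling))
  cat("\n")
  invisible(x)
}

#' Bias energy and force on a collective variable
#'
#' Closed forms: harmonic \eqn{U = \kappa/2 (x - r_0)^2}; moving harmonic
#' with \eqn{r_0(t) = r_0 + \mathrm{rate}\cdot t}; an upper wall is the
#' harmonic branch active only for \eqn{x} above the ceiling (and a lower
#' wall below it). The returned `force` is \eqn{-dU/dx}.
#'
#' @param spec A [bias_spec()].
#' @param x Collective-variable value(s), Angstrom.
#' @param t Time, ns (moving restraints; default 0, must be >= 0).
#' @return A tibble with columns `x`, `energy` (kcal/mol), `force`
#'   (kcal/mol/Angstrom) and `reference` (the instantaneous reference
#'   length or ceiling).
#' @export
bias_energy_force <- function(spec, x, t = 0) {
  stopifnot(inherits(spec, "bias_spec"))
  if (any(t < 0)) stop("time `t` must be non-negative", call. = FALSE)
  ref <- switch(spec$kind,
    "harmonic" = rep_len(spec$r0, length(x)),
    "moving-harmonic" = rep_len(spec$r0 + spec$rate * t, length(x)),
    rep_len(spec$ceiling, length(x)))
  d <- x - ref
  active <- switch(spec$kind,
    "upper-wall" = d > 0,
    "lower-wall" = d < 0,
    rep_len(TRUE, length(x)))
  u <- ifelse(active, 0.5 * spec$kappa * d^2, 0)
  f <- ifelse(active, -spec$kappa * d, 0)
  tibble::tibble(x = x, energy = u, force = f, reference = ref)
}

# bias_spec list -> engine matrix (kind, i, j, kappa, r0, rate A/ns, ceiling)
bias_matrix <- function(biases) {
  if (length(biases) == 0L) return(matrix(numeric(0), ncol = 7))
  rows <- lapply(biases, function(b) {
    spec <- b$spec
    kind <- match(spec$kind, c("harmonic", "moving-harmonic", "upper-wall", "lower-wall")) - 1L
    c(kind, b$i, b$j, spec$kappa,
      if (is.na(spec$ceiling)) spec$r0 else 0,         # r0 (engine col 5)
      ifelse(is.na(spec$rate), 0, spec$rate),          # A/ns
      ifelse(is.na(spec$ceiling), 0, spec$ceiling))    # ceiling (engine col 7)
  })
  do.call(rbind, rows)
}

#' Write a human-readable bias protocol
#'
#' Emits the configured biases as a plain-text protocol block (one line per
#' bias, in the idiom of common biasing plugins) so that a run's biasing
#' setup can be archived alongside its outputs.
#'
#' @param biases A list of entries `list(spec = bias_spec, cv = "label")`.
#' @param path File path or `""` for stdout.
#' @return Invisibly, the character vector written.
#' @export
write_bias_protocol <- function(biases, path = "") {
  lines <- c("# hemeforge bias protocol",
             vapply(biases, function(b) {
               s <- b$spec
               extra <- switch(s$kind,
                 "harmonic" = sprintf("AT=%g KAPPA=%g", s$r0, s$kappa),
                 "moving-harmonic" = sprintf("FROM=%g RATE=%g KAPPA=%g", s$r0, s$rate, s$kappa),
                 sprintf("AT=%g KAPPA=%g", s$ceiling, s$kappa))
               sprintf("%s ARG=%s %s", toupper(gsub("-", "_", s$kind)), b$cv, extra)
             }, character(1)))
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
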