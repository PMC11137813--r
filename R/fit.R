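#' Fit pair-specific LJ parameters to a coordination force curve
#'
#' Least-squares fit of the LJ force \eqn{F_{LJ}(\epsilon, \sigma; r)} to a
#' tabulated force curve over a fitting window (default 1.75-2.95 Angstrom,
#' the domain over which a coordination force curve is informative about
#' both the well and the wall). Levenberg-Marquardt with bounds and a
#' multistart over \eqn{\sigma} guards against the repulsive-wall local
#' minimum.
#'
#' When the input force was produced by [finite_difference_force()], the
#' model force is by default differenced with the same adjacent-difference
#' rule on the same grid (`model = "auto"`), so that generate-then-fit
#' roundtrips are exact rather than biased by the \eqn{O(\Delta r)} offset
#' of the forward difference. Set `model = "analytic"` to fit the closed
#' form instead.
#'
#' @param curve A [potential_curve()] with an `F` column (forces in
#'   kcal/mol/Angstrom).
#' @param r_lo,r_hi Fitting window, Angstrom.
#' @param convention LJ length convention of the returned parameters.
#' @param model `"auto"`, `"analytic"` or `"fd"`; see Details.
#' @param mask Optional logical or integer vector of points to exclude
#'   (e.g. known finite-difference artifact spikes).
#' @param weights Optional per-point weights (default unweighted).
#' @param start_sigma Multistart grid for sigma, Angstrom.
#' @param lower,upper Bounds on `c(|epsilon|, sigma)`.
#' @return An object of class `lj_fit`: fitted [lj_pair()] (epsilon signed
#'   negative, as printed in coordination parameter tables), residual norm,
#'   convergence flag and diagnostics. `tidy()` and `glance()` methods are
#'   provided.
#' @export
fit_lj_to_force <- function(curve, r_lo = 1.75, r_hi = 2.95,
                            convention = c("sigma", "rmin"),
                            model = c("auto", "analytic", "fd"),
                            mask = NULL, weights = NULL,
                            start_sigma = seq(1.6, 3.4, by = 0.45),
                            lower = c(1e-8, 1.0), upper = c(200, 4.0)) {
  stopifnot(inherits(curve, "potential_curve"))
  convention <- match.arg(convention)
  model <- match.arg(model)
  if (!"F" %in% names(curve)) stop("curve has no `F` column to fit", call. = FALSE)
  if (model == "auto")
    model <- if (identical(curve_f_method(curve), "fd")) "fd" else "analytic"

  keep <- is.finite(curve$F) & curve$r >= r_lo & curve$r <= r_hi
  if (!is.null(mask)) {
    if (is.logical(mask)) keep <- keep & !mask else keep[mask] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) < 4L)
    stop("fewer than 4 usable grid points inside the fitting window", call. = FALSE)
  r_fit <- curve$r[idx]
  f_obs <- curve$F[idx]
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]

  dr <- if (model == "fd") {
    drs <- diff(curve$r)
    drs[1]
  } else NA_real_

  model_force <- function(e, s, r) {
    p <- lj_pair(-e, s)
    if (model == "fd") {
      -(lj_energy(p, r + dr) - lj_energy(p, r)) / dr
    } else {
      lj_force(p, r)
    }
  }
  resid_fn <- function(par) sqrt(w) * (model_force(par[1], par[2], r_fit) - f_obs)

  # initial |epsilon| guess from the strongest attraction in the window
  e0 <- max(abs(f_obs)) * max(r_fit) / 2.4
  e0 <- min(max(e0, lower[1] * 10), upper[1] * 0.9)
  best <- NULL
  for (s0 in start_sigma) {
    fit <- try(minpack.lm::nls.lm(
      par = c(e0, s0), lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("LJ fit failed from every start", call. = FALSE)

  converged <- best$info %in% 1:4
  eps_hat <- -abs(best$par[1])
  sig_hat <- best$par[2]
  sig_out <- if (convention == "rmin") sig_hat * 2^(1/6) else sig_hat
  params <- lj_pair(eps_hat, sig_out, convention = convention)
  fitted <- model_force(abs(eps_hat), sig_hat, r_fit)
  structure(list(
    params = params,
    epsilon = eps_hat, sigma = sig_out, convention = convention,
    residual_norm = sqrt(best$deviance),
    converged = converged, info = best$info, message = best$message,
    model = model, window = c(r_lo, r_hi), n = length(idx),
    data = tibble::tibble(r = r_fit, F_obs = f_obs, F_fit = fitted,
                          resid = f_obs - fitted)
  ), class = "lj_fit")
}

#' @export
print.lj_fit <- function(x, ...) {
  cat(sprintf(paste0("<lj_fit> epsilon = %.4f kcal/mol, sigma = %.4f A (%s form)\n",
                     "  model force: %s | window [%.2f, %.2f] A | n = %d\n",
                     "  residual norm = %.3g kcal/mol/A | converged: %s\n"),
              x$epsilon, x$sigma, x$convention, x$model,
              x$window[1], x$window[2], x$n, x$residual_norm, x$converged))
  invisible(x)
}

#' @method tidy lj_fit
#' @export
tidy.lj_fit <- function(x, ...) {
  tibble::tibble(term = c("epsilon", "sigma"),
                 estimate = c(x$epsilon, x$sigma),
                 unit = c("kcal/mol", "Angstrom"))
}

#' @method glance lj_fit
#' @export
glance.lj_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 rmsd = x$residual_norm / sqrt(x$n),
                 n = x$n, converged = x$converged, model = x$model)
}

#' @method autoplot lj_fit
#' @export
autoplot.lj_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$F_obs), size = 1.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$F_fit), colour = "firebrick") +
    ggplot2::labs(x = "r (Å)", y = "F (kcal/mol/Å)",
                  title = sprintf("LJ fit: ε = %.3f kcal/mol, σ = %.3f Å",
                                  object$epsilon, object$sigma)) +
    ggplot2::theme_minimal()
}

#' Effective single-LJ features of a composite force curve
#'
#' Fits one LJ force law to the total force curve of the two-site O2 model
#' (or any composite curve) and returns the effective well depth and length
#' \eqn{(\epsilon_f, \sigma_f)} used as inverse-design features.
#'
#' @inheritParams fit_lj_to_force
#' @param ... Passed to [fit_lj_to_force()].
#' @return A list with `epsilon_f` (kcal/mol, signed negative), `sigma_f`
#'   (Angstrom) and the underlying `fit` object.
#' @export
fit_effective_lj <- function(curve, r_lo = 1.75, r_hi = 2.95, ...) {
  fit <- fit_lj_to_force(curve, r_lo = r_lo, r_hi = r_hi, ...)
  list(epsilon_f = fit$epsilon, sigma_f = fit$sigma, fit = fit)
}
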