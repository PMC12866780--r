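# Unconfined compression: strain/stress kinematics from side-camera
# geometry, Poisson-ratio estimation, and neo-Hookean equilibrium fitting.

#' Per-frame strain state and Cauchy stress from compression geometry
#'
#' Strain definitions: `eps_rr = r_c/R0 - 1`, `eps_zz = h_c/H0 - 1`;
#' stretches `lambda = 1 + eps`; first invariant
#' `I_C = lambda_z^2 + 2 lambda_r^2`. The axial Cauchy stress is
#' `sigma = F / (pi r_c^2)` with the stored compressive load magnitude
#' mapped to negative (compressive) stress.
#'
#' @param series A [mech_series()] with force, per-frame `height` and
#'   `radius`, and `H0`, `R0`.
#' @return A data frame with columns `time`, `eps_rr`, `eps_zz`,
#'   `lambda_r`, `lambda_z`, `I_C`, `sigma` (Pa, negative in compression).
#' @export
compute_strain_stress <- function(series) {
  stopifnot(inherits(series, "mech_series"))
  if (is.null(series$height) || is.null(series$radius) ||
      is.na(series$H0) || is.na(series$R0)) {
    stop_mechisto("geometry frames and H0/R0 required", "mechisto_format_error")
  }
  if (is.null(series$force)) {
    stop_mechisto("force channel required", "mechisto_format_error")
  }
  if (any(series$radius <= 0)) {
    stop_mechisto("radius must be > 0", "mechisto_domain_error")
  }
  eps_rr <- series$radius / series$R0 - 1
  eps_zz <- series$height / series$H0 - 1
  lambda_r <- 1 + eps_rr
  lambda_z <- 1 + eps_zz
  data.frame(time = series$time, eps_rr = eps_rr, eps_zz = eps_zz,
             lambda_r = lambda_r, lambda_z = lambda_z,
             I_C = lambda_z^2 + 2 * lambda_r^2,
             sigma = -series$force / (pi * series$radius^2))
}

#' Estimate the true Poisson's ratio from axial and radial strains
#'
#' `nu = -slope` of the least-squares line through the origin of `eps_rr`
#' on `eps_zz`. Estimates outside (0, 0.5] are clamped (to 0 below, 0.5
#' above) and flagged.
#'
#' @param states Data frame with columns `eps_rr` and `eps_zz` (e.g. from
#'   [compute_strain_stress()]), or a numeric vector of `eps_rr` with
#'   `eps_zz` supplied separately.
#' @param eps_zz Axial strains when `states` is a numeric vector.
#' @return An object of class `poisson_fit`: `nu`, `slope`, `clamped`.
#' @export
fit_poisson <- function(states, eps_zz = NULL) {
  if (is.data.frame(states)) {
    eps_rr <- states$eps_rr; eps_zz <- states$eps_zz
  } else {
    eps_rr <- states
  }
  keep <- eps_zz != 0 | eps_rr != 0
  if (sum(eps_zz != 0) < 1 || length(eps_zz[keep]) < 2) {
    stop_mechisto("need >= 2 states with nonzero axial strain",
                  "mechisto_fit_error")
  }
  slope <- sum(eps_rr * eps_zz) / sum(eps_zz^2)
  nu <- -slope
  clamped <- FALSE
  if (nu <= 0) { nu <- 0; clamped <- TRUE }
  if (nu > 0.5) { nu <- 0.5; clamped <- TRUE }
  structure(list(nu = nu, slope = slope, clamped = clamped),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> nu = %.4g%s\n", x$nu,
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Per-hold equilibrium points from a compression record
#'
#' Means of the strain state and Cauchy stress over the final
#' `window_fraction` of each hold, one row per protocol step.
#'
#' @param series A [mech_series()] with geometry frames.
#' @param protocol The [step_protocol()] used (e.g.
#'   [compression_protocol()]).
#' @param window_fraction Tail fraction of each hold (default 0.1).
#' @return Data frame with `step`, `eps_rr`, `eps_zz`, `lambda_r`,
#'   `lambda_z`, `sigma`.
#' @export
extract_equilibrium <- function(series, protocol, window_fraction = 0.1) {
  ss <- compute_strain_stress(series)
  cols <- c("eps_rr", "eps_zz", "lambda_r", "lambda_z", "sigma")
  out <- data.frame(step = seq_len(protocol$n_steps))
  for (cl in cols) {
    out[[cl]] <- .hold_window_means(series$time, ss[[cl]], protocol,
                                    window_fraction)$value
  }
  out
}

#' Fit the neo-Hookean equilibrium response of unconfined compression
#'
#' For the strain energy `W = (c/2)(I_C - 3)` with traction-free lateral
#' surfaces, the axial Cauchy stress is `sigma = c (lambda_z^2 -
#' lambda_r^2)` when the lateral stretch is measured; when it is not,
#' incompressible kinematics `lambda_r = lambda_z^(-1/2)` give the
#' classical uniaxial form `sigma = c (lambda_z^2 - 1/lambda_z)`. The model
#' is linear in `c`, so the least-squares estimate is closed form. The
#' global Young's modulus is `E = 2 c (1 + nu)`.
#'
#' @param points Data frame of equilibrium points with `lambda_z`, `sigma`
#'   and (optionally) `lambda_r`, e.g. from [extract_equilibrium()].
#' @param nu Poisson's ratio for the modulus conversion; default estimates
#'   it from the points via [fit_poisson()] when strains are present, else
#'   0.5.
#' @param use_measured_lambda_r Use measured lateral stretches in the
#'   stress model when available (default `TRUE`); otherwise substitute
#'   incompressible kinematics.
#' @return An object of class `neo_hookean_fit`: `c` (Pa), `nu`,
#'   `E_global` (Pa), `residual` (RMS stress, Pa).
#' @export
fit_neo_hookean <- function(points, nu = NULL, use_measured_lambda_r = TRUE) {
  lambda_z <- points$lambda_z
  sigma <- points$sigma
  if (length(lambda_z) < 2 || all(abs(lambda_z - 1) < 1e-12)) {
    stop_mechisto("need >= 2 points with at least one lambda_z != 1",
                  "mechisto_fit_error")
  }
  has_lr <- use_measured_lambda_r && !is.null(points$lambda_r)
  lambda_r <- if (has_lr) points$lambda_r else lambda_z^(-1 / 2)
  if (is.null(nu)) {
    nu <- if (!is.null(points$eps_rr) && !is.null(points$eps_zz)) {
      fit_poisson(points)$nu
    } else 0.5
  }
  m <- lambda_z^2 - lambda_r^2
  if (all(m == 0)) {
    stop_mechisto("degenerate design: lambda_z^2 == lambda_r^2 everywhere",
                  "mechisto_fit_error")
  }
  c_hat <- sum(sigma * m) / sum(m^2)
  if (!is.finite(c_hat)) {
    stop_mechisto("neo-Hookean fit did not converge (non-finite c)",
                  "mechisto_fit_error")
  }
  clamped <- FALSE
  if (c_hat < 0) { c_hat <- 0; clamped <- TRUE }
  structure(list(c = c_hat, nu = nu, E_global = 2 * c_hat * (1 + nu),
                 residual = sqrt(mean((sigma - c_hat * m)^2)),
                 used_measured_lambda_r = has_lr, clamped = clamped),
            class = "neo_hookean_fit")
}

#' @export
print.neo_hookean_fit <- function(x, ...) {
  cat(sprintf(
    "<neo_hookean_fit> c = %.4g Pa, nu = %.3f, E_global = %.4g Pa (rms %.3g Pa)%s\n",
    x$c, x$nu, x$E_global, x$residual,
    if (x$clamped) " [clamped]" else ""))
  invisible(x)
}
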