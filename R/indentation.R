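# Local flat-punch indentation: steady-state forces from stepped holds,
# fitted with Sneddon's solution F = E * 2R/(1 - nu^2) * delta.

#' Extract per-hold steady states from a stepped indentation record
#'
#' One row per protocol hold: the steady force is the mean force over the
#' final `window_fraction` of the hold (tail averaging suppresses residual
#' relaxation), and the indentation depth is the cumulative imposed
#' displacement `i * step_magnitude * H0`.
#'
#' @param series A [mech_series()] with force and `H0` set.
#' @param protocol The [step_protocol()] used (e.g.
#'   [indentation_protocol()]).
#' @param window_fraction Tail fraction of each hold to average, in (0, 1]
#'   (default 0.2).
#' @return A data frame with columns `step`, `delta` (m), `force` (N).
#' @export
extract_steady_states <- function(series, protocol, window_fraction = 0.2) {
  stopifnot(inherits(series, "mech_series"),
            inherits(protocol, "step_protocol"),
            window_fraction > 0, window_fraction <= 1)
  if (is.null(series$force)) {
    stop_mechisto("series has no force channel", "mechisto_format_error")
  }
  if (is.na(series$H0)) {
    stop_mechisto("series has no H0 (needed for imposed indentation)",
                  "mechisto_format_error")
  }
  tl <- protocol_timeline(protocol)
  missing <- tl$step[tl$hold_end > max(series$time) + 1e-9]
  if (length(missing)) {
    stop_mechisto(sprintf("series too short: missing holds %s",
                          paste(missing, collapse = ", ")),
                  "mechisto_format_error")
  }
  forces <- .hold_window_means(series$time, series$force, protocol,
                               window_fraction)$value
  if (protocol$n_steps * protocol$step_magnitude > 0.05 + 1e-12) {
    warning("total indentation exceeds 5% of H0: outside the small-",
            "deformation regime of the flat-punch solution", call. = FALSE)
  }
  data.frame(step = tl$step,
             delta = tl$step * protocol$step_magnitude * series$H0,
             force = forces)
}

#' Fit Sneddon's flat-punch solution to steady-state indentation data
#'
#' Least-squares line through the origin of steady force against
#' indentation depth (the contact solution has no offset term), converted
#' to a Young's modulus: `E = slope * (1 - nu^2) / (2R)`.
#'
#' @param steps Data frame with columns `delta` (m) and `force` (N), e.g.
#'   from [extract_steady_states()].
#' @param R Punch radius in meters (default 38.1 um).
#' @param nu Poisson's ratio (default 0.5, incompressible).
#' @return An object of class `sneddon_fit`: `E_local` (Pa), `R`, `nu`,
#'   `residual` (RMS force, N), `n_steps`, `clamped` (TRUE if a negative
#'   fitted slope was clamped to zero).
#' @export
fit_sneddon <- function(steps, R = 38.1e-6, nu = 0.5) {
  stopifnot(R > 0, nu > 0, nu < 1)
  delta <- steps$delta; force <- steps$force
  if (length(delta) < 2 || length(unique(delta)) < 2) {
    stop_mechisto("need >= 2 steps with distinct indentation depths",
                  "mechisto_fit_error")
  }
  if (all(delta == 0)) {
    stop_mechisto("all indentation depths are zero (degenerate design)",
                  "mechisto_fit_error")
  }
  slope <- sum(force * delta) / sum(delta^2)
  clamped <- FALSE
  if (slope < 0) {
    warning("negative fitted stiffness; E clamped at 0", call. = FALSE)
    slope <- 0
    clamped <- TRUE
  }
  E <- slope * (1 - nu^2) / (2 * R)
  structure(list(E_local = E, R = R, nu = nu,
                 residual = sqrt(mean((force - slope * delta)^2)),
                 n_steps = length(delta), clamped = clamped),
            class = "sneddon_fit")
}

#' @export
print.sneddon_fit <- function(x, ...) {
  cat(sprintf(
    "<sneddon_fit> E_local = %.4g Pa (R = %.3g m, nu = %.2f, %d steps, rms %.3g N)%s\n",
    x$E_local, x$R, x$nu, x$n_steps, x$residual,
    if (x$clamped) " [clamped]" else ""))
  invisible(x)
}
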