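# Mechanical time-series container, unit-suffixed CSV IO, cantilever force
# estimation and step protocols. All internal quantities are SI (s, m, N, Pa).

.unit_factors <- list(
  time       = c(s = 1, ms = 1e-3, min = 60),
  deflection = c(m = 1, mm = 1e-3, um = 1e-6),
  force      = c(N = 1, mN = 1e-3, uN = 1e-6),
  height     = c(m = 1, mm = 1e-3, um = 1e-6),
  radius     = c(m = 1, mm = 1e-3, um = 1e-6)
)

#' Mechanical time series for one specimen test
#'
#' Container for a time-stamped force and/or cantilever-deflection record,
#' with optional per-frame specimen geometry (current height and radius from
#' side-camera imaging) and the undeformed dimensions `H0`, `R0`.
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param force Forces in newtons (optional if `deflection` given). For
#'   compression/indentation records the stored force is the load magnitude
#'   (positive in compression); signed Cauchy stress is derived downstream.
#' @param deflection Cantilever deflections in meters (optional if `force`
#'   given).
#' @param height,radius Optional per-frame specimen height/radius in meters.
#' @param specimen_id Specimen identifier.
#' @param H0,R0 Initial (undeformed) specimen height and radius in meters.
#' @return An object of class `mech_series`.
#' @export
mech_series <- function(time, force = NULL, deflection = NULL,
                        height = NULL, radius = NULL,
                        specimen_id = "specimen",
                        H0 = NA_real_, R0 = NA_real_) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 1L) stop_mechisto("empty time vector", "mechisto_format_error")
  if (any(diff(time) <= 0)) {
    stop_mechisto("time must be strictly increasing", "mechisto_format_error")
  }
  if (is.null(force) && is.null(deflection)) {
    stop_mechisto("at least one of force or deflection is required",
                  "mechisto_format_error")
  }
  for (nm in c("force", "deflection", "height", "radius")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n) {
      stop_mechisto(sprintf("%s length (%d) != time length (%d)",
                            nm, length(v), n), "mechisto_format_error")
    }
  }
  if (!is.na(H0) && H0 <= 0) stop_mechisto("H0 must be > 0", "mechisto_format_error")
  if (!is.na(R0) && R0 <= 0) stop_mechisto("R0 must be > 0", "mechisto_format_error")
  if (!is.null(height) && any(height <= 0)) {
    stop_mechisto("all heights must be > 0", "mechisto_format_error")
  }
  if (!is.null(radius) && any(radius <= 0)) {
    stop_mechisto("all radii must be > 0", "mechisto_format_error")
  }
  structure(
    list(time = time, force = force, deflection = deflection,
         height = height, radius = radius,
         specimen_id = specimen_id, H0 = H0, R0 = R0),
    class = "mech_series"
  )
}

#' @export
print.mech_series <- function(x, ...) {
  cat(sprintf("<mech_series> specimen '%s': %d samples, %.1f-%.1f s\n",
              x$specimen_id, length(x$time), min(x$time), max(x$time)))
  cat("  channels:",
      paste(c("time",
              names(Filter(Negate(is.null),
                           x[c("force", "deflection", "height", "radius")]))),
            collapse = ", "), "\n")
  if (!is.na(x$H0)) cat(sprintf("  H0 = %.4g m, R0 = %.4g m\n", x$H0, x$R0))
  invisible(x)
}

.parse_unit_column <- function(colname) {
  m <- regmatches(colname, regexec("^([A-Za-z0-9]+)_([A-Za-z]+)$", colname))[[1]]
  if (length(m) != 3L) return(NULL)
  list(quantity = m[2], unit = m[3])
}

#' Read a mechanical time series from CSV
#'
#' Columns are matched by name with a mandatory unit suffix
#' (`time_s`, `force_N`, `force_mN`, `deflection_mm`, `height_um`, ...);
#' undeclared units are rejected rather than guessed, because silent unit
#' errors dominate this domain. Optional constant columns `H0_*` / `R0_*`
#' (or the `H0` / `R0` arguments) supply the undeformed geometry. All values
#' are converted to SI on read.
#'
#' @param path CSV file path.
#' @param units Optional named list overriding the suffix of specific
#'   quantities, e.g. `list(time = "ms")` for a plain `time` column.
#' @param specimen_id,H0,R0 Metadata overrides.
#' @return A [mech_series()].
#' @export
read_mech_csv <- function(path, units = NULL, specimen_id = NULL,
                          H0 = NULL, R0 = NULL) {
  df <- read.csv(path, check.names = FALSE)
  fields <- list()
  for (cn in names(df)) {
    if (cn == "specimen_id") {
      specimen_id <- specimen_id %||% as.character(df[[cn]][1])
      next
    }
    parsed <- .parse_unit_column(cn)
    quantity <- if (!is.null(parsed)) parsed$quantity else cn
    base_q <- sub("^(H0|R0)$", "\\1", quantity)
    lookup_q <- switch(base_q, H0 = "height", R0 = "radius", base_q)
    if (!lookup_q %in% names(.unit_factors)) next  # unknown columns ignored
    unit <- if (!is.null(parsed)) parsed$unit else units[[base_q]]
    if (is.null(unit)) {
      stop_mechisto(sprintf(
        "column '%s' has no unit suffix and no unit was configured", cn),
        "mechisto_format_error")
    }
    fac <- .unit_factors[[lookup_q]][unit]
    if (is.na(fac)) {
      stop_mechisto(sprintf("unknown unit '%s' for column '%s'", unit, cn),
                    "mechisto_format_error")
    }
    fields[[base_q]] <- as.numeric(df[[cn]]) * unname(fac)
  }
  if (is.null(fields$time)) {
    stop_mechisto("no time column found", "mechisto_format_error")
  }
  mech_series(
    time = fields$time, force = fields$force, deflection = fields$deflection,
    height = fields$height, radius = fields$radius,
    specimen_id = specimen_id %||% "specimen",
    H0 = H0 %||% (if (!is.null(fields$H0)) fields$H0[1] else NA_real_),
    R0 = R0 %||% (if (!is.null(fields$R0)) fields$R0[1] else NA_real_)
  )
}

#' Write a mechanical time series to CSV (SI unit suffixes)
#'
#' Numeric fields are written with 15 significant digits so that a
#' read/write round trip is lossless to at least 12 significant digits.
#'
#' @param x A [mech_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mech_csv <- function(x, path) {
  stopifnot(inherits(x, "mech_series"))
  df <- data.frame(time_s = x$time)
  if (!is.null(x$force)) df$force_N <- x$force
  if (!is.null(x$deflection)) df$deflection_m <- x$deflection
  if (!is.null(x$height)) df$height_m <- x$height
  if (!is.null(x$radius)) df$radius_m <- x$radius
  if (!is.na(x$H0)) df$H0_m <- x$H0
  if (!is.na(x$R0)) df$R0_m <- x$R0
  df$specimen_id <- x$specimen_id
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Force-sensing cantilever specification
#'
#' End-loaded Euler-Bernoulli microbeam used to estimate tissue forces from
#' measured beam deflection. The instrument's exact calibration is
#' unpublished, so a directly measured stiffness (N/m) may be supplied to
#' bypass the beam formula.
#'
#' @param beam_modulus Beam elastic modulus in Pa (default 411 GPa).
#' @param length Beam length in meters (57-59 mm typical).
#' @param diameter Beam diameter in meters. Typical indentation beams:
#'   0.0762, 0.1016 or 0.1524 mm; compression beams: 0.3048, 0.4064 or
#'   0.5588 mm.
#' @param stiffness Optional measured stiffness in N/m; when given it
#'   overrides the Euler-Bernoulli formula.
#' @return An object of class `cantilever_spec`.
#' @export
cantilever_spec <- function(beam_modulus = 411e9, length = 58e-3,
                            diameter = 0.3048e-3, stiffness = NULL) {
  stopifnot(beam_modulus > 0, length > 0, diameter > 0,
            is.null(stiffness) || stiffness > 0)
  structure(list(beam_modulus = beam_modulus, length = length,
                 diameter = diameter, stiffness = stiffness),
            class = "cantilever_spec")
}

#' Convert cantilever deflection to force
#'
#' End-loaded Euler-Bernoulli beam: `F = 3 E_b I delta / L^3` with second
#' moment `I = pi Phi^4 / 64`; or `F = k delta` when a measured stiffness
#' `k` is part of the spec. Linear in deflection.
#'
#' @param deflection Beam tip deflection(s) in meters.
#' @param spec A [cantilever_spec()].
#' @return Force(s) in newtons.
#' @export
beam_force <- function(deflection, spec) {
  stopifnot(inherits(spec, "cantilever_spec"))
  if (!is.null(spec$stiffness)) return(spec$stiffness * deflection)
  I <- pi * spec$diameter^4 / 64
  3 * spec$beam_modulus * I * deflection / spec$length^3
}

#' Stepped loading protocol
#'
#' Incremental ramp-hold protocol: `n_steps` strain increments of
#' `step_magnitude` (fraction of initial specimen height) each followed by a
#' hold of `hold_duration` seconds. `ramp_rate` (fraction of height per
#' second) renders ramps as finite linear segments; `NULL` means idealized
#' instantaneous steps.
#'
#' @param n_steps Number of steps (>= 1).
#' @param step_magnitude Per-step deformation, fraction of initial height in
#'   (0, 1).
#' @param hold_duration Hold time per step, seconds.
#' @param ramp_rate Optional ramp rate, fraction per second.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(n_steps, step_magnitude, hold_duration,
                          ramp_rate = NULL) {
  stopifnot(n_steps >= 1, step_magnitude > 0, step_magnitude < 1,
            hold_duration > 0, is.null(ramp_rate) || ramp_rate > 0)
  structure(list(n_steps = as.integer(n_steps),
                 step_magnitude = step_magnitude,
                 hold_duration = hold_duration, ramp_rate = ramp_rate),
            class = "step_protocol")
}

#' Standard local-indentation protocol: 5 steps of 1%, 1-min holds
#' @param ramp_rate Optional ramp rate (fraction/s), default 0.005.
#' @return A [step_protocol()].
#' @export
indentation_protocol <- function(ramp_rate = 0.005) {
  step_protocol(5L, 0.01, 60, ramp_rate)
}

#' Standard unconfined-compression protocol: 8 steps of 2.5%, 2-min holds
#' @param ramp_rate Optional ramp rate (fraction/s); `NULL` for idealized
#'   instantaneous steps.
#' @return A [step_protocol()].
#' @export
compression_protocol <- function(ramp_rate = NULL) {
  step_protocol(8L, 0.025, 120, ramp_rate)
}

#' Total cumulative deformation of a step protocol
#' @param protocol A [step_protocol()].
#' @return Total deformation as a fraction of initial height.
#' @export
total_deformation <- function(protocol) {
  stopifnot(inherits(protocol, "step_protocol"))
  protocol$n_steps * protocol$step_magnitude
}

# Per-step (ramp start, hold start, hold end) times. Idealized protocols
# (ramp_rate NULL) have zero-length ramps with the step applied at hold start.
protocol_timeline <- function(protocol) {
  d <- if (is.null(protocol$ramp_rate)) 0 else
    protocol$step_magnitude / protocol$ramp_rate
  period <- d + protocol$hold_duration
  i <- seq_len(protocol$n_steps)
  data.frame(step = i,
             ramp_start = (i - 1) * period,
             hold_start = (i - 1) * period + d,
             hold_end = i * period)
}
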