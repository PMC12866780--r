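# Modified Maxwell-Wiechert model for stepped stress relaxation: a nonlinear
# (exponentially stiffening) equilibrium spring in parallel with two Maxwell
# elements sharing stiffness c_m but with distinct viscosities eta1 < eta2.
#
# Sign convention: this module works with compressive strain/stress
# MAGNITUDES (positive numbers). With positive strains each Maxwell branch
# relaxes monotonically toward zero, which is the regime in which the
# stepwise closed-form solution (and its equilibrium interpretation) is
# well posed; the signed kinematics live in the compression module.

#' Maxwell-Wiechert parameter set
#'
#' @param c_a Nonlinear-spring stiffness, Pa (> 0).
#' @param c_b Dimensionless nonlinearity exponent coefficient of the
#'   equilibrium spring (stress `c_a exp(c_b eps) eps`).
#' @param c_m Shared Maxwell spring stiffness, Pa (>= 0; 0 degenerates the
#'   Maxwell elements to pure equilibrium response).
#' @param eta1,eta2 Dashpot viscosities, Pa s (> 0). Relabeled if needed so
#'   that `eta1 <= eta2` (fast element first).
#' @return An object of class `visco_params`.
#' @export
visco_params <- function(c_a, c_b, c_m, eta1, eta2) {
  stopifnot(c_a > 0, c_m >= 0, eta1 > 0, eta2 > 0)
  eta <- sort(c(eta1, eta2))
  structure(list(c_a = c_a, c_b = c_b, c_m = c_m,
                 eta1 = eta[1], eta2 = eta[2]),
            class = "visco_params")
}

#' @export
print.visco_params <- function(x, ...) {
  cat(sprintf(
    "<visco_params> c_a = %.4g Pa, c_b = %.4g, c_m = %.4g Pa, eta1 = %.4g Pa s, eta2 = %.4g Pa s\n",
    x$c_a, x$c_b, x$c_m, x$eta1, x$eta2))
  invisible(x)
}

#' Equilibrium (nonlinear spring) stress
#'
#' `sigma_i^0 = c_a exp(c_b eps_i) eps_i`: the long-time stress carried by
#' the nonlinear spring at step strain `eps_i`.
#'
#' @param eps Strain (any sign; dimensionless).
#' @param c_a Stiffness, Pa.
#' @param c_b Nonlinearity coefficient (dimensionless).
#' @return Stress in Pa.
#' @export
equilibrium_stress <- function(eps, c_a, c_b) {
  c_a * exp(c_b * eps) * eps
}

#' Maxwell spring strain during a hold (closed form)
#'
#' `eps^s(t) = eta ehat / (eta + ehat c_m (t - t_i))`, the closed-form
#' solution of the implied quadratic dashpot law
#' `d eps^s/dt = -(c_m/eta) (eps^s)^2` with `eps^s(t_i) = ehat`. For
#' negative `ehat` the denominator vanishes at the critical time
#' `t_i - eta/(ehat c_m)`; such evaluations raise a domain error that
#' reports the critical time.
#'
#' @param t Evaluation time(s), seconds (`t >= t_i`).
#' @param t_i Hold start time, seconds.
#' @param ehat Effective strain loaded into the element at `t_i`.
#' @param c_m Maxwell spring stiffness, Pa.
#' @param eta Dashpot viscosity, Pa s (> 0).
#' @return Spring strain(s), dimensionless.
#' @export
spring_strain <- function(t, t_i, ehat, c_m, eta) {
  stopifnot(eta > 0, all(t >= t_i))
  denom <- eta + ehat * c_m * (t - t_i)
  if (any(denom <= 0)) {
    t_crit <- t_i - eta / (ehat * c_m)
    stop_mechisto(sprintf(
      "spring_strain denominator <= 0 at t >= %.6g s (critical time %.6g s)",
      min(t[denom <= 0]), t_crit), "mechisto_domain_error")
  }
  eta * ehat / denom
}

# Per-step element states for a stepped protocol.
# strains: cumulative strain magnitude at each step (eps_1..eps_n); steps
# are applied instantaneously at hold starts t_i. Returns per-step hold
# start times, equilibrium stresses and per-element effective strains.
.visco_states <- function(params, protocol, strains = NULL) {
  n <- protocol$n_steps
  tl <- protocol_timeline(protocol)
  t_i <- tl$hold_start
  eps <- strains %||% (seq_len(n) * protocol$step_magnitude)
  stopifnot(length(eps) == n)
  etas <- c(params$eta1, params$eta2)
  ehat <- matrix(0, n, 2)
  eps_prev <- 0
  carry <- c(0, 0)  # eps_(i-1)j^s evaluated at t_i
  for (i in seq_len(n)) {
    ehat[i, ] <- eps[i] - eps_prev + carry
    if (i < n) {
      carry <- vapply(1:2, function(j) {
        spring_strain(t_i[i + 1], t_i[i], ehat[i, j], params$c_m, etas[j])
      }, numeric(1))
      eps_prev <- eps[i]
    }
  }
  list(t_i = t_i, eps = eps, ehat = ehat,
       sigma0 = equilibrium_stress(eps, params$c_a, params$c_b))
}

#' Simulate the Maxwell-Wiechert stress response to a stepped protocol
#'
#' Strain steps are applied instantaneously at the start of each hold;
#' within hold `i` the stress is
#' `sigma_i(t) = sigma_i^0 + sum_j c_m eps_ij^s(t)` with the per-element
#' carry-over rule `ehat_ij = eps_i - eps_(i-1) + eps_((i-1)j)^s(t_i)` and
#' initial conditions `eps_0 = 0`, `eps_0j^s(t_1) = 0`.
#'
#' @param params A [visco_params()].
#' @param protocol A [step_protocol()]; strains default to the cumulative
#'   protocol magnitudes `i * step_magnitude` (compression magnitudes,
#'   positive).
#' @param sample_times Times (s) at which to evaluate the stress; must lie
#'   within the protocol span. Times before the first step return 0.
#' @param strains Optional measured cumulative step strains overriding the
#'   protocol values (length `n_steps`).
#' @return Stress magnitudes (Pa) at `sample_times`.
#' @export
simulate_protocol <- function(params, protocol, sample_times, strains = NULL) {
  stopifnot(inherits(params, "visco_params"),
            inherits(protocol, "step_protocol"))
  tl <- protocol_timeline(protocol)
  if (any(sample_times < 0) || any(sample_times > max(tl$hold_end) + 1e-9)) {
    stop_mechisto("sample_times outside protocol span", "mechisto_domain_error")
  }
  st <- .visco_states(params, protocol, strains)
  idx <- findInterval(sample_times, st$t_i)
  sigma <- numeric(length(sample_times))
  etas <- c(params$eta1, params$eta2)
  for (i in seq_len(protocol$n_steps)) {
    sel <- idx == i
    if (!any(sel)) next
    tt <- sample_times[sel]
    maxwell <- params$c_m *
      (spring_strain(tt, st$t_i[i], st$ehat[i, 1], params$c_m, etas[1]) +
       spring_strain(tt, st$t_i[i], st$ehat[i, 2], params$c_m, etas[2]))
    sigma[sel] <- st$sigma0[i] + maxwell
  }
  sigma
}

# Mean stress and strain over the final `window_fraction` of each hold.
.hold_window_means <- function(time, values, protocol, window_fraction) {
  tl <- protocol_timeline(protocol)
  out <- data.frame(step = tl$step, value = NA_real_)
  for (i in seq_len(nrow(tl))) {
    w0 <- tl$hold_end[i] - window_fraction *
      (tl$hold_end[i] - tl$hold_start[i])
    # the sample at the exact hold end coincides with the next step and
    # belongs to it; keep it only for the final hold
    sel <- if (i < nrow(tl)) {
      time >= w0 - 1e-9 & time < tl$hold_end[i] - 1e-9
    } else {
      time >= w0 - 1e-9 & time <= tl$hold_end[i] + 1e-9
    }
    if (!any(sel)) {
      stop_mechisto(sprintf(
        "series does not cover the tail window of hold %d (%.6g-%.6g s)",
        i, w0, tl$hold_end[i]), "mechisto_format_error")
    }
    out$value[i] <- mean(values[sel])
  }
  out
}

#' Fit the Maxwell-Wiechert model to a stepped stress-relaxation record
#'
#' Two-step procedure with an optional joint polish:
#' \enumerate{
#'   \item Equilibrium: per-step end-of-hold stresses (mean of the final
#'     `window_fraction` of each hold) are fitted with the nonlinear-spring
#'     law `sigma = c_a exp(c_b eps) eps` by nonlinear least squares
#'     (log-linearized start).
#'   \item Transient: `c_m`, `eta1`, `eta2` are fitted to the full sampled
#'     hold trace with `(c_a, c_b)` frozen, using Levenberg-Marquardt with
#'     multi-start over a log-spaced grid of `(eta1, eta2)` initializations;
#'     `eta1 <= eta2` is enforced by relabeling.
#'   \item `refine = TRUE` (default) jointly re-fits all five parameters
#'     from the best two-step solution. The slow branch has typically not
#'     fully decayed at the end of a hold, which biases the equilibrium
#'     estimates of step 1; the polish removes that bias.
#' }
#'
#' The record is reduced to compressive stress magnitudes: if geometry
#' frames are present the Cauchy stress and per-step strains are computed
#' from them, otherwise the protocol strains and a provided or constant
#' radius are used.
#'
#' @param series A [mech_series()] with force and (ideally) geometry frames.
#' @param protocol The [step_protocol()] used for the test.
#' @param stress Optional precomputed stress magnitudes (Pa), overriding
#'   derivation from the series.
#' @param window_fraction Tail fraction of each hold used for the
#'   equilibrium stresses (default 0.1).
#' @param n_starts Number of `(eta1, eta2)` multi-start initializations
#'   (default 8).
#' @param refine Jointly polish all five parameters after the two-step fit
#'   (default `TRUE`).
#' @return An object of class `visco_fit`: `params` ([visco_params()]),
#'   `rms` residual (Pa), per-start convergence diagnostics, and flags
#'   (`slow_eta`: `eta2 / c_m` exceeds 10 x the hold duration, a warning
#'   that the slow time constant is poorly constrained by the record).
#' @export
fit_viscoelastic <- function(series, protocol, stress = NULL,
                             window_fraction = 0.1, n_starts = 8,
                             refine = TRUE) {
  stopifnot(inherits(series, "mech_series"),
            inherits(protocol, "step_protocol"))
  n <- protocol$n_steps
  if (is.null(stress)) {
    if (!is.null(series$height) && !is.null(series$radius) &&
        !is.na(series$H0) && !is.na(series$R0)) {
      ss <- compute_strain_stress(series)
      stress <- abs(ss$sigma)
      strains <- abs(.hold_window_means(series$time, ss$eps_zz, protocol,
                                        window_fraction)$value)
    } else {
      stop_mechisto(
        "geometry frames absent: supply `stress` explicitly",
        "mechisto_format_error")
    }
  } else {
    strains <- seq_len(n) * protocol$step_magnitude
  }
  if (n < 2) stop_mechisto("need >= 2 holds", "mechisto_format_error")

  # -- step 1: equilibrium fit of (c_a, c_b)
  eq <- .hold_window_means(series$time, stress, protocol, window_fraction)
  eps_i <- strains
  sig_i <- eq$value
  ok <- sig_i > 0 & eps_i > 0
  if (sum(ok) < 2) {
    stop_mechisto("fewer than 2 positive equilibrium stresses",
                  "mechisto_fit_error")
  }
  lin <- lm(log(sig_i[ok] / eps_i[ok]) ~ eps_i[ok])
  start_eq <- c(c_a = exp(coef(lin)[[1]]), c_b = coef(lin)[[2]])
  eq_fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start_eq,
      fn = function(p) sig_i[ok] - equilibrium_stress(eps_i[ok], p[1], p[2]),
      lower = c(1, -50), upper = c(1e6, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  cab <- if (is.null(eq_fit)) start_eq else eq_fit$par
  c_a0 <- unname(cab[1]); c_b0 <- unname(cab[2])

  # -- step 2: transient fit of (c_m, eta1, eta2) on the hold samples
  tl <- protocol_timeline(protocol)
  hold_sel <- rep(FALSE, length(series$time))
  for (i in seq_len(n)) {
    hold_sel <- hold_sel |
      (series$time >= tl$hold_start[i] - 1e-9 &
       series$time <= tl$hold_end[i] + 1e-9)
  }
  t_fit <- series$time[hold_sel]
  s_fit <- stress[hold_sel]

  model_sigma <- function(c_a, c_b, c_m, eta1, eta2) {
    p <- visco_params(c_a, c_b, c_m, eta1, eta2)
    simulate_protocol(p, protocol, t_fit, strains = eps_i)
  }

  # characteristic eta scale: decay time ~ eta / (c_m * eps) ~ hold duration
  c_m0 <- max(c_a0 / 2, 1)
  eta_char <- c_m0 * mean(eps_i) * protocol$hold_duration
  alpha <- 10^seq(-1.5, 1, length.out = max(2, ceiling(n_starts / 2)))
  starts <- do.call(rbind, lapply(alpha, function(a) {
    rbind(c(eta1 = a * eta_char, eta2 = 10 * a * eta_char),
          c(eta1 = a * eta_char, eta2 = 100 * a * eta_char))
  }))[seq_len(n_starts), , drop = FALSE]

  runs <- vector("list", nrow(starts))
  for (k in seq_len(nrow(starts))) {
    runs[[k]] <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = c(c_m = c_m0, eta1 = unname(starts[k, 1]),
                eta2 = unname(starts[k, 2])),
        fn = function(p) s_fit - model_sigma(c_a0, c_b0, p[1], p[2], p[3]),
        lower = c(1, 1, 1), upper = c(1e6, 1e8, 1e8),
        control = minpack.lm::nls.lm.control(maxiter = 300))
      list(coef = fit$par, rss = sum(fit$fvec^2),
           converged = fit$info %in% 1:4, message = fit$message)
    }, error = function(e) {
      list(coef = NULL, rss = Inf, converged = FALSE,
           message = conditionMessage(e))
    })
  }
  rss <- vapply(runs, `[[`, numeric(1), "rss")
  if (all(!is.finite(rss))) {
    stop_mechisto(paste0(
      "viscoelastic transient fit failed from every start:\n",
      paste(vapply(runs, `[[`, character(1), "message"), collapse = "\n")),
      "mechisto_fit_error")
  }
  best <- runs[[which.min(rss)]]$coef
  est <- c(c_a = c_a0, c_b = c_b0, best)

  # -- step 3: joint polish of all five parameters
  if (refine) {
    joint <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = est,
        fn = function(p) s_fit - model_sigma(p[1], p[2], p[3], p[4], p[5]),
        lower = c(1, -50, 1, 1, 1),
        upper = c(1e6, 50, 1e6, 1e8, 1e8),
        control = minpack.lm::nls.lm.control(maxiter = 500))
      list(coef = fit$par, rss = sum(fit$fvec^2))
    }, error = function(e) NULL)
    if (!is.null(joint) && joint$rss <= min(rss, na.rm = TRUE)) {
      est <- joint$coef
    }
  }

  params <- visco_params(est[["c_a"]], est[["c_b"]], est[["c_m"]],
                         est[["eta1"]], est[["eta2"]])
  pred <- model_sigma(params$c_a, params$c_b, params$c_m,
                      params$eta1, params$eta2)
  structure(list(
    params = params,
    rms = sqrt(mean((s_fit - pred)^2)),
    equilibrium = data.frame(step = seq_len(n), eps = eps_i, sigma = sig_i),
    starts = data.frame(starts, rss = rss,
                        converged = vapply(runs, `[[`, logical(1), "converged")),
    refined = refine,
    flags = list(slow_eta = params$eta2 / params$c_m >
                   10 * protocol$hold_duration)
  ), class = "visco_fit")
}

#' @export
print.visco_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  rms residual %.4g Pa; %d/%d starts converged%s\n",
              x$rms, sum(x$starts$converged), nrow(x$starts),
              if (x$flags$slow_eta) "; flag: eta2/c_m >> hold" else ""))
  invisible(x)
}
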