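# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. All generators are pure functions of (parameters, seed):
# the RNG state is scoped with withr::with_seed, so the same call is
# byte-reproducible and the caller's RNG stream is untouched.

#' Ground-truth record for a synthetic artifact
#'
#' @param generator Generator name.
#' @param parameters Named list of generating parameters.
#' @param seed Integer seed used.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(generator, parameters, seed) {
  structure(list(generator = generator, parameters = parameters,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Write / read a ground-truth sidecar as YAML
#' @param truth A [synthetic_truth()].
#' @param path YAML file path.
#' @return `path` (write) or the reconstructed [synthetic_truth()] (read).
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_truth(x$generator, x$parameters, x$seed)
}

#' Synthetic stepped indentation record
#'
#' Renders the stepped flat-punch protocol: linear force ramps to each new
#' step, then holds whose (noise-free) force sits exactly on the Sneddon
#' line `F = E 2R delta / (1 - nu^2)` at the cumulative indentation
#' `delta_i = i * step_magnitude * H0`, plus zero-mean Gaussian force noise
#' on every sample.
#'
#' @param E_true True Young's modulus, Pa (>= 0).
#' @param R Punch radius, m (default 38.1 um).
#' @param nu Poisson's ratio in (0, 0.5].
#' @param H0 Initial specimen height, m.
#' @param protocol A [step_protocol()] (default [indentation_protocol()]).
#' @param noise_sd Force noise standard deviation, N.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate, Hz (default 10).
#' @return List with `series` ([mech_series()]) and `truth`
#'   ([synthetic_truth()]).
#' @export
gen_indentation <- function(E_true, R = 38.1e-6, nu = 0.5, H0 = 3e-3,
                            protocol = indentation_protocol(),
                            noise_sd = 0, seed = 1, sample_rate = 10) {
  stopifnot(E_true >= 0, R > 0, H0 > 0, noise_sd >= 0)
  if (!(nu > 0 && nu <= 0.5)) {
    stop_mechisto("nu must be in (0, 0.5]", "mechisto_domain_error")
  }
  tl <- protocol_timeline(protocol)
  t_end <- max(tl$hold_end)
  time <- seq(0, t_end, by = 1 / sample_rate)
  delta_i <- c(0, tl$step * protocol$step_magnitude * H0)
  F_i <- E_true * 2 * R * delta_i / (1 - nu^2)
  force <- numeric(length(time))
  for (i in seq_len(protocol$n_steps)) {
    ramp <- time >= tl$ramp_start[i] & time < tl$hold_start[i]
    if (any(ramp)) {
      frac <- (time[ramp] - tl$ramp_start[i]) /
        (tl$hold_start[i] - tl$ramp_start[i])
      force[ramp] <- F_i[i] + frac * (F_i[i + 1] - F_i[i])
    }
    hold <- time >= tl$hold_start[i] & time <= tl$hold_end[i]
    force[hold] <- F_i[i + 1]
  }
  force <- withr::with_seed(seed, force + rnorm(length(force), 0, noise_sd))
  list(series = mech_series(time, force = force, H0 = H0,
                            specimen_id = "synthetic-indentation"),
       truth = synthetic_truth("gen_indentation",
                               list(E_true = E_true, R = R, nu = nu, H0 = H0,
                                    n_steps = protocol$n_steps,
                                    step_magnitude = protocol$step_magnitude,
                                    hold_duration = protocol$hold_duration,
                                    noise_sd = noise_sd,
                                    sample_rate = sample_rate), seed))
}

#' Synthetic stepped stress-relaxation (unconfined compression) record
#'
#' Strain steps are applied instantaneously at hold starts; the
#' compressive stress magnitude follows the Maxwell-Wiechert response of
#' [simulate_protocol()], Gaussian noise is added on the stress, and the
#' record is stored as a force (`F = sigma * pi * r_c^2`) plus noise-free
#' geometry frames whose radii satisfy `eps_rr = -nu_true * eps_zz`
#' exactly.
#'
#' @param params A [visco_params()]; the default is a soft-tissue-scale
#'   parameter set (equilibrium tangent stiffness 1 kPa, fast/slow
#'   relaxation times of roughly 10 and 100 s under the standard protocol).
#' @param nu_true True Poisson's ratio in (0, 0.5].
#' @param H0,R0 Initial specimen height and radius, m.
#' @param protocol A [step_protocol()] (default [compression_protocol()]);
#'   total deformation must stay below 100%.
#' @param noise_sd Stress noise standard deviation, Pa.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate, Hz (default 2).
#' @return List with `series` and `truth`.
#' @export
gen_relaxation <- function(params = visco_params(1000, 2, 500, 150, 1500),
                           nu_true = 0.45, H0 = 3e-3, R0 = 1.5e-3,
                           protocol = compression_protocol(),
                           noise_sd = 0, seed = 1, sample_rate = 2) {
  stopifnot(inherits(params, "visco_params"), noise_sd >= 0)
  if (!(nu_true > 0 && nu_true <= 0.5)) {
    stop_mechisto("nu_true must be in (0, 0.5]", "mechisto_domain_error")
  }
  if (total_deformation(protocol) >= 1) {
    stop_mechisto("protocol total deformation >= 100%", "mechisto_domain_error")
  }
  tl <- protocol_timeline(protocol)
  time <- seq(0, max(tl$hold_end), by = 1 / sample_rate)
  sigma <- simulate_protocol(params, protocol, time)
  step_idx <- findInterval(time, tl$hold_start)
  eps_zz <- -c(0, tl$step * protocol$step_magnitude)[step_idx + 1]
  eps_rr <- -nu_true * eps_zz
  height <- H0 * (1 + eps_zz)
  radius <- R0 * (1 + eps_rr)
  sigma_noisy <- withr::with_seed(seed, sigma + rnorm(length(sigma), 0, noise_sd))
  force <- sigma_noisy * pi * radius^2
  list(series = mech_series(time, force = force, height = height,
                            radius = radius, H0 = H0, R0 = R0,
                            specimen_id = "synthetic-relaxation"),
       truth = synthetic_truth("gen_relaxation",
                               c(unclass(params),
                                 list(nu_true = nu_true, H0 = H0, R0 = R0,
                                      n_steps = protocol$n_steps,
                                      step_magnitude = protocol$step_magnitude,
                                      hold_duration = protocol$hold_duration,
                                      noise_sd = noise_sd,
                                      sample_rate = sample_rate)), seed))
}

# Smooth low-frequency random field on an n x n grid (sum of random plane
# waves) used to carve contiguous, irregular regions.
.smooth_field <- function(n, n_waves = 8) {
  x <- matrix(rep(seq_len(n) / n, n), n, n)
  y <- t(x)
  f <- matrix(0, n, n)
  for (k in seq_len(n_waves)) {
    fx <- rnorm(1, 0, 2.5); fy <- rnorm(1, 0, 2.5)
    ph <- runif(1, 0, 2 * pi)
    f <- f + rnorm(1) * sin(2 * pi * (fx * x + fy * y) + ph)
  }
  f
}

#' Synthetic stained-section raster with known class area fractions
#'
#' Composes contiguous class regions with irregular boundaries by
#' thresholding smooth random fields at exact pixel-count quantiles: the
#' requested `class_fractions` are fractions of the TOTAL image area, the
#' remainder is background (white for MTC, black for PSR), and class
#' colors are drawn from the interior of the corresponding printed HSL
#' band so that colorimetric classification recovers the label map.
#'
#' @param stain `"MTC"` or `"PSR"`.
#' @param class_fractions Named fractions in [0, 1] summing to <= 1; names
#'   must match the stain's band names ([mtc_bands()] / [psr_bands()]).
#' @param size Image side length in pixels (default 256).
#' @param seed Integer seed.
#' @return List with `img` (RGB array in [0, 1]), `labels` (character
#'   matrix: band names, `"background"`), and `truth`.
#' @export
gen_stain_raster <- function(stain = c("MTC", "PSR"), class_fractions,
                             size = 256, seed = 1) {
  stain <- match.arg(stain)
  if (any(class_fractions < 0) || any(class_fractions > 1) ||
      sum(class_fractions) > 1 + 1e-12) {
    stop_mechisto("class fractions must lie in [0, 1] and sum to <= 1",
                  "mechisto_domain_error")
  }
  bands <- if (stain == "MTC") mtc_bands() else psr_bands()
  band_names <- vapply(bands, `[[`, character(1), "name")
  if (!all(names(class_fractions) %in% band_names)) {
    stop_mechisto(sprintf("unknown class name(s); %s bands are: %s", stain,
                          paste(band_names, collapse = ", ")),
                  "mechisto_domain_error")
  }
  npix <- size^2
  withr::with_seed(seed, {
    tissue_field <- .smooth_field(size)
    class_field <- .smooth_field(size)
    n_tissue <- round(sum(class_fractions) * npix)
    # tissue = the n_tissue pixels with the highest tissue-field values
    ord <- order(tissue_field, decreasing = TRUE)
    labels <- matrix("background", size, size)
    tissue_idx <- ord[seq_len(n_tissue)]
    # partition tissue pixels by class-field order at exact counts
    stops <- round(cumsum(class_fractions) / sum(class_fractions) * n_tissue)
    counts <- diff(c(0, stops))
    t_ord <- tissue_idx[order(class_field[tissue_idx])]
    starts <- c(1, head(stops, -1) + 1)
    for (k in seq_along(class_fractions)) {
      if (counts[k] > 0) {
        labels[t_ord[starts[k]:stops[k]]] <- names(class_fractions)[k]
      }
    }
    img <- array(if (stain == "MTC") 1 else 0, dim = c(size, size, 3))
    for (k in seq_along(bands)) {
      b <- bands[[k]]
      sel <- labels == b$name
      n_sel <- sum(sel)
      if (!n_sel) next
      width <- (b$hue_hi - b$hue_lo) %% 360
      h <- (b$hue_lo + width * runif(n_sel, 0.25, 0.75)) %% 360
      s <- b$sat[1] + diff(b$sat) * runif(n_sel, 0.4, 0.8)
      l <- b$light[1] + diff(b$light) * runif(n_sel, 0.35, 0.6)
      rgb <- hsl_to_rgb(h, s, l)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- round(rgb[, ch] * 255) / 255  # 8-bit quantization
        img[, , ch] <- plane
      }
    }
    list(img = img, labels = labels,
         truth = synthetic_truth("gen_stain_raster",
                                 list(stain = stain,
                                      class_fractions = as.list(class_fractions),
                                      size = size), seed))
  })
}

#' Write an RGB array to PNG
#' @param img RGB array in [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm); kappa = 0
# falls back to the circular uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

#' Synthetic fiber segment table with controlled angular concentration
#'
#' Axial angles are drawn by sampling a von Mises distribution on the
#' doubled angles `2 theta` with concentration `kappa` and halving (the
#' standard axial-data construction); `kappa = 0` gives the uniform axial
#' distribution and `grid = TRUE` places one fiber at each of `n` evenly
#' spaced angles instead. Lengths and widths are Gaussian truncated at
#' zero.
#'
#' @param n Number of fibers (>= 1).
#' @param mean_angle Mean fiber angle, degrees.
#' @param kappa von Mises concentration on the doubled angles (>= 0).
#' @param length_dist,width_dist `(mean, sd)` in micrometers.
#' @param seed Integer seed.
#' @param grid Use an even angular grid over [0, 180) instead of sampling.
#' @return List with `fibers` ([fiber_set()]) and `truth`.
#' @export
gen_fibers <- function(n, mean_angle = 90, kappa = 1,
                       length_dist = c(30, 10), width_dist = c(3, 1),
                       seed = 1, grid = FALSE) {
  stopifnot(n >= 1, kappa >= 0)
  withr::with_seed(seed, {
    angles <- if (grid) {
      seq(0, 180, length.out = n + 1)[seq_len(n)]
    } else {
      (rvonmises(n, 2 * mean_angle * pi / 180, kappa) / 2 * 180 / pi) %% 180
    }
    lengths <- pmax(rnorm(n, length_dist[1], length_dist[2]), 1e-6)
    widths <- pmax(rnorm(n, width_dist[1], width_dist[2]), 1e-6)
    intens <- pmax(rnorm(n, 100, 20), 0)
    list(fibers = fiber_set(angles, lengths, widths, intens),
         truth = synthetic_truth("gen_fibers",
                                 list(n = n, mean_angle = mean_angle,
                                      kappa = kappa,
                                      length_dist = length_dist,
                                      width_dist = width_dist,
                                      grid = grid), seed))
  })
}

# Archetype means on natural scales: area um^2 (log-normal), aspect ratio
# (log-normal), marker intensities a.u. (log-normal). The four archetypes
# mirror the phenotype rule: PanCK marks epithelium, Vimentin stroma and
# immune cells, area splits large vs small.
.cell_archetypes <- function(separation = 1) {
  list(
    `epithelial-large` = c(area = 400, aspect = 1.3, PanCK = 1000, Vimentin = 100),
    `epithelial-small` = c(area = 120, aspect = 1.2, PanCK = 1000, Vimentin = 100),
    stroma             = c(area = 350, aspect = 2.2, PanCK = 100,  Vimentin = 900),
    immune             = c(area = 80,  aspect = 1.1, PanCK = 100,  Vimentin = 700)
  )
}

#' Synthetic single-cell feature table with four latent phenotypes
#'
#' Mixes four phenotype archetypes (epithelial-large, epithelial-small,
#' stroma, immune) within each of the four study groups (onset AO/EO x
#' tissue normal/cancer). Cell areas and marker intensities are log-normal
#' (positive, right-skewed); axes are derived from area and aspect ratio
#' via an elliptical model. `group_effects` shifts the log-scale location
#' of area, aspect ratio, PanCK and Vimentin per group; the defaults
#' emulate the qualitative study contrasts (smaller cells and more
#' elongated, Vimentin-shifted stroma in early-onset tissue, strongest in
#' cancer).
#'
#' @param n_per_group Cells per group (>= 10; default 250).
#' @param group_effects Named list `group -> c(area, aspect, PanCK,
#'   Vimentin)` of log-scale location shifts; groups are `"AO.normal"`,
#'   `"AO.cancer"`, `"EO.normal"`, `"EO.cancer"`. `NULL` uses the defaults
#'   below; pass zero vectors for an exchangeable null.
#' @param archetype_sd Log-scale within-archetype spread (default 0.25;
#'   smaller values separate the archetypes more cleanly).
#' @param seed Integer seed.
#' @return List with `cells` (data frame incl. `onset`, `tissue`, `group`
#'   columns), `truth` (latent phenotype labels in
#'   `truth$parameters$latent`).
#' @export
gen_cell_table <- function(n_per_group = 250, group_effects = NULL,
                           archetype_sd = 0.25, seed = 1) {
  stopifnot(n_per_group >= 10)
  groups <- c("AO.normal", "AO.cancer", "EO.normal", "EO.cancer")
  if (is.null(group_effects)) {
    group_effects <- list(
      AO.normal = c(area = 0,     aspect = 0,    PanCK = 0,    Vimentin = 0),
      AO.cancer = c(area = 0.05,  aspect = 0.05, PanCK = 0.1,  Vimentin = 0.05),
      EO.normal = c(area = -0.15, aspect = 0.05, PanCK = 0,    Vimentin = 0.05),
      EO.cancer = c(area = -0.20, aspect = 0.10, PanCK = 0.1,  Vimentin = 0.15))
  }
  stopifnot(all(groups %in% names(group_effects)))
  arch <- .cell_archetypes()
  withr::with_seed(seed, {
    rows <- list()
    latent <- character(0)
    for (g in groups) {
      eff <- group_effects[[g]]
      ph <- sample(names(arch), n_per_group, replace = TRUE)
      a <- do.call(rbind, arch[ph])
      area <- exp(rnorm(n_per_group, log(a[, "area"]) + eff[["area"]],
                        archetype_sd))
      aspect <- pmax(exp(rnorm(n_per_group, log(a[, "aspect"]) + eff[["aspect"]],
                               archetype_sd / 2)), 1)
      minor <- sqrt(4 * area / (pi * aspect))
      major <- aspect * minor
      onset_tissue <- strsplit(g, ".", fixed = TRUE)[[1]]
      rows[[g]] <- data.frame(
        onset = onset_tissue[1], tissue = onset_tissue[2], group = g,
        area = area, major_axis = major, minor_axis = minor,
        eccentricity = sqrt(pmax(1 - 1 / aspect^2, 0)),
        solidity = pmin(pmax(rnorm(n_per_group, 0.92, 0.03), 0.5), 1),
        extent = pmin(pmax(rnorm(n_per_group, 0.7, 0.05), 0.2), 1),
        orientation = runif(n_per_group, -90, 90),
        PanCK = exp(rnorm(n_per_group, log(a[, "PanCK"]) + eff[["PanCK"]],
                          archetype_sd)),
        Vimentin = exp(rnorm(n_per_group, log(a[, "Vimentin"]) +
                               eff[["Vimentin"]], archetype_sd)))
      latent <- c(latent, ph)
    }
    cells <- do.call(rbind, rows)
    rownames(cells) <- NULL
    list(cells = cells,
         truth = synthetic_truth("gen_cell_table",
                                 list(n_per_group = n_per_group,
                                      group_effects = group_effects,
                                      archetype_sd = archetype_sd,
                                      latent = latent), seed))
  })
}

#' Synthetic grouped measurement table
#'
#' Gaussian samples with per-group location shifts; a fixture for the
#' group-statistics module. One-factor design when `shifts` is a named
#' vector; two-factor (crossed) design when `shifts` is a named matrix
#' (rows = factor A levels, columns = factor B levels).
#'
#' @param n_per_group Observations per group/cell.
#' @param shifts Named numeric vector or matrix of location shifts.
#' @param noise_sd Noise scale (default 1).
#' @param seed Integer seed.
#' @return List with `data` (data frame `value`, `group` or `value`, `a`,
#'   `b`) and `truth`.
#' @export
gen_grouped <- function(n_per_group, shifts, noise_sd = 1, seed = 1) {
  stopifnot(n_per_group >= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    if (is.matrix(shifts)) {
      cells <- expand.grid(a = rownames(shifts), b = colnames(shifts),
                           stringsAsFactors = FALSE)
      df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        data.frame(value = rnorm(n_per_group,
                                 shifts[cells$a[i], cells$b[i]], noise_sd),
                   a = cells$a[i], b = cells$b[i])
      }))
    } else {
      df <- do.call(rbind, lapply(names(shifts), function(g) {
        data.frame(value = rnorm(n_per_group, shifts[[g]], noise_sd),
                   group = g)
      }))
    }
    rownames(df) <- NULL
    list(data = df,
         truth = synthetic_truth("gen_grouped",
                                 list(n_per_group = n_per_group,
                                      shifts = shifts,
                                      noise_sd = noise_sd), seed))
  })
}
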