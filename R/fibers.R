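# Fiber-segment summaries: mean geometry/intensity and the Orientation
# Index (1 - circular variance) of fiber angles.

#' Fiber segment table
#'
#' Per-fiber angle/length/width/intensity records of the kind produced by
#' ridge/line detection on second-harmonic-generation images.
#'
#' @param angle_deg Fiber angles in degrees; reduced mod 180 (axial data).
#' @param length_um,width_um Fiber length and width in micrometers (> 0).
#' @param intensity Mean fiber intensity, arbitrary units (>= 0); defaults
#'   to 0 when not recorded.
#' @return A data frame of class `fiber_set`.
#' @export
fiber_set <- function(angle_deg, length_um, width_um,
                      intensity = rep(0, length(angle_deg))) {
  if (length(angle_deg) < 1) {
    stop_mechisto("empty fiber set", "mechisto_format_error")
  }
  stopifnot(all(length_um > 0), all(width_um > 0), all(intensity >= 0))
  structure(data.frame(angle_deg = angle_deg %% 180,
                       length_um = length_um, width_um = width_um,
                       intensity = intensity),
            class = c("fiber_set", "data.frame"))
}

#' Orientation Index and circular variance of fiber angles
#'
#' `OI = 1 - circular variance`. In axial mode (default) angles are doubled
#' before computing the mean resultant length `Rbar` of the unit vectors
#' (the standard construction for orientations defined modulo 180 degrees),
#' so `OI = Rbar` ranges from 0 for uniformly spread orientations to 1 for
#' perfectly aligned fibers. Non-axial mode computes the same quantities on
#' the raw angles.
#'
#' @param angles_deg Angles in degrees (>= 1 value).
#' @param axial Double angles before averaging (default `TRUE`).
#' @param weights Optional non-negative weights (e.g. fiber lengths).
#' @return List with `oi` and `circular_variance` (`oi = 1 -
#'   circular_variance` exactly).
#' @export
orientation_index <- function(angles_deg, axial = TRUE, weights = NULL) {
  if (length(angles_deg) < 1) {
    stop_mechisto("empty angle set", "mechisto_domain_error")
  }
  theta <- (if (axial) 2 else 1) * angles_deg * pi / 180
  w <- weights %||% rep(1, length(theta))
  stopifnot(length(w) == length(theta), all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  rbar <- sqrt(sum(w * cos(theta))^2 + sum(w * sin(theta))^2)
  cv <- 1 - rbar
  list(oi = 1 - cv, circular_variance = cv)  # oi = 1 - cv holds exactly
}

#' Summarize a fiber set
#'
#' Arithmetic means of length, width and intensity plus the Orientation
#' Index of the angles.
#'
#' @param fibers A [fiber_set()].
#' @param axial Axial-angle doubling for the OI (default `TRUE`).
#' @param length_weighted Weight the OI by fiber length (default `FALSE`;
#'   each fiber counts once).
#' @return List with `mean_length`, `mean_width`, `mean_intensity`, `oi`,
#'   `circular_variance`, `n_fibers`.
#' @export
fiber_summary <- function(fibers, axial = TRUE, length_weighted = FALSE) {
  if (!nrow(fibers)) stop_mechisto("empty fiber set", "mechisto_domain_error")
  oi <- orientation_index(
    fibers$angle_deg, axial = axial,
    weights = if (length_weighted) fibers$length_um else NULL)
  list(mean_length = mean(fibers$length_um),
       mean_width = mean(fibers$width_um),
       mean_intensity = mean(fibers$intensity),
       oi = oi$oi, circular_variance = oi$circular_variance,
       n_fibers = nrow(fibers))
}

#' Mean signal intensity over a region mask
#'
#' @param img Single-channel numeric matrix (e.g. an SHG image).
#' @param mask Logical matrix of the same dimensions; must select at least
#'   one pixel. Defaults to the whole image.
#' @return Arithmetic mean intensity over masked pixels.
#' @export
mean_shg_intensity <- function(img, mask = NULL) {
  mask <- mask %||% matrix(TRUE, nrow(img), ncol(img))
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) stop_mechisto("empty region mask", "mechisto_domain_error")
  mean(img[mask])
}
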