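# Colorimetric pixel classification of trichrome (MTC) and Picrosirius-red
# (PSR) stains in HSL space, with area-fraction reporting over tissue
# (non-background) pixels.

#' Convert an RGB raster to HSL channels
#'
#' Standard bi-cone hue-saturation-lightness conversion from normalized
#' RGB. Hue in degrees [0, 360); saturation and lightness in [0, 1].
#' Conversion is done in floating point; no gamma correction is applied.
#'
#' @param img Numeric array `h x w x 3` with values in [0, 1] (as returned
#'   by [png::readPNG()]/[tiff::readTIFF()]), or integer 0-255.
#' @return List of matrices `H`, `S`, `L`.
#' @export
rgb_to_hsl <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop_mechisto("expected an h x w x 3 RGB array", "mechisto_format_error")
  }
  if (max(img) > 1) img <- img / 255
  nr <- dim(img)[1]; nc <- dim(img)[2]
  r <- matrix(img[, , 1], nr, nc)
  g <- matrix(img[, , 2], nr, nc)
  b <- matrix(img[, , 3], nr, nc)
  M <- pmax(r, g, b); m <- pmin(r, g, b)
  L <- (M + m) / 2
  C <- M - m
  S <- ifelse(C == 0, 0, C / (1 - abs(2 * L - 1)))
  H <- matrix(0, nr, nc)
  sel <- C > 0 & M == r
  H[sel] <- ((g - b)[sel] / C[sel]) %% 6
  sel <- C > 0 & M == g & M != r
  H[sel] <- (b - r)[sel] / C[sel] + 2
  sel <- C > 0 & M == b & M != r & M != g
  H[sel] <- (r - g)[sel] / C[sel] + 4
  list(H = 60 * H, S = S, L = L)
}

#' Convert HSL values to RGB
#'
#' @param h Hue in degrees (any real; reduced mod 360).
#' @param s,l Saturation and lightness in [0, 1].
#' @return Matrix with columns r, g, b in [0, 1].
#' @export
hsl_to_rgb <- function(h, s, l) {
  h <- h %% 360
  C <- (1 - abs(2 * l - 1)) * s
  X <- C * (1 - abs((h / 60) %% 2 - 1))
  m <- l - C / 2
  k <- floor(h / 60) %% 6
  r <- ifelse(k == 0 | k == 5, C, ifelse(k == 1 | k == 4, X, 0))
  g <- ifelse(k == 1 | k == 2, C, ifelse(k == 0 | k == 3, X, 0))
  b <- ifelse(k == 3 | k == 4, C, ifelse(k == 2 | k == 5, X, 0))
  cbind(r = r + m, g = g + m, b = b + m)
}

#' Hue/saturation/lightness band definition
#'
#' Printed integer hue bounds are inclusive; comparisons use the half-open
#' interval `[lo, hi + 1)` after wraparound unrolling, so adjacent printed
#' bands (e.g. 12 / 13 degrees) partition without double counting.
#' `hue_lo > hue_hi` denotes a band crossing 0 degrees.
#'
#' @param name Band name.
#' @param hue_lo,hue_hi Hue bounds in degrees (inclusive, as printed).
#' @param sat,light Length-2 saturation and lightness ranges in [0, 1]
#'   (inclusive).
#' @return An object of class `hue_band`.
#' @export
hue_band <- function(name, hue_lo, hue_hi, sat = c(0, 1), light = c(0, 1)) {
  stopifnot(hue_lo >= 0, hue_lo < 360, hue_hi >= 0, hue_hi < 360,
            all(sat >= 0), all(sat <= 1), all(light >= 0), all(light <= 1))
  structure(list(name = name, hue_lo = hue_lo, hue_hi = hue_hi,
                 sat = sat, light = light), class = "hue_band")
}

# Unroll a band into non-wrapping half-open hue intervals [lo, hi + 1).
.band_intervals <- function(band) {
  hi <- band$hue_hi + 1
  if (band$hue_lo <= band$hue_hi) {
    matrix(c(band$hue_lo, hi), ncol = 2)
  } else {
    matrix(c(band$hue_lo, 360, 0, hi), ncol = 2, byrow = TRUE)
  }
}

#' Masson's trichrome band set: blue = total collagen
#'
#' Blue pixels (H 150-249 degrees, S 0-1, L 0.01-1) are classified as
#' collagen.
#' @return List of [hue_band()]s.
#' @export
mtc_bands <- function() {
  list(hue_band("blue", 150, 249, sat = c(0, 1), light = c(0.01, 1)))
}

#' Picrosirius-red birefringence band set
#'
#' Red (H 324-12, wrapping), orange (13-52), yellow (53-72) and green
#' (73-180) pixels, all with S 0.1-1 and L 0.1-0.93, grading collagen from
#' thick/mature (red) to thin/immature (green).
#' @return List of [hue_band()]s.
#' @export
psr_bands <- function() {
  s <- c(0.1, 1); l <- c(0.1, 0.93)
  list(hue_band("red", 324, 12, s, l),
       hue_band("orange", 13, 52, s, l),
       hue_band("yellow", 53, 72, s, l),
       hue_band("green", 73, 180, s, l))
}

#' Background mask for a stained section
#'
#' Background is saturated to uniform white in MTC images and black in PSR
#' images; pixels with lightness at or above `white_cutoff` (MTC) or at or
#' below `black_cutoff` (PSR) are background, the complement is tissue.
#'
#' @param img RGB array.
#' @param stain `"MTC"` or `"PSR"`.
#' @param white_cutoff,black_cutoff Lightness cutoffs (defaults 0.95 /
#'   0.05). Cutoffs of 1 and 0 disable masking.
#' @return Logical matrix, `TRUE` = tissue.
#' @export
mask_background <- function(img, stain = c("MTC", "PSR"),
                            white_cutoff = 0.95, black_cutoff = 0.05) {
  stain <- match.arg(stain)
  L <- rgb_to_hsl(img)$L
  tissue <- if (stain == "MTC") L < white_cutoff else L > black_cutoff
  if (!any(tissue)) {
    stop_mechisto("empty tissue mask: nothing to quantify",
                  "mechisto_domain_error")
  }
  tissue
}

#' Classify tissue pixels into hue bands and report area fractions
#'
#' Each tissue pixel is assigned to at most one band (bands must be
#' non-overlapping after wraparound unrolling); fractions are band pixels
#' over tissue pixels and need not sum to 1 (unclassified tissue is
#' allowed).
#'
#' @param img RGB array.
#' @param bands List of [hue_band()]s (e.g. [mtc_bands()], [psr_bands()]).
#' @param tissue Logical tissue mask from [mask_background()].
#' @return An object of class `area_fraction_report`: data frame with
#'   `band`, `pixels`, `fraction`, plus attributes `tissue_pixels`,
#'   `background_pixels`, `unclassified_fraction`.
#' @export
classify_and_fraction <- function(img, bands, tissue) {
  ivs <- lapply(bands, .band_intervals)
  flat <- do.call(rbind, ivs)
  if (nrow(flat) > 1) {
    o <- order(flat[, 1])
    so <- flat[o, , drop = FALSE]
    if (any(so[-nrow(so), 2] > so[-1, 1] + 1e-12)) {
      stop_mechisto("hue bands overlap after wraparound expansion",
                    "mechisto_config_error")
    }
  }
  hsl <- rgb_to_hsl(img)
  n_tissue <- sum(tissue)
  counts <- integer(length(bands))
  for (k in seq_along(bands)) {
    b <- bands[[k]]
    in_hue <- Reduce(`|`, lapply(seq_len(nrow(ivs[[k]])), function(i) {
      hsl$H >= ivs[[k]][i, 1] & hsl$H < ivs[[k]][i, 2]
    }))
    in_band <- in_hue & hsl$S >= b$sat[1] & hsl$S <= b$sat[2] &
      hsl$L >= b$light[1] & hsl$L <= b$light[2] & tissue
    counts[k] <- sum(in_band)
  }
  out <- data.frame(band = vapply(bands, `[[`, character(1), "name"),
                    pixels = counts, fraction = counts / n_tissue)
  attr(out, "tissue_pixels") <- n_tissue
  attr(out, "background_pixels") <- length(tissue) - n_tissue
  attr(out, "unclassified_fraction") <- 1 - sum(counts) / n_tissue
  class(out) <- c("area_fraction_report", "data.frame")
  out
}

#' Quantify a stained section end to end
#'
#' Reads the raster if given a path (PNG or TIFF), masks background and
#' reports per-band area fractions with the standard band set for the
#' stain.
#'
#' @param img RGB array, or path to a PNG/TIFF file.
#' @param stain `"MTC"` or `"PSR"`.
#' @param bands Band set override.
#' @param ... Passed to [mask_background()].
#' @return An `area_fraction_report`.
#' @export
quant_histology <- function(img, stain = c("MTC", "PSR"), bands = NULL, ...) {
  stain <- match.arg(stain)
  if (is.character(img)) img <- read_raster(img)
  bands <- bands %||% if (stain == "MTC") mtc_bands() else psr_bands()
  classify_and_fraction(img, bands, mask_background(img, stain, ...))
}

#' Read an RGB raster from PNG or TIFF
#' @param path File path (.png, .tif/.tiff).
#' @return Numeric array `h x w x 3` in [0, 1].
#' @export
read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
  } else {
    stop_mechisto("unsupported raster format (use PNG or TIFF)",
                  "mechisto_format_error")
  }
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  img
}
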