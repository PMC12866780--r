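px <- function(h, s, l) {
  # 1x1 RGB image from HSL
  array(hsl_to_rgb(h, s, l), dim = c(1, 1, 3))
}

test_that("RGB to HSL conversion handles primaries and achromatic pixels", {
  red <- array(c(1, 0, 0), dim = c(1, 1, 3))
  hsl <- rgb_to_hsl(red)
  expect_equal(c(hsl$H, hsl$S, hsl$L), c(0, 1, 0.5))

  white <- array(1, dim = c(1, 1, 3))
  hsl <- rgb_to_hsl(white)
  expect_equal(c(hsl$S, hsl$L), c(0, 1))

  blue <- array(c(0, 0, 1), dim = c(1, 1, 3))
  expect_equal(as.vector(rgb_to_hsl(blue)$H), 240)

  # 8-bit integer input is normalized
  expect_equal(as.vector(rgb_to_hsl(array(c(255, 0, 0), c(1, 1, 3)))$H), 0)
})

test_that("HSL to RGB inverts the forward conversion", {
  set.seed(71)
  h <- runif(200, 0, 360); s <- runif(200); l <- runif(200, 0.05, 0.95)
  rgb <- hsl_to_rgb(h, s, l)
  img <- array(rgb, dim = c(200, 1, 3))
  back <- rgb_to_hsl(img)
  chromatic <- s > 1e-6 & l > 1e-6 & l < 1 - 1e-6
  expect_equal(back$L[, 1], l, tolerance = 1e-12)
  expect_equal(back$S[, 1][chromatic], s[chromatic], tolerance = 1e-9)
  dh <- (back$H[, 1][chromatic] - h[chromatic]) %% 360
  expect_lt(max(pmin(dh, 360 - dh)), 1e-9)
})

test_that("background masking separates tissue at the lightness cutoffs", {
  all_white <- array(1, dim = c(8, 8, 3))
  expect_error(mask_background(all_white, "MTC"), "empty tissue")
  # disabled masking keeps every pixel
  expect_true(all(mask_background(all_white, "MTC", white_cutoff = 1.01)))

  g <- gen_stain_raster("MTC", c(blue = 0.6), size = 128, seed = 21)
  tissue <- mask_background(g$img, "MTC")
  # generator label map is the oracle for the tissue/background split
  expect_identical(sum(tissue), sum(g$labels != "background"))
  expect_equal(sum(g$labels != "background"), round(0.6 * 128^2))
})

test_that("hue-band classification respects wraparound and partitioning", {
  g <- gen_stain_raster("MTC", c(blue = 1), size = 64, seed = 3)
  rep <- quant_histology(g$img, "MTC", white_cutoff = 1.01)
  expect_equal(rep$fraction[rep$band == "blue"], 1)

  # H = 350 degrees falls in the wrapped red band of the PSR set
  rep2 <- classify_and_fraction(px(350, 0.5, 0.5), psr_bands(),
                                matrix(TRUE, 1, 1))
  expect_equal(rep2$fraction[rep2$band == "red"], 1)
  # printed integer boundaries partition: H = 12.5 is red, H = 13 is orange
  for (h in c(12.5, 12.99)) {
    r <- classify_and_fraction(px(h, 0.5, 0.5), psr_bands(), matrix(TRUE, 1, 1))
    expect_equal(r$fraction[r$band == "red"], 1)
  }
  r13 <- classify_and_fraction(px(13, 0.5, 0.5), psr_bands(), matrix(TRUE, 1, 1))
  expect_equal(r13$fraction[r13$band == "orange"], 1)

  overlapping <- list(hue_band("a", 10, 50), hue_band("b", 40, 80))
  expect_error(classify_and_fraction(px(20, .5, .5), overlapping,
                                     matrix(TRUE, 1, 1)), "overlap")
})

test_that("area fractions are exhaustive and geometry-invariant", {
  g <- gen_stain_raster("PSR", c(red = 0.3, orange = 0.2, yellow = 0.15,
                                 green = 0.15), size = 128, seed = 8)
  tissue <- mask_background(g$img, "PSR")
  rep0 <- classify_and_fraction(g$img, psr_bands(), tissue)
  # band fractions + unclassified sum to 1 over tissue, exactly
  expect_equal(sum(rep0$fraction) + attr(rep0, "unclassified_fraction"), 1)

  rot90 <- function(a) {
    out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
    for (ch in 1:3) out[, , ch] <- t(a[dim(a)[1]:1, , ch])
    out
  }
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  for (im in list(rot90(g$img), flip(g$img), aperm(g$img, c(2, 1, 3)))) {
    rep1 <- classify_and_fraction(im, psr_bands(), mask_background(im, "PSR"))
    expect_identical(rep1$fraction, rep0$fraction)
  }

  # nearest-neighbor upsampling leaves fractions unchanged
  up <- g$img[rep(1:128, each = 2), rep(1:128, each = 2), , drop = FALSE]
  rep2 <- classify_and_fraction(up, psr_bands(), mask_background(up, "PSR"))
  expect_equal(rep2$fraction, rep0$fraction)
})

test_that("stain rasters honor requested class fractions and determinism", {
  expect_error(gen_stain_raster("PSR", c(red = 0.7, green = 0.4)), "sum")
  expect_error(gen_stain_raster("MTC", c(magenta = 0.5)), "unknown class")

  g <- gen_stain_raster("PSR", c(red = 0.25, orange = 0.25, yellow = 0.25,
                                 green = 0.25), size = 256, seed = 12)
  rep <- quant_histology(g$img, "PSR")
  expect_true(all(abs(rep$fraction - 0.25) < 0.01))

  # same seed: byte-identical PNG artifacts
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_raster_png(gen_stain_raster("PSR", c(red = 0.5), 64, seed = 9)$img, p1)
  write_raster_png(gen_stain_raster("PSR", c(red = 0.5), 64, seed = 9)$img, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # PNG round trip preserves the 8-bit image
  expect_equal(read_raster(p1),
               gen_stain_raster("PSR", c(red = 0.5), 64, seed = 9)$img,
               tolerance = 1e-9)
})
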