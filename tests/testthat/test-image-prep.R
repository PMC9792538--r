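test_that("load_image min-max scales and handles constant images", {
  p <- write_png_tmp(matrix(c(0, 1, 1, 0), 2, 8))
  img <- load_image(p)
  expect_setequal(unique(as.numeric(img$pixels)), c(0, 1))

  p2 <- write_png_tmp(matrix(128 / 255, 4, 4))
  img2 <- load_image(p2)
  expect_true(all(img2$pixels == 0))
})

test_that("RGB with equal channels loads like the single plane", {
  m <- matrix(runif(64), 8, 8)
  arr <- array(rep(m, 3), dim = c(8, 8, 3))
  p_rgb <- write_png_tmp(arr)
  p_gray <- write_png_tmp(m)
  expect_equal(load_image(p_rgb)$pixels, load_image(p_gray)$pixels,
               tolerance = 1e-6)
})

test_that("load_image rejects missing files and unknown formats", {
  expect_error(load_image(file.path(tempdir(), "nope.png")), "does not exist")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", bad)
  expect_error(load_image(bad), "unsupported")
})

test_that("enhance honours identity settings and degenerate ranges", {
  m <- matrix(seq(0, 1, length.out = 64), 8, 8)
  img <- gray_image(m)
  out <- enhance(img, p_low = 0, p_high = 100, upsample = 1)
  expect_equal(out$pixels, m, tolerance = 1e-12)

  const <- gray_image(matrix(0.5, 8, 8))
  expect_equal(enhance(const)$pixels, const$pixels)
})

test_that("upsampling scales shape and pixel spacing", {
  img <- gray_image(matrix(runif(64 * 64), 64, 64), pixel_spacing = 0.5)
  out <- enhance(img, p_low = 0, p_high = 100, upsample = 2)
  expect_equal(dim(out$pixels), c(128, 128))
  expect_equal(out$pixel_spacing, 0.25)
  expect_error(enhance(img, upsample = 0), "positive")
  # bicubic interpolation reproduces a smooth column ramp closely
  ramp <- gray_image(matrix(rep(seq(0.1, 0.9, length.out = 64), each = 64), 64))
  up <- enhance(ramp, upsample = 2, stretch = FALSE)
  j <- 5:124
  expected <- 0.1 + 0.8 * (((j - 0.5) / 2 + 0.5) - 1) / 63
  expect_lt(max(abs(sweep(up$pixels[j, j], 2, expected))), 0.005)
})

test_that("Otsu separates a bimodal image; fixed thresholds are strict", {
  mask <- binarize(bimodal_image())
  expect_equal(sum(mask$pixels), 16 * 8)
  expect_true(all(mask$pixels[, 9:16] == 1))

  img <- gray_image(matrix(c(0.4, 0.6), 8, 8))
  m2 <- binarize(img, method = "fixed", threshold = 0.5)
  expect_equal(as.numeric(m2$pixels), rep(c(0, 1), 32))
  # strictness: a pixel exactly at the threshold is background
  m3 <- binarize(gray_image(matrix(c(0.5, 0.6), 8, 8)),
                 method = "fixed", threshold = 0.5)
  expect_equal(sum(m3$pixels), 32)
})

test_that("empty masks warn, carry a marker, and are rejected downstream", {
  img <- gray_image(matrix(0, 8, 8))
  expect_warning(mask <- binarize(img, method = "fixed", threshold = 0.5),
                 "empty")
  expect_true(is_empty_mask(mask))
  expect_error(apparent_area(mask), "non-empty")
  expect_error(measure_from_mask(mask), "empty")
})

test_that("fixed-threshold foreground count is non-increasing in t", {
  img <- gray_image(matrix(runif(256), 16, 16))
  counts <- vapply(seq(0, 1, by = 0.1), function(t) {
    suppressWarnings(sum(binarize(img, "fixed", t)$pixels))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("apparent area counts pixels times spacing squared", {
  m <- matrix(0L, 10, 10)
  m[sample(100, 37)] <- 1L
  mask <- structure(list(pixels = m, pixel_spacing = 1, threshold = 0.5,
                         method = "fixed"), class = "binary_mask")
  expect_equal(apparent_area(mask), 37)
  mask$pixel_spacing <- 0.5
  expect_equal(apparent_area(mask), 9.25)

  full <- structure(list(pixels = matrix(1L, 8, 8), pixel_spacing = 1,
                         threshold = 0, method = "fixed"),
                    class = "binary_mask")
  expect_equal(apparent_area(full), 64)
})

test_that("apparent area is invariant under foreground translation", {
  img <- gray_image(rbind(cbind(matrix(1, 6, 6), matrix(0, 6, 10)),
                          matrix(0, 10, 16)))
  shifted <- gray_image(rbind(matrix(0, 10, 16),
                              cbind(matrix(0, 6, 10), matrix(1, 6, 6))))
  a1 <- apparent_area(binarize(img, "fixed", 0.5))
  a2 <- apparent_area(binarize(shifted, "fixed", 0.5))
  expect_equal(a1, a2)
})

test_that("enhance then binarize is deterministic", {
  img <- gray_image(matrix(runif(256), 16, 16))
  m1 <- binarize(enhance(img, equalize = TRUE))
  m2 <- binarize(enhance(img, equalize = TRUE))
  expect_identical(m1$pixels, m2$pixels)
  expect_identical(m1$threshold, m2$threshold)
})

test_that("largest-component filter keeps only the biggest blob", {
  m <- matrix(0, 12, 12)
  m[2:6, 2:6] <- 1    # 25 px blob
  m[10:11, 10:11] <- 1 # 4 px blob
  img <- gray_image(m)
  mask <- binarize(img, "fixed", 0.5, keep_largest = TRUE)
  expect_equal(sum(mask$pixels), 25)
  expect_true(all(mask$pixels[10:11, 10:11] == 0))
})
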