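#' Grayscale image container
#'
#' A `gray_image` wraps a matrix of intensities in `[0, 1]` together with the
#' physical side length of one pixel. All downstream analysis (binarization,
#' box counting) works on this container; `pixel_spacing` only enters the
#' apparent-area feature, so with the default spacing of 1 areas are reported
#' in pixel^2 units.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param pixel_spacing Physical side length of one pixel (default 1).
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, pixel_spacing = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) == 0 || ncol(pixels) == 0) {
    abort("zero-sized image")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("image intensities must be finite")
  }
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12) {
    abort("image intensities must lie in [0, 1]")
  }
  .assert_scalar_number(pixel_spacing, "pixel_spacing", lower = 1e-300)
  structure(
    list(pixels = pmin(pmax(pixels, 0), 1), pixel_spacing = pixel_spacing),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, intensities [%.3f, %.3f], pixel spacing %g\n",
    nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
    x$pixel_spacing
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Rec. 709 luminance weights; they sum to 1 so an R=G=B image reduces to any
# single plane.
.luminance <- function(arr) {
  0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
}

#' Load a 2D image as a normalized grayscale matrix
#'
#' Reads PNG or TIFF directly (JPEG/BMP through EBImage when installed),
#' converts colour to luminance, and min-max scales intensities to `[0, 1]`.
#' A constant image maps to all zeros.
#'
#' @param path Path to a PNG/JPEG/TIFF/BMP file.
#' @param pixel_spacing Physical side length of one pixel (default 1).
#' @return A [gray_image()].
#' @export
load_image <- function(path, pixel_spacing = 1) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("cannot read image: '%s' does not exist", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = ,
    bmp = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        abort("reading JPEG/BMP requires the EBImage package")
      }
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores x (columns) first; transpose to row-major matrix form
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    },
    abort(sprintf("unsupported image format: '%s'", ext))
  )
  if (is.list(arr)) arr <- arr[[1L]]
  if (length(dim(arr)) == 3L) {
    arr <- if (dim(arr)[3] >= 3L) .luminance(arr) else arr[, , 1L]
  }
  if (!is.matrix(arr)) arr <- as.matrix(arr)
  if (nrow(arr) == 0 || ncol(arr) == 0) abort("zero-sized image")
  rng <- range(arr)
  arr <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
  gray_image(arr, pixel_spacing = pixel_spacing)
}

# Catmull-Rom cubic kernel (a = -0.5)
.cubic_kernel <- function(x) {
  x <- abs(x)
  w <- numeric(length(x))
  i1 <- x < 1
  i2 <- !i1 & x < 2
  w[i1] <- 1.5 * x[i1]^3 - 2.5 * x[i1]^2 + 1
  w[i2] <- -0.5 * x[i2]^3 + 2.5 * x[i2]^2 - 4 * x[i2] + 2
  w
}

# Separable bicubic resampling weight matrix mapping n input samples to
# n * factor output samples; borders are clamped and rows renormalized.
.resample_weights <- function(n, factor) {
  n_out <- n * factor
  centers <- (seq_len(n_out) - 0.5) / factor + 0.5 # input coords, 1-based centers
  w <- matrix(0, n_out, n)
  base <- floor(centers)
  for (tap in -1:2) {
    idx <- pmin(pmax(base + tap, 1L), n)
    wt <- .cubic_kernel(centers - (base + tap))
    w[cbind(seq_len(n_out), idx)] <- w[cbind(seq_len(n_out), idx)] + wt
  }
  w / rowSums(w)
}

#' Contrast/resolution enhancement
#'
#' Applies, in order: contrast stretching to the `[p_low, p_high]` intensity
#' percentiles, optional 256-bin histogram equalization, and optional integer
#' upsampling by bicubic (Catmull-Rom) interpolation. The output is re-clipped
#' to `[0, 1]` and `pixel_spacing` is divided by the upsampling factor.
#'
#' @param img A [gray_image()].
#' @param p_low,p_high Stretch percentiles in `[0, 100]` (defaults 1 and 99).
#' @param equalize Apply histogram equalization after the stretch?
#' @param upsample Integer upsampling factor (default 1 = none).
#' @param stretch Apply the percentile contrast stretch at all? Disable for
#'   images whose absolute gray levels are calibrated (e.g. the synthetic
#'   phantoms).
#' @return A [gray_image()].
#' @export
enhance <- function(img, p_low = 1, p_high = 99, equalize = FALSE,
                    upsample = 1, stretch = TRUE) {
  stopifnot(inherits(img, "gray_image"))
  .assert_scalar_number(p_low, "p_low", 0, 100)
  .assert_scalar_number(p_high, "p_high", 0, 100)
  if (p_high <= p_low) abort("`p_high` must exceed `p_low`")
  if (!is.numeric(upsample) || length(upsample) != 1L || upsample < 1 ||
      upsample != round(upsample)) {
    abort("`upsample` must be a positive whole number")
  }
  p <- img$pixels
  if (isTRUE(stretch)) {
    lo <- as.numeric(quantile(p, p_low / 100, names = FALSE))
    hi <- as.numeric(quantile(p, p_high / 100, names = FALSE))
    if (hi > lo) p <- (p - lo) / (hi - lo) # degenerate range: stretch is a no-op
  }
  p <- pmin(pmax(p, 0), 1)
  if (isTRUE(equalize)) {
    bins <- pmin(floor(p * 256), 255L) + 1L
    cdf <- cumsum(tabulate(bins, 256L)) / length(p)
    cdf0 <- cdf[cdf > 0][1L]
    p <- matrix(
      if (cdf0 < 1) (cdf[bins] - cdf0) / (1 - cdf0) else p[TRUE],
      nrow(p), ncol(p)
    )
    p <- pmin(pmax(p, 0), 1)
  }
  factor <- as.integer(upsample)
  if (factor > 1L) {
    wr <- .resample_weights(nrow(p), factor)
    wc <- .resample_weights(ncol(p), factor)
    p <- pmin(pmax(wr %*% p %*% t(wc), 0), 1)
  }
  gray_image(p, pixel_spacing = img$pixel_spacing / factor)
}

#' Otsu threshold on a 256-bin histogram
#'
#' @param pixels Numeric values in `[0, 1]`.
#' @return Threshold in `[0, 1]` (midpoint of the selected bin boundary);
#'   foreground is everything strictly above it.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.numeric(pixels)
  bins <- pmin(floor(v * 256), 255L) + 1L
  counts <- tabulate(bins, 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mids <- (seq_len(256L) - 0.5) / 256
  mu <- cumsum(p * mids)
  mu_t <- mu[256L]
  # between-class variance for a split after bin t
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  sigma_b[denom <= 0] <- -Inf
  t_bin <- which.max(sigma_b[-256L]) # split cannot be after the last bin
  t_bin / 256 # upper edge of the chosen bin
}

#' Binarize an image into a brain mask
#'
#' Foreground is every pixel strictly above the threshold (ties go to
#' background). The threshold is either Otsu's (256-bin histogram) or a fixed
#' value in `[0, 1]`. An empty foreground raises a warning and returns a mask
#' flagged empty, which downstream operations reject.
#'
#' @param img A [gray_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Fixed threshold in `[0, 1]` (required for
#'   `method = "fixed"`).
#' @param keep_largest Retain only the largest 4-connected foreground
#'   component (off by default).
#' @return A `binary_mask` object: 0/1 matrix plus the spacing and the
#'   threshold used.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     keep_largest = FALSE) {
  stopifnot(inherits(img, "gray_image"))
  method <- match.arg(method)
  t <- if (method == "otsu") {
    otsu_threshold(img$pixels)
  } else {
    if (is.null(threshold)) abort("`threshold` is required for method 'fixed'")
    .assert_scalar_number(threshold, "threshold", 0, 1)
    threshold
  }
  m <- (img$pixels > t) * 1L
  storage.mode(m) <- "integer"
  if (isTRUE(keep_largest) && sum(m) > 0) m <- .largest_component(m)
  if (sum(m) == 0) {
    warn("binarize produced an empty mask")
  }
  structure(
    list(pixels = m, pixel_spacing = img$pixel_spacing, threshold = t,
         method = method),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d, %d foreground pixels (threshold %.4f, %s)\n",
    nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$threshold, x$method
  ))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' Is a mask empty (no foreground)?
#' @param mask A `binary_mask`.
#' @export
is_empty_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$pixels) == 0L
}

# 4-connected component labelling by iterative label propagation; adequate for
# the image sizes this package targets and dependency-free.
.largest_component <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m == 1L] <- seq_len(sum(m))
  repeat {
    nb <- lab
    nb[-1, ] <- pmax(nb[-1, ], lab[-nrow(lab), ])
    nb[-nrow(lab), ] <- pmax(nb[-nrow(lab), ], lab[-1, ])
    nb[, -1] <- pmax(nb[, -1], lab[, -ncol(lab)])
    nb[, -ncol(lab)] <- pmax(nb[, -ncol(lab)], lab[, -1])
    nb[m == 0L] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  counts <- table(lab[lab > 0L])
  keep <- as.integer(names(counts)[which.max(counts)])
  out <- (lab == keep) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Apparent section area
#'
#' The apparent area of the (brain) section: foreground pixel count times
#' `pixel_spacing^2`. Units follow the spacing supplied at load time; with the
#' default spacing of 1 the area is in pixel^2.
#'
#' @param mask A non-empty `binary_mask`.
#' @return Area (squared length units).
#' @export
apparent_area <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is_empty_mask(mask)) abort("apparent_area requires a non-empty mask")
  sum(mask$pixels) * mask$pixel_spacing^2
}
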