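#' Canonical feature order
#'
#' The fixed serialization order of the ten multifractal features: information
#' dimension, correlation dimension, alpha at q = 0, the alpha extrema with
#' their f values, spectrum width, symmetry shift, and apparent area.
#'
#' @export
mf_feature_names <- c(
  "d1", "d2", "alpha0", "alpha_min", "f_alpha_min",
  "alpha_max", "f_alpha_max", "width", "shift", "area"
)

#' Singularity-spectrum width
#'
#' `W = alpha_max - alpha_min`, the spread of Hoelder exponents present in the
#' measure; broad spectra indicate strong multifractality (heterogeneous
#' structure, many gap sizes).
#'
#' @param alpha_min,alpha_max Spectrum endpoints.
#' @return Width (same units as alpha).
#' @export
spectrum_width <- function(alpha_min, alpha_max) alpha_max - alpha_min

#' Symmetry shift of the singularity spectrum
#'
#' Distance of the spectrum apex `alpha_0` from the midpoint of the alpha
#' range: `|alpha_0 - (alpha_min + alpha_max) / 2|`. A symmetric spectrum has
#' shift 0; atrophic, heterogeneous sections shift the apex toward
#' `alpha_min`.
#'
#' @param alpha0 Hoelder exponent at q = 0 (spectrum apex).
#' @param alpha_min,alpha_max Spectrum endpoints.
#' @return Nonnegative shift.
#' @export
symmetry_shift <- function(alpha0, alpha_min, alpha_max) {
  abs(alpha0 - (alpha_min + alpha_max) / 2)
}

#' Extract the ten-feature multifractal signature
#'
#' Reduces the generalized-dimension and singularity spectra plus the apparent
#' section area to the ten features used for staging. The alpha extrema are
#' located over the moment grid (ties broken toward larger `|q|`), and their
#' `f(alpha)` values are read at the achieving moment orders.
#'
#' @param gen An `mf_genspec` (or an `mf_spectrum`, in which case `sing` is
#'   taken from it).
#' @param sing An `mf_singularity` on the same moment grid.
#' @param area Apparent section area (> 0), from [apparent_area()].
#' @param image_id Optional identifier prepended as a column.
#' @return A one-row tibble with columns [mf_feature_names] (preceded by
#'   `image_id` when supplied).
#' @export
extract_features <- function(gen, sing = NULL, area, image_id = NULL) {
  if (inherits(gen, "mf_spectrum")) {
    sing <- gen$singularity
    gen <- gen$dimensions
  }
  stopifnot(inherits(gen, "mf_genspec"), inherits(sing, "mf_singularity"))
  if (!isTRUE(all.equal(gen$q, sing$q, tolerance = 1e-9))) {
    abort("the two spectra must share one moment grid")
  }
  .assert_scalar_number(area, "area", lower = 1e-300)
  if (any(!is.finite(gen$Dq)) || any(!is.finite(sing$alpha)) ||
      any(!is.finite(sing$f_alpha))) {
    abort("non-finite spectrum values")
  }
  nd <- named_dimensions(gen)
  i0 <- which(abs(sing$q - 0) < 1e-9)
  if (length(i0) != 1) abort("q = 0 absent from the moment grid")
  alpha0 <- sing$alpha[i0]

  pick_extremum <- function(target) {
    idx <- which(abs(sing$alpha - target) < 1e-12)
    idx[which.max(abs(sing$q[idx]))] # tie toward larger |q|
  }
  imin <- pick_extremum(min(sing$alpha))
  imax <- pick_extremum(max(sing$alpha))

  out <- tibble(
    d1 = nd[["D1"]],
    d2 = nd[["D2"]],
    alpha0 = alpha0,
    alpha_min = sing$alpha[imin],
    f_alpha_min = sing$f_alpha[imin],
    alpha_max = sing$alpha[imax],
    f_alpha_max = sing$f_alpha[imax],
    width = spectrum_width(sing$alpha[imin], sing$alpha[imax]),
    shift = symmetry_shift(alpha0, sing$alpha[imin], sing$alpha[imax]),
    area = area
  )
  if (!is.null(image_id)) {
    out <- dplyr::bind_cols(tibble(image_id = as.character(image_id)), out)
  }
  out
}

#' Per-image feature pipeline
#'
#' Load (or accept) an image, enhance, binarize, build the mask measure,
#' estimate both spectra and emit the ten-feature row. This is the unit of
#' work behind [pipeline_extract()].
#'
#' @param image A file path or a [gray_image()].
#' @param config A [default_config()]-style list.
#' @param image_id Identifier for the output row (defaults to the file name).
#' @return One-row feature tibble.
#' @export
image_features <- function(image, config = default_config(), image_id = NULL) {
  if (is.character(image)) {
    image_id <- image_id %||% basename(image)
    image <- load_image(image, pixel_spacing = config$pixel_spacing)
  }
  stopifnot(inherits(image, "gray_image"))
  img <- enhance(
    image,
    p_low = config$enhance$p_low, p_high = config$enhance$p_high,
    equalize = config$enhance$equalize, upsample = config$enhance$upsample,
    stretch = config$enhance$stretch
  )
  mask <- binarize(
    img,
    method = config$binarize$method, threshold = config$binarize$threshold,
    keep_largest = config$binarize$keep_largest
  )
  if (is_empty_mask(mask)) abort("empty mask: no foreground to analyse")
  measure <- if (identical(config$measure, "gray")) {
    measure_from_gray(img)
  } else {
    measure_from_mask(mask)
  }
  q <- default_q_grid(config$q$min, config$q$max, config$q$step)
  fit_range <- if (!is.null(config$fit$min_scale)) {
    c(config$fit$min_scale, config$fit$max_scale)
  }
  spec <- mf_spectrum(
    measure, scales = config$scales, q = q,
    fit_range = fit_range, r2_warn = config$fit$r2_warn,
    offsets = config$offsets
  )
  message(sprintf(
    "[%s] threshold %.4f (%s); fit R^2 in [%.4f, %.4f]",
    image_id %||% "image", mask$threshold, mask$method,
    min(spec$dimensions$r_squared), max(spec$dimensions$r_squared)
  ))
  extract_features(spec, area = apparent_area(mask), image_id = image_id)
}
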