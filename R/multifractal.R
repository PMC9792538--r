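#' Default moment-order grid
#'
#' Uniformly spaced moment orders from `q_min` to `q_max`; the grid must
#' contain 0, 1 and 2 so the capacity, information and correlation dimensions
#' are always available.
#'
#' @param q_min,q_max,q_step Grid limits and spacing (defaults -5, 5, 0.25).
#' @return Numeric vector of moment orders.
#' @export
default_q_grid <- function(q_min = -5, q_max = 5, q_step = 0.25) {
  q <- seq(q_min, q_max, by = q_step)
  q <- round(q / q_step) * q_step # kill accumulation error so 0/1/2 are exact
  for (must in c(0, 1, 2)) {
    if (!any(abs(q - must) < 1e-9)) {
      abort(sprintf("q grid must contain %g", must))
    }
  }
  q
}

#' Default box scales for an image
#'
#' Dyadic box sides `2, 4, 8, ...` up to a quarter of the smaller image
#' dimension.
#'
#' @param dims Integer vector `c(height, width)` (or anything `min()` accepts).
#' @return Integer vector of box sides.
#' @export
default_scales <- function(dims) {
  top <- floor(min(dims) / 4)
  if (top < 2) abort("image too small for box counting (need min dim >= 8)")
  2L^(1:floor(log2(top)))
}

#' Normalized measure from a binary mask
#'
#' The mass distribution analysed by box counting: each foreground pixel
#' carries equal mass `1 / n_foreground`.
#'
#' @param mask A non-empty `binary_mask`.
#' @return A numeric matrix summing to 1.
#' @export
measure_from_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is_empty_mask(mask)) abort("cannot build a measure from an empty mask")
  mask$pixels / sum(mask$pixels)
}

#' Normalized measure from grayscale intensities
#'
#' Alternative to [measure_from_mask()]: mass proportional to pixel intensity.
#'
#' @param img A [gray_image()] with positive total intensity.
#' @return A numeric matrix summing to 1.
#' @export
measure_from_gray <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  tot <- sum(img$pixels)
  if (tot <= 0) abort("cannot build a measure from an all-zero image")
  img$pixels / tot
}

.validate_measure <- function(mass) {
  if (!is.matrix(mass) || !is.numeric(mass)) {
    abort("a measure must be a numeric matrix")
  }
  if (min(mass) < -1e-12) abort("a measure cannot carry negative mass")
  if (abs(sum(mass) - 1) > 1e-9) abort("measure mass must sum to 1")
  invisible(mass)
}

# sum the mass matrix over an r x r box grid anchored at the top-left corner
# (optionally shifted by a zero-mass margin), zero-padding so both dimensions
# are multiples of r
.block_sums <- function(m, r, dx = 0, dy = 0) {
  if (dx > 0 || dy > 0) {
    mm <- matrix(0, nrow(m) + dx, ncol(m) + dy)
    mm[dx + seq_len(nrow(m)), dy + seq_len(ncol(m))] <- m
    m <- mm
  }
  nr <- ceiling(nrow(m) / r) * r
  nc <- ceiling(ncol(m) / r) * r
  if (nr != nrow(m) || nc != ncol(m)) {
    mm <- matrix(0, nr, nc)
    mm[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    m <- mm
  }
  g <- rowsum.default(m, rep(seq_len(nr / r), each = r))
  t(rowsum.default(t(g), rep(seq_len(nc / r), each = r)))
}

#' Box-counting scale table
#'
#' Partitions a measure with grids of box side `r` (anchored at the top-left
#' corner, zero-padded) and records, per scale, the occupied-box count, the
#' entropy sum over box probabilities, and the log moment sums
#' `ln sum_i P_i(r)^q` for every moment order. Boxes with probability below
#' `1e-12` are treated as empty, which keeps negative-order moments finite.
#'
#' @param measure Numeric matrix of nonnegative mass summing to 1.
#' @param scales Integer box sides (default [default_scales()]).
#' @param q Moment orders (default [default_q_grid()]).
#' @param offsets Number of grid placements to average per scale (default 1 =
#'   the anchored grid only). With `offsets = n`, the log moment sums, box
#'   counts and entropies are averaged over `n` diagonal grid shifts evenly
#'   spaced in `[0, r)`, which damps the sensitivity of negative-order
#'   moments to a single unluckily placed box.
#' @return A tibble of class `mf_scale_table` with columns `scale`, `q`,
#'   `log_moment`, and attributes `scale_summary` (tibble `scale`, `n_boxes`,
#'   `entropy` where entropy is `sum P ln P`), `q_grid`, and `dims`.
#' @export
box_partition <- function(measure, scales = NULL, q = default_q_grid(),
                          offsets = 1) {
  .validate_measure(measure)
  scales <- scales %||% default_scales(dim(measure))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) == 0 || any(scales < 1)) {
    abort("scales must be positive integers")
  }
  if (max(scales) > min(dim(measure))) {
    abort("largest scale exceeds the image size")
  }
  if (offsets < 1 || offsets != round(offsets)) {
    abort("`offsets` must be a positive whole number")
  }
  per_scale <- purrr::map(scales, function(r) {
    shifts <- unique(floor(r * (seq_len(offsets) - 1) / offsets))
    per_offset <- purrr::map(shifts, function(d) {
      pmat <- .block_sums(measure, r, d, d)
      p <- pmat[pmat > 1e-12]
      if (length(p) == 0) abort(sprintf("no occupied boxes at scale %d", r))
      logp <- log(p)
      # sum_i P_i^q for all q at once; computed in log space per box
      list(
        n_boxes = length(p),
        entropy = sum(p * logp),
        log_moment = log(colSums(exp(outer(logp, q))))
      )
    })
    list(
      n_boxes = as.integer(round(mean(purrr::map_int(per_offset, "n_boxes")))),
      entropy = mean(purrr::map_dbl(per_offset, "entropy")),
      log_moment = rowMeans(
        do.call(cbind, purrr::map(per_offset, "log_moment"))
      )
    )
  })
  tbl <- tidyr::expand_grid(scale = scales, q = q)
  tbl$log_moment <- unlist(purrr::map(per_scale, "log_moment"))
  tbl <- tibble::new_tibble(tbl, class = "mf_scale_table")
  attr(tbl, "scale_summary") <- tibble(
    scale = scales,
    n_boxes = purrr::map_int(per_scale, "n_boxes"),
    entropy = purrr::map_dbl(per_scale, "entropy")
  )
  attr(tbl, "q_grid") <- q
  attr(tbl, "dims") <- dim(measure)
  tbl
}

#' Generalized dimensions by log-log regression
#'
#' For each moment order `q != 1`, `D_q` is the slope of the ordinary
#' least-squares fit of `ln sum_i P_i(r)^q` against `ln r`, divided by
#' `(q - 1)`. The information dimension `D_1` is the slope of
#' `sum_i P_i(r) ln P_i(r)` against `ln r`. Per-order fit diagnostics
#' (slope, intercept, R^2) are reported, with a warning when any R^2 falls
#' below `r2_warn`.
#'
#' @param table An `mf_scale_table` from [box_partition()].
#' @param fit_range Optional `c(min_scale, max_scale)` restricting the scales
#'   used in the fits; at least 3 scales must remain.
#' @param r2_warn Warn when any per-order R^2 is below this value
#'   (default 0.98); set to 0 to silence.
#' @return A tibble of class `mf_genspec` with columns `q`, `Dq`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
generalized_dimensions <- function(table, fit_range = NULL, r2_warn = 0.98) {
  stopifnot(inherits(table, "mf_scale_table"))
  summ <- attr(table, "scale_summary")
  q_grid <- attr(table, "q_grid")
  keep <- summ$scale
  if (!is.null(fit_range)) {
    keep <- keep[keep >= fit_range[1] & keep <= fit_range[2]]
  }
  if (length(keep) < 3) abort("need at least 3 scales within the fit range")
  log_r <- log(keep)
  summ_k <- summ[summ$scale %in% keep, ]
  rows <- purrr::map(q_grid, function(qq) {
    if (abs(qq - 1) < 1e-9) {
      fit <- .ols(log_r, summ_k$entropy)
      dq <- fit$slope
    } else {
      y <- table$log_moment[abs(table$q - qq) < 1e-9 & table$scale %in% keep]
      fit <- .ols(log_r, y)
      dq <- fit$slope / (qq - 1)
    }
    tibble(q = qq, Dq = dq, slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared)
  })
  out <- dplyr::bind_rows(rows)
  if (r2_warn > 0 && any(out$r_squared < r2_warn)) {
    warn(sprintf(
      "scaling fit quality below %.2f for %d moment order(s) (min R^2 %.4f)",
      r2_warn, sum(out$r_squared < r2_warn), min(out$r_squared)
    ))
  }
  tibble::new_tibble(out, class = "mf_genspec")
}

#' Named dimensions from a generalized spectrum
#'
#' @param spec An `mf_genspec`.
#' @return Named vector with `D0` (capacity), `D1` (information) and `D2`
#'   (correlation) dimensions.
#' @export
named_dimensions <- function(spec) {
  stopifnot(inherits(spec, "mf_genspec"))
  pick <- function(qq) {
    i <- which(abs(spec$q - qq) < 1e-9)
    if (length(i) != 1) abort(sprintf("q = %g absent from the spectrum", qq))
    spec$Dq[i]
  }
  c(D0 = pick(0), D1 = pick(1), D2 = pick(2))
}

#' Mass exponent tau(q)
#'
#' `tau(q) = (q - 1) D_q`, the convention under which the Legendre pair
#' `alpha = dtau/dq`, `f = q alpha - tau` holds; `tau(1) = 0` exactly.
#'
#' @param spec An `mf_genspec`.
#' @return A tibble of class `mf_tau` with columns `q`, `Dq`, `tau`.
#' @export
mass_exponent <- function(spec) {
  stopifnot(inherits(spec, "mf_genspec"))
  tau <- (spec$q - 1) * spec$Dq
  tau[abs(spec$q - 1) < 1e-9] <- 0
  tibble::new_tibble(
    tibble(q = spec$q, Dq = spec$Dq, tau = tau),
    class = "mf_tau"
  )
}

#' Singularity spectrum by Legendre transform
#'
#' The Hoelder exponent `alpha(q)` is the derivative of `tau(q)`, taken by
#' central finite differences on the uniform moment grid (one-sided at the two
#' ends); `f(alpha) = q alpha(q) - tau(q)`.
#'
#' @param tau An `mf_tau` from [mass_exponent()], on a uniformly spaced grid of
#'   at least 5 moment orders.
#' @return A tibble of class `mf_singularity` with columns `q`, `tau`,
#'   `alpha`, `f_alpha`.
#' @export
legendre_spectrum <- function(tau) {
  stopifnot(inherits(tau, "mf_tau"))
  q <- tau$q
  if (length(q) < 5) abort("need at least 5 moment orders")
  h <- diff(q)
  if (max(h) - min(h) > 1e-8) abort("moment grid must be uniformly spaced")
  h <- mean(h)
  n <- length(q)
  t_ <- tau$tau
  alpha <- c(
    (t_[2] - t_[1]) / h,
    (t_[3:n] - t_[1:(n - 2)]) / (2 * h),
    (t_[n] - t_[n - 1]) / h
  )
  tibble::new_tibble(
    tibble(q = q, tau = t_, alpha = alpha, f_alpha = q * alpha - t_),
    class = "mf_singularity"
  )
}

#' Full multifractal spectrum of a measure
#'
#' Convenience wrapper running [box_partition()],
#' [generalized_dimensions()], [mass_exponent()] and [legendre_spectrum()].
#'
#' @inheritParams box_partition
#' @inheritParams generalized_dimensions
#' @return An object of class `mf_spectrum`: list with elements `dimensions`
#'   (`mf_genspec`) and `singularity` (`mf_singularity`).
#' @export
mf_spectrum <- function(measure, scales = NULL, q = default_q_grid(),
                        fit_range = NULL, r2_warn = 0.98, offsets = 1) {
  tbl <- box_partition(measure, scales = scales, q = q, offsets = offsets)
  gen <- generalized_dimensions(tbl, fit_range = fit_range, r2_warn = r2_warn)
  sing <- legendre_spectrum(mass_exponent(gen))
  structure(list(dimensions = gen, singularity = sing), class = "mf_spectrum")
}

#' @export
print.mf_spectrum <- function(x, ...) {
  nd <- named_dimensions(x$dimensions)
  cat(sprintf(
    "<mf_spectrum> %d moment orders; D0 = %.4f, D1 = %.4f, D2 = %.4f\n",
    nrow(x$dimensions), nd["D0"], nd["D1"], nd["D2"]
  ))
  cat(sprintf(
    "  alpha range [%.4f, %.4f] over the moment grid\n",
    min(x$singularity$alpha), max(x$singularity$alpha)
  ))
  invisible(x)
}

#' @rdname mf_spectrum
#' @param x An `mf_spectrum`.
#' @param ... Unused.
#' @export
tidy.mf_spectrum <- function(x, ...) {
  dplyr::left_join(
    as_tibble(x$dimensions),
    as_tibble(x$singularity),
    by = "q"
  )
}

#' @rdname mf_spectrum
#' @export
glance.mf_spectrum <- function(x, ...) {
  nd <- named_dimensions(x$dimensions)
  tibble(
    D0 = nd[["D0"]], D1 = nd[["D1"]], D2 = nd[["D2"]],
    alpha_min = min(x$singularity$alpha),
    alpha_max = max(x$singularity$alpha),
    min_r_squared = min(x$dimensions$r_squared)
  )
}
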