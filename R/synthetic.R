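#' Deterministic or shuffled 2D multiplicative cascade
#'
#' Recursive quadrant subdivision of unit mass: at each of `depth` levels,
#' every cell splits into 2x2 children whose masses are the parent mass times
#' the four `weights`. With `shuffle = TRUE` the quadrant assignment is a
#' seeded independent permutation per cell (a statistically self-similar
#' cascade); otherwise the assignment is fixed. Cascades have closed-form
#' multifractal spectra ([cascade_closed_form()]) and serve as the analytic
#' oracle for the box-counting estimator.
#'
#' @param weights Four nonnegative quadrant weights summing to 1.
#' @param depth Recursion depth `k >= 1`; the grid side is `2^k`.
#' @param shuffle Randomize quadrant assignment per cell?
#' @param seed Seed for the shuffled variant.
#' @param max_side Guard against accidental huge grids (default 4096).
#' @return A `2^depth` square matrix of nonnegative mass summing to 1.
#' @export
cascade_measure <- function(weights, depth, shuffle = FALSE, seed = 1,
                            max_side = 4096) {
  if (length(weights) != 4 || any(weights < 0)) {
    abort("`weights` must be 4 nonnegative numbers")
  }
  if (abs(sum(weights) - 1) > 1e-12) abort("`weights` must sum to 1")
  if (depth < 1 || depth != round(depth)) {
    abort("`depth` must be a positive whole number")
  }
  if (2^depth > max_side) {
    abort(sprintf("grid side 2^%d exceeds the cap of %d", depth, max_side))
  }
  build <- function() {
    m <- matrix(1, 1, 1)
    for (level in seq_len(depth)) {
      s <- nrow(m)
      if (shuffle) {
        perms <- matrix(
          apply(matrix(runif(4 * s^2), 4), 2, order),
          nrow = 4
        )
        w <- matrix(0, 2 * s, 2 * s)
        # block (i, j) of the weight mask receives a permuted weight quadruple
        odd_r <- rep(seq(1, 2 * s, by = 2), times = s)
        odd_c <- rep(seq(1, 2 * s, by = 2), each = s)
        w[cbind(odd_r, odd_c)] <- weights[perms[1, ]]
        w[cbind(odd_r, odd_c + 1)] <- weights[perms[2, ]]
        w[cbind(odd_r + 1, odd_c)] <- weights[perms[3, ]]
        w[cbind(odd_r + 1, odd_c + 1)] <- weights[perms[4, ]]
        m <- m[rep(seq_len(s), each = 2), rep(seq_len(s), each = 2)] * w
      } else {
        m <- kronecker(m, matrix(weights, 2, 2))
      }
    }
    m
  }
  m <- if (shuffle) withr::with_seed(seed, build()) else build()
  m / sum(m)
}

#' Closed-form cascade spectra
#'
#' Analytic generalized dimensions and singularity spectrum of a quadrant
#' cascade with the given weights: `D_q = log2(sum p_i^q) / (1 - q)` with the
#' Shannon limit `D_1 = -sum p_i log2 p_i` at `q = 1`;
#' `tau = (q - 1) D_q`; `alpha = -sum p_i^q log2 p_i / sum p_i^q`;
#' `f = q alpha - tau`. Zero weights are excluded from all sums.
#'
#' @param weights Four nonnegative quadrant weights summing to 1.
#' @param q Moment orders (default [default_q_grid()]).
#' @return A tibble: `q`, `Dq`, `tau`, `alpha`, `f_alpha`.
#' @export
cascade_closed_form <- function(weights, q = default_q_grid()) {
  if (any(weights < 0)) abort("`weights` must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) abort("`weights` must sum to 1")
  p <- weights[weights > 0]
  rows <- purrr::map(q, function(qq) {
    pq <- p^qq
    dq <- if (abs(qq - 1) < 1e-9) {
      -sum(p * log2(p))
    } else {
      log2(sum(pq)) / (1 - qq)
    }
    alpha <- -sum(pq * log2(p)) / sum(pq)
    tau <- (qq - 1) * dq
    tibble(q = qq, Dq = dq, tau = tau, alpha = alpha,
           f_alpha = qq * alpha - tau)
  })
  dplyr::bind_rows(rows)
}

#' Stage profile for the synthetic brain phantom
#'
#' The phantom is a purely synthetic construction (not anatomical): a bright
#' noisy tissue disk on a mid-gray background with dark elliptical "fluid"
#' gaps punched inside. Across stages the disk shrinks while the gaps grow in
#' number, size and darkness, emulating progressive atrophy with expanding
#' fluid-filled spaces: the apparent area falls with stage, and the growing
#' population of low-intensity gap regions pulls the negative-moment branch
#' of the grayscale singularity spectrum up, so the spectrum width rises with
#' stage. The background sits at an intermediate gray so the section's outer
#' rim does not compete with the gaps for the rarefied branch of the
#' spectrum.
#'
#' @param n_stages Number of stages (default 4).
#' @return A tibble with one row per stage: `stage` (0-based index),
#'   `radius_frac` (disk radius as a fraction of the image side),
#'   `n_gaps`, `gap_meanlog`, `gap_sdlog` (log-normal semi-axis distribution,
#'   pixels), `gap_intensity` (gray level inside gaps, darkening with stage),
#'   `fg_intensity`, `bg_intensity`, `noise_sd` (Gaussian intensity noise).
#' @export
stage_phantom_profile <- function(n_stages = 4) {
  if (n_stages < 1 || n_stages > 4) abort("`n_stages` must be 1..4")
  tibble(
    stage = 0:3,
    radius_frac = c(0.42, 0.39, 0.36, 0.33),
    n_gaps = c(0L, 18L, 40L, 70L),
    gap_meanlog = log(c(3.0, 3.3, 3.6, 4.0)),
    gap_sdlog = 0.35,
    gap_intensity = c(0.15, 0.15, 0.10, 0.06),
    fg_intensity = 0.8,
    bg_intensity = 0.45,
    noise_sd = 0.025
  )[seq_len(n_stages), ]
}

#' Synthetic stage-parameterized brain phantom image
#'
#' Draws one phantom for the requested stage of a profile (see
#' [stage_phantom_profile()]). Fully seeded: identical inputs give identical
#' images.
#'
#' @param stage Stage index (0-based row of `profile`).
#' @param seed Integer seed.
#' @param profile Profile tibble (default [stage_phantom_profile()]).
#' @param side Image side in pixels (default 256).
#' @return A [gray_image()].
#' @export
brain_phantom <- function(stage, seed = 1, profile = stage_phantom_profile(),
                          side = 256) {
  row <- profile[profile$stage == stage, ]
  if (nrow(row) != 1) abort(sprintf("stage %s not in the profile", stage))
  radius <- row$radius_frac * side
  exp_gap_area <- row$n_gaps * pi * exp(2 * row$gap_meanlog + row$gap_sdlog^2)
  if (exp_gap_area > 0.9 * pi * radius^2) {
    abort("expected gap area exceeds the disk area")
  }
  withr::with_seed(seed, {
    cx <- side / 2
    cy <- side / 2
    xs <- matrix(rep(seq_len(side), each = side), side)
    ys <- matrix(rep(seq_len(side), times = side), side)
    inside <- (xs - cx)^2 + (ys - cy)^2 <= radius^2
    img <- matrix(row$bg_intensity, side, side)
    img[inside] <- row$fg_intensity
    if (row$n_gaps > 0) {
      for (g in seq_len(row$n_gaps)) {
        # uniform position within the disk
        rr <- radius * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        gx <- cx + rr * cos(th)
        gy <- cy + rr * sin(th)
        a <- stats::rlnorm(1, row$gap_meanlog, row$gap_sdlog)
        b <- stats::rlnorm(1, row$gap_meanlog, row$gap_sdlog)
        phi <- runif(1, 0, pi)
        dx <- xs - gx
        dy <- ys - gy
        u <- dx * cos(phi) + dy * sin(phi)
        v <- -dx * sin(phi) + dy * cos(phi)
        img[(u / a)^2 + (v / b)^2 <= 1] <- row$gap_intensity
      }
    }
    img <- img + rnorm(side^2, 0, row$noise_sd)
    gray_image(pmin(pmax(img, 0), 1))
  })
}

#' Reference per-stage feature distribution parameters
#'
#' The per-stage mean and SD of each of the ten features for the two staging
#' schemes the package supports: the 4-stage `"kaggle"` scheme (no_dementia,
#' very_mild, mild, moderate) and the 3-stage `"adni"` scheme (CN, MCI, AD).
#' These parameters drive [sample_feature_table()].
#'
#' @param scheme `"kaggle"` or `"adni"`.
#' @return A tibble: `scheme`, `stage` (factor, stage-ordered), `feature`,
#'   `mean`, `sd`.
#' @export
stage_profiles <- function(scheme = c("kaggle", "adni")) {
  scheme <- match.arg(scheme)
  path <- system.file("extdata", "stage_profiles.csv",
                      package = "fractalstage", mustWork = TRUE)
  tab <- suppressMessages(readr::read_csv(path, show_col_types = FALSE))
  tab <- tab[tab$scheme == scheme, ]
  tab$stage <- factor(tab$stage, levels = unique(tab$stage))
  as_tibble(tab)
}

#' Sample a labeled Gaussian feature table
#'
#' Draws `n_per_stage` feature vectors per stage from independent Gaussians
#' with the per-stage means and SDs of [stage_profiles()] (feature
#' correlations are not modelled). Used as the classifier test-bed.
#'
#' @param scheme `"kaggle"` or `"adni"`.
#' @param n_per_stage Rows per stage (default 140).
#' @param seed Integer seed.
#' @return A tibble: `stage` (factor) plus the ten feature columns in
#'   [mf_feature_names] order.
#' @export
sample_feature_table <- function(scheme = c("kaggle", "adni"),
                                 n_per_stage = 140, seed = 1) {
  scheme <- match.arg(scheme)
  if (n_per_stage < 1) abort("`n_per_stage` must be at least 1")
  pars <- stage_profiles(scheme)
  stages <- levels(pars$stage)
  withr::with_seed(seed, {
    dplyr::bind_rows(purrr::map(stages, function(st) {
      p <- pars[pars$stage == st, ]
      draws <- purrr::map(mf_feature_names, function(f) {
        row <- p[p$feature == f, ]
        rnorm(n_per_stage, row$mean, row$sd)
      })
      names(draws) <- mf_feature_names
      dplyr::bind_cols(
        tibble(stage = factor(rep(st, n_per_stage), levels = stages)),
        as_tibble(draws)
      )
    }))
  })
}
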