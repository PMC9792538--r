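#' One-way ANOVA for a grouped feature
#'
#' Classical between/within mean-square F ratio with its p-value from the F
#' distribution on `(k - 1, N - k)` degrees of freedom, computed through
#' `stats::aov`. When both the between- and within-group variances are zero
#' the statistic is undefined and reported as `NA` with a warning.
#'
#' @param data Data frame with one value column and one grouping column.
#' @param value,group Column names (strings; defaults `"value"`, `"stage"`).
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
one_way_anova <- function(data, value = "value", group = "stage") {
  data <- as_tibble(data)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 3)) abort("each group needs at least 3 values")
  if (var(v) < 1e-300) {
    warn("ANOVA undefined: zero variance within and between groups")
    return(tibble(f_statistic = NA_real_, df_between = nlevels(g) - 1,
                  df_within = length(v) - nlevels(g), p_value = NA_real_))
  }
  fit <- stats::aov(v ~ g)
  tab <- summary(fit)[[1]]
  tibble(
    f_statistic = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Sample skewness and excess kurtosis
#'
#' Fisher definitions via `e1071` (moment type 1): `g1 = m3 / m2^(3/2)` and
#' `g2 = m4 / m2^2 - 3`, so a normal distribution has both near 0 and the
#' conventional normality band of -2 to +2 applies directly.
#'
#' @param values Numeric vector, `n >= 4`, nonzero variance.
#' @return A one-row tibble: `skewness`, `kurtosis`.
#' @export
moments <- function(values) {
  if (length(values) < 4) abort("need at least 4 values")
  if (var(values) < 1e-300) abort("zero variance")
  tibble(
    skewness = e1071::skewness(values, type = 1),
    kurtosis = e1071::kurtosis(values, type = 1)
  )
}

#' Homogeneity of variances across groups
#'
#' Default is the Hartley-style ratio of the maximum to the minimum group
#' variance; its p-value is approximated by the upper-tail F probability with
#' the degrees of freedom of the max- and min-variance groups (exact for two
#' groups, conservative beyond). `method = "levene"` runs the Brown-Forsythe
#' variant (ANOVA on absolute deviations from group medians) instead.
#'
#' @inheritParams one_way_anova
#' @param method `"hartley"` (variance ratio, default) or `"levene"`.
#' @param f_critical Optional critical value; when supplied the verdict column
#'   reports `f_statistic < f_critical`.
#' @return A one-row tibble: `f_statistic`, `p_value`, `method`, and
#'   `homogeneous` (logical, `NA` when no critical value is given).
#' @export
variance_homogeneity <- function(data, value = "value", group = "stage",
                                 method = c("hartley", "levene"),
                                 f_critical = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 3)) abort("each group needs at least 3 values")
  if (method == "hartley") {
    vars <- tapply(v, g, var)
    ns <- tapply(v, g, length)
    if (min(vars) < 1e-300) {
      warn("variance ratio undefined: a group has zero variance")
      f <- NA_real_
      p <- NA_real_
    } else {
      i_max <- which.max(vars)
      i_min <- which.min(vars)
      f <- vars[[i_max]] / vars[[i_min]]
      p <- pf(f, ns[[i_max]] - 1, ns[[i_min]] - 1, lower.tail = FALSE)
    }
  } else {
    dev <- abs(v - stats::ave(v, g, FUN = median))
    res <- one_way_anova(tibble(value = dev, stage = g))
    f <- res$f_statistic
    p <- res$p_value
  }
  tibble(
    f_statistic = unname(f),
    p_value = unname(p),
    method = method,
    homogeneous = if (is.null(f_critical)) NA else unname(f < f_critical)
  )
}

#' Per-feature significance and normality table
#'
#' Runs the whole feature-statistics battery over a labeled feature table:
#' per-stage mean and SD, one-way ANOVA F and p, pooled skewness and excess
#' kurtosis, and the homogeneity-of-variances statistic — one row per
#' feature, mirroring the layout used to report stage-wise feature
#' significance.
#'
#' @param data Labeled feature table (columns [mf_feature_names] plus the
#'   label column).
#' @param label_col Label column name (default `"stage"`).
#' @param features Feature columns (default: those of [mf_feature_names]
#'   present).
#' @inheritParams variance_homogeneity
#' @return A tibble with one row per feature: `mean_<stage>`, `sd_<stage>`
#'   columns, `f_statistic`, `p_value`, `skewness`, `kurtosis`,
#'   `homogeneity_f`, `homogeneity_p`.
#' @export
feature_significance <- function(data, label_col = "stage", features = NULL,
                                 method = c("hartley", "levene"),
                                 f_critical = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  features <- features %||% intersect(mf_feature_names, names(data))
  if (length(features) == 0) abort("no feature columns found")
  g <- factor(data[[label_col]])
  dplyr::bind_rows(purrr::map(features, function(f) {
    v <- data[[f]]
    by_stage <- tibble(stage = levels(g)) |>
      dplyr::mutate(
        mean = tapply(v, g, mean)[.data$stage],
        sd = tapply(v, g, sd)[.data$stage]
      )
    wide <- tidyr::pivot_wider(
      by_stage,
      names_from = "stage", values_from = c("mean", "sd")
    )
    an <- one_way_anova(tibble(value = v, stage = g))
    mo <- moments(v)
    ho <- variance_homogeneity(tibble(value = v, stage = g),
                               method = method, f_critical = f_critical)
    dplyr::bind_cols(
      tibble(feature = f), wide,
      tibble(
        f_statistic = an$f_statistic, p_value = an$p_value,
        skewness = mo$skewness, kurtosis = mo$kurtosis,
        homogeneity_f = ho$f_statistic, homogeneity_p = ho$p_value
      )
    )
  }))
}
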