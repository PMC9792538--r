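#' Default pipeline configuration
#'
#' All tunables of the extract/train/evaluate workflow as one nested list.
#' [read_config()] merges a YAML file over these defaults and rejects unknown
#' keys; flags of the command-line wrapper override the file.
#'
#' @return A named list of class `mf_config`.
#' @export
default_config <- function() {
  structure(list(
    pixel_spacing = 1,
    enhance = list(stretch = TRUE, p_low = 1, p_high = 99, equalize = FALSE,
                   upsample = 1L),
    binarize = list(method = "otsu", threshold = NULL, keep_largest = FALSE),
    measure = "mask",
    q = list(min = -5, max = 5, step = 0.25),
    scales = NULL,
    offsets = 1L,
    fit = list(min_scale = NULL, max_scale = NULL, r2_warn = 0.98),
    knn = list(k = 5L),
    split = list(n_train = 100L, n_test = 40L),
    runs = 7L,
    seed = 1L,
    scheme = "kaggle"
  ), class = "mf_config")
}

.merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base)) {
      abort(sprintf("unknown config key: %s", paste(here, collapse = ".")))
    }
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(override[[key]])) {
        abort(sprintf("config key %s must be a mapping",
                      paste(here, collapse = ".")))
      }
      base[[key]] <- .merge_config(base[[key]], override[[key]], here)
    } else {
      base[key] <- override[key] # key <- list() form keeps NULL assignments
    }
  }
  base
}

#' Analysis configuration for the phantom stage study
#'
#' The configuration under which the synthetic phantom sequence is analysed:
#' the grayscale intensities serve as the measure (the phantom's staging
#' signal lives in the growing population of dark fluid gaps, which only an
#' intensity-weighted measure can see), the percentile stretch is disabled so
#' the calibrated phantom gray levels survive unchanged, and the mask for the
#' apparent area uses a fixed threshold between the background and tissue
#' levels.
#'
#' @return An `mf_config`.
#' @export
phantom_config <- function() {
  cfg <- default_config()
  cfg$measure <- "gray"
  cfg$enhance$stretch <- FALSE
  cfg$binarize$method <- "fixed"
  cfg$binarize$threshold <- 0.62
  cfg
}

#' @rdname default_config
#' @param path Path to a YAML config file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  override <- yaml::read_yaml(path)
  cfg <- .merge_config(unclass(default_config()), override)
  structure(cfg, class = "mf_config")
}

#' @rdname default_config
#' @param config An `mf_config`.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

.write_manifest <- function(path, config, extra = list()) {
  manifest <- c(
    list(
      tool = "fractalstage",
      version = as.character(utils::packageVersion("fractalstage")),
      config_hash = config_hash(config)
    ),
    extra
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Extract features from a set of images
#'
#' Runs the per-image pipeline ([image_features()]) over files or a
#' directory: load, enhance, binarize, box-count, extract the ten features.
#' Individually unreadable images are skipped with a logged error; if every
#' image fails, the call errors.
#'
#' @param inputs Image file paths, or one directory containing images.
#' @param config An `mf_config` (default [default_config()]).
#' @param labels Optional per-image stage labels (recycled against `inputs`).
#' @param out Optional CSV output path; a `.manifest.json` sidecar naming the
#'   tool version and config hash is written next to it.
#' @return Feature tibble: `image_id`, the ten features, and `stage` when
#'   labels are given.
#' @export
pipeline_extract <- function(inputs, config = default_config(), labels = NULL,
                             out = NULL) {
  if (length(inputs) == 1 && dir.exists(inputs)) {
    inputs <- sort(list.files(
      inputs, pattern = "\\.(png|jpe?g|tiff?|bmp)$",
      ignore.case = TRUE, full.names = TRUE
    ))
  }
  if (length(inputs) == 0) abort("no input images")
  if (!is.null(labels) && length(labels) != length(inputs)) {
    abort("`labels` must match `inputs` in length")
  }
  rows <- purrr::imap(inputs, function(path, i) {
    tryCatch(
      {
        row <- image_features(path, config)
        if (!is.null(labels)) row$stage <- labels[i]
        row
      },
      error = function(e) {
        message(sprintf("[%s] skipped: %s", basename(path), conditionMessage(e)))
        NULL
      }
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("all images failed to process")
  out_tbl <- dplyr::bind_rows(rows)
  if (!is.null(out)) {
    readr::write_csv(out_tbl, out)
    .write_manifest(out, config, list(n_images = nrow(out_tbl)))
  }
  out_tbl
}

#' Train a KNN stage model from a labeled feature table
#'
#' @param features Labeled feature tibble (or CSV path).
#' @param config An `mf_config` supplying `knn$k`.
#' @param out Optional path for the plain-text model bundle.
#' @return A `knn_model`.
#' @export
pipeline_train <- function(features, config = default_config(), out = NULL) {
  if (is.character(features)) {
    features <- suppressMessages(readr::read_csv(features,
                                                 show_col_types = FALSE))
  }
  model <- knn_fit(features, label_col = "stage", k = config$knn$k)
  if (!is.null(out)) {
    write_knn_model(model, out)
    .write_manifest(out, config, list(n_train = nrow(model$x)))
  }
  model
}

#' Predict stages for a feature table
#'
#' @param model A `knn_model` (or bundle path).
#' @param features Feature tibble or CSV path.
#' @param config An `mf_config` (for the output manifest).
#' @param out Optional prediction CSV path.
#' @return Tibble: `image_id` (when present), `predicted`, one vote-fraction
#'   column per class.
#' @export
pipeline_predict <- function(model, features, config = default_config(),
                             out = NULL) {
  if (is.character(model)) model <- read_knn_model(model)
  if (is.character(features)) {
    features <- suppressMessages(readr::read_csv(features,
                                                 show_col_types = FALSE))
  }
  preds <- predict(model, features)
  preds <- dplyr::rename(preds, predicted = "pred")
  if ("image_id" %in% names(features)) {
    preds <- dplyr::bind_cols(features["image_id"], preds)
  }
  if (!is.null(out)) {
    readr::write_csv(preds, out)
    .write_manifest(out, config, list(n_predicted = nrow(preds)))
  }
  preds
}

#' Split-and-average evaluation with full reporting
#'
#' Runs [knn_evaluate_split()] under the configured protocol and emits the
#' per-run and averaged metrics, the multiclass confusion matrix of the first
#' run, and pooled one-vs-rest ROC/AUC tables per class.
#'
#' @param features Labeled feature tibble or CSV path.
#' @param config An `mf_config` (split sizes, k, runs, seed).
#' @param out_dir Optional directory for `metrics_runs.csv`,
#'   `metrics_mean.csv`, `confusion.csv`, `roc_<class>.csv` plus manifests.
#' @return A list: `eval` (`knn_eval`), `roc` (named list of `mf_roc`),
#'   `auc` (named numeric).
#' @export
pipeline_evaluate <- function(features, config = default_config(),
                              out_dir = NULL) {
  if (is.character(features)) {
    features <- suppressMessages(readr::read_csv(features,
                                                 show_col_types = FALSE))
  }
  ev <- knn_evaluate_split(
    features,
    label_col = "stage",
    n_train_per_class = config$split$n_train,
    n_test_per_class = config$split$n_test,
    k = config$knn$k, n_runs = config$runs, seed = config$seed
  )
  classes <- levels(ev$predictions$truth)
  roc <- purrr::map(classes, function(cl) {
    roc_curve(ev$predictions[[paste0("vote_", cl)]],
              ev$predictions$truth == cl)
  })
  names(roc) <- classes
  auc <- purrr::map_dbl(roc, attr, "auc")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p_runs <- file.path(out_dir, "metrics_runs.csv")
    readr::write_csv(ev$class_metrics, p_runs)
    .write_manifest(p_runs, config)
    p_mean <- file.path(out_dir, "metrics_mean.csv")
    readr::write_csv(ev$summary, p_mean)
    .write_manifest(p_mean, config)
    p_conf <- file.path(out_dir, "confusion.csv")
    conf <- as_tibble(as.data.frame(ev$confusions[[1]]$table))
    readr::write_csv(conf, p_conf)
    .write_manifest(p_conf, config)
    for (cl in classes) {
      p_roc <- file.path(out_dir, paste0("roc_", cl, ".csv"))
      readr::write_csv(as_tibble(roc[[cl]]), p_roc)
      .write_manifest(p_roc, config, list(class = cl, auc = auc[[cl]]))
    }
  }
  list(eval = ev, roc = roc, auc = auc)
}

#' Write synthetic fixtures to disk
#'
#' `kind = "cascade"` writes the cascade measure as a PNG (mass rescaled to
#' `[0, 1]`) plus its closed-form spectrum CSV; `"phantom"` writes one PNG per
#' stage/seed combination; `"features"` writes a labeled Gaussian feature
#' CSV. A JSON manifest recording the parameters and seed accompanies every
#' run.
#'
#' @param kind `"cascade"`, `"phantom"` or `"features"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param weights,depth Cascade parameters.
#' @param stages,n_seeds Phantom parameters (stage indices, seeds per stage).
#' @param scheme,n_per_stage Feature-table parameters.
#' @return Character vector of the files written, invisibly.
#' @export
pipeline_simulate <- function(kind = c("cascade", "phantom", "features"),
                              out_dir = ".", seed = 1,
                              weights = c(0.4, 0.3, 0.2, 0.1), depth = 7,
                              stages = 0:3, n_seeds = 5,
                              scheme = "kaggle", n_per_stage = 140) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- default_config()
  files <- switch(kind,
    cascade = {
      m <- cascade_measure(weights, depth, shuffle = TRUE, seed = seed)
      p_png <- file.path(out_dir, sprintf("cascade_depth%d.png", depth))
      png::writePNG(m / max(m), p_png)
      p_csv <- file.path(out_dir, sprintf("cascade_depth%d_spectrum.csv",
                                          depth))
      readr::write_csv(cascade_closed_form(weights), p_csv)
      c(p_png, p_csv)
    },
    phantom = {
      seeds <- withr::with_seed(seed, sample.int(2147483646L, n_seeds))
      unlist(purrr::map(stages, function(st) {
        purrr::map_chr(seq_len(n_seeds), function(i) {
          img <- brain_phantom(st, seed = seeds[i])
          p <- file.path(out_dir, sprintf("phantom_stage%d_seed%d.png", st, i))
          png::writePNG(img$pixels, p)
          p
        })
      }))
    },
    features = {
      tab <- sample_feature_table(scheme, n_per_stage = n_per_stage,
                                  seed = seed)
      p <- file.path(out_dir, sprintf("features_%s.csv", scheme))
      readr::write_csv(tab, p)
      p
    }
  )
  manifest <- file.path(out_dir, paste0("simulate_", kind, ".manifest.json"))
  jsonlite::write_json(
    list(
      tool = "fractalstage",
      version = as.character(utils::packageVersion("fractalstage")),
      kind = kind, seed = seed,
      params = switch(kind,
        cascade = list(weights = weights, depth = depth),
        phantom = list(stages = stages, n_seeds = n_seeds),
        features = list(scheme = scheme, n_per_stage = n_per_stage)
      ),
      files = basename(files)
    ),
    manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(files)
}
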