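#' Fit a k-nearest-neighbour stage classifier
#'
#' Stores the training matrix after z-score standardization (per-feature mean
#' and SD fitted on the training data only) together with the labels; there is
#' no iterative training. Constant features are rejected because they cannot
#' be standardized.
#'
#' @param data Data frame with feature columns and a label column.
#' @param label_col Name of the label column (default `"stage"`).
#' @param k Number of neighbours (default 5); must not exceed the number of
#'   training rows.
#' @param features Feature column names; defaults to [mf_feature_names] when
#'   all are present, otherwise every numeric column except the label.
#' @return A `knn_model`.
#' @export
knn_fit <- function(data, label_col = "stage", k = 5, features = NULL) {
  data <- as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("label column '%s' not found", label_col))
  }
  if (nrow(data) == 0) abort("training data is empty")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a positive whole number")
  }
  if (k > nrow(data)) abort("`k` cannot exceed the number of training rows")
  features <- features %||% {
    if (all(mf_feature_names %in% names(data))) {
      mf_feature_names
    } else {
      setdiff(names(data)[purrr::map_lgl(data, is.numeric)], label_col)
    }
  }
  x <- as.matrix(data[features])
  if (anyNA(x) || any(!is.finite(x))) abort("non-finite feature values")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  if (any(scale_ <= 0)) {
    abort(sprintf(
      "zero-variance feature(s): %s",
      paste(features[scale_ <= 0], collapse = ", ")
    ))
  }
  labels <- factor(data[[label_col]])
  structure(
    list(
      x = sweep(sweep(x, 2, center), 2, scale_, `/`),
      labels = labels,
      classes = levels(labels),
      k = as.integer(k),
      features = features,
      center = center,
      scale = scale_,
      label_col = label_col
    ),
    class = "knn_model"
  )
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf(
    "<knn_model> k = %d, %d training rows, %d features, classes: %s\n",
    x$k, nrow(x$x), length(x$features), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' @rdname knn_fit
#' @param x A `knn_model`.
#' @param ... Unused.
#' @export
tidy.knn_model <- function(x, ...) {
  tibble(feature = x$features, center = unname(x$center),
         scale = unname(x$scale))
}

#' @rdname knn_fit
#' @export
glance.knn_model <- function(x, ...) {
  tibble(k = x$k, n_train = nrow(x$x), n_features = length(x$features),
         n_classes = length(x$classes))
}

# classify one standardized query row; deterministic tie rules:
# distance ties -> training-row order (stable order()); vote ties -> the class
# of the single nearest neighbour among the tied classes.
.knn_one <- function(model, z) {
  d2 <- colSums((t(model$x) - z)^2)
  nn <- order(d2)[seq_len(model$k)]
  votes <- table(factor(model$labels[nn], levels = model$classes))
  top <- names(votes)[votes == max(votes)]
  label <- if (length(top) == 1) {
    top
  } else {
    as.character(model$labels[nn][match(TRUE, model$labels[nn] %in% top)])
  }
  list(label = label, votes = as.numeric(votes) / model$k)
}

#' Predict stages with a fitted KNN model
#'
#' Euclidean distance on standardized features; the k smallest distances vote
#' by majority. Returns the predicted label and the per-class vote fractions
#' (class counts among the k neighbours divided by k), which serve as scores
#' for ROC analysis.
#'
#' @param object A `knn_model`.
#' @param new_data Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return A tibble with `pred` (factor over the training classes) and one
#'   `vote_<class>` column per class.
#' @export
predict.knn_model <- function(object, new_data, ...) {
  new_data <- as_tibble(new_data)
  missing <- setdiff(object$features, names(new_data))
  if (length(missing) > 0) {
    abort(sprintf("missing feature column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- as.matrix(new_data[object$features])
  if (anyNA(x) || any(!is.finite(x))) abort("non-finite feature values")
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  res <- purrr::map(seq_len(nrow(z)), function(i) .knn_one(object, z[i, ]))
  votes <- do.call(rbind, purrr::map(res, "votes"))
  colnames(votes) <- paste0("vote_", object$classes)
  dplyr::bind_cols(
    tibble(pred = factor(purrr::map_chr(res, "label"),
                         levels = object$classes)),
    as_tibble(votes)
  )
}

#' Seeded split-and-average KNN evaluation
#'
#' The evaluation protocol used for staging: in each run, draw a per-class
#' random split without replacement (`n_train_per_class` training and
#' `n_test_per_class` test rows per class), fit the KNN on the training part,
#' predict the test part, and collect the confusion matrix and per-class
#' one-vs-rest metrics; metrics are averaged over `n_runs` runs.
#'
#' @inheritParams knn_fit
#' @param n_train_per_class,n_test_per_class Per-class split sizes.
#' @param n_runs Number of seeded runs to average (default 7).
#' @param seed Integer seed controlling all splits.
#' @return A `knn_eval` object: list with `runs` (per-run accuracy),
#'   `class_metrics` (per-run per-class counts and metrics, full precision),
#'   `predictions` (pooled truth/pred/votes), `confusions` (per-run
#'   `mf_confusion`), and `summary` (means over runs).
#' @export
knn_evaluate_split <- function(data, label_col = "stage",
                               n_train_per_class = 100,
                               n_test_per_class = 40,
                               k = 5, n_runs = 7, seed = 1,
                               features = NULL) {
  data <- as_tibble(data)
  labels <- factor(data[[label_col]])
  need <- n_train_per_class + n_test_per_class
  sizes <- table(labels)
  if (any(sizes < need)) {
    abort(sprintf(
      "each class needs at least %d rows (smallest has %d)", need, min(sizes)
    ))
  }
  run_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_runs))
  runs <- purrr::map(seq_len(n_runs), function(run) {
    idx <- withr::with_seed(run_seeds[run], {
      purrr::map(levels(labels), function(cl) {
        rows <- which(labels == cl)
        picked <- sample(rows, need)
        list(train = picked[seq_len(n_train_per_class)],
             test = picked[n_train_per_class + seq_len(n_test_per_class)])
      })
    })
    train <- data[unlist(purrr::map(idx, "train")), ]
    test <- data[unlist(purrr::map(idx, "test")), ]
    model <- knn_fit(train, label_col = label_col, k = k, features = features)
    preds <- predict(model, test)
    truth <- factor(test[[label_col]], levels = model$classes)
    conf <- confusion_matrix(truth, preds$pred, levels = model$classes)
    cm <- dplyr::mutate(
      binary_metrics(conf$by_class, digits = NULL),
      run = run, .before = 1
    )
    list(
      accuracy = 100 * mean(as.character(truth) == as.character(preds$pred)),
      class_metrics = cm,
      predictions = dplyr::bind_cols(tibble(run = run, truth = truth), preds),
      confusion = conf
    )
  })
  class_metrics <- dplyr::bind_rows(purrr::map(runs, "class_metrics"))
  summary <- tibble(
    mean_accuracy = mean(purrr::map_dbl(runs, "accuracy")),
    mean_sensitivity = mean(class_metrics$sensitivity),
    mean_specificity = mean(class_metrics$specificity),
    mean_precision = mean(class_metrics$precision),
    min_class_sensitivity = min(
      dplyr::summarise(
        dplyr::group_by(class_metrics, .data$class),
        m = mean(.data$sensitivity)
      )$m
    )
  )
  structure(
    list(
      runs = tibble(run = seq_len(n_runs), seed = run_seeds,
                    accuracy = purrr::map_dbl(runs, "accuracy")),
      class_metrics = class_metrics,
      predictions = dplyr::bind_rows(purrr::map(runs, "predictions")),
      confusions = purrr::map(runs, "confusion"),
      summary = summary,
      k = k, n_runs = n_runs, seed = seed
    ),
    class = "knn_eval"
  )
}

#' @export
print.knn_eval <- function(x, ...) {
  cat(sprintf(
    "<knn_eval> %d runs, k = %d; mean accuracy %.2f%% (per run: %s)\n",
    x$n_runs, x$k, x$summary$mean_accuracy,
    paste(sprintf("%.1f", x$runs$accuracy), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname knn_evaluate_split
#' @param x A `knn_eval`.
#' @param ... Unused.
#' @export
tidy.knn_eval <- function(x, ...) x$class_metrics

#' @rdname knn_evaluate_split
#' @export
glance.knn_eval <- function(x, ...) {
  dplyr::bind_cols(x$summary, tibble(n_runs = x$n_runs, k = x$k))
}

#' Persist / restore a KNN model as a plain-text bundle
#'
#' The bundle is a single text file: a key-value header (format version, k,
#' feature names, classes, standardization constants) followed by the
#' standardized training matrix with labels as CSV.
#'
#' @param model A `knn_model`.
#' @param path Output file path.
#' @return `path`, invisibly (`write_knn_model`); a `knn_model`
#'   (`read_knn_model`).
#' @export
write_knn_model <- function(model, path) {
  stopifnot(inherits(model, "knn_model"))
  header <- c(
    "#fractalstage_knn_model v1",
    paste0("#k=", model$k),
    paste0("#label_col=", model$label_col),
    paste0("#features=", paste(model$features, collapse = ",")),
    paste0("#classes=", paste(model$classes, collapse = ",")),
    paste0("#center=", paste(format(model$center, digits = 17), collapse = ",")),
    paste0("#scale=", paste(format(model$scale, digits = 17), collapse = ","))
  )
  body <- dplyr::bind_cols(
    as_tibble(model$x),
    tibble(.label = as.character(model$labels))
  )
  writeLines(header, path)
  suppressMessages(readr::write_csv(body, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname write_knn_model
#' @export
read_knn_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#fractalstage_knn_model")) {
    abort("not a fractalstage KNN model bundle")
  }
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    row <- hdr[startsWith(hdr, paste0("#", key, "="))]
    sub(paste0("^#", key, "="), "", row)
  }
  features <- strsplit(get("features"), ",")[[1]]
  classes <- strsplit(get("classes"), ",")[[1]]
  body <- suppressMessages(readr::read_csv(
    I(paste(lines[!startsWith(lines, "#")], collapse = "\n")),
    show_col_types = FALSE
  ))
  labels <- factor(body$.label, levels = classes)
  structure(
    list(
      x = as.matrix(body[features]),
      labels = labels,
      classes = classes,
      k = as.integer(get("k")),
      features = features,
      center = setNames(as.numeric(strsplit(get("center"), ",")[[1]]),
                        features),
      scale = setNames(as.numeric(strsplit(get("scale"), ",")[[1]]),
                       features),
      label_col = get("label_col")
    ),
    class = "knn_model"
  )
}
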