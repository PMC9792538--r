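make_blobs <- function(n_per_class = 10, centers = list(a = 0, b = 6, c = 12),
                       sd = 0.3, d = 3, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(purrr::imap(centers, function(mu, lab) {
      x <- matrix(rnorm(n_per_class * d, mu, sd), n_per_class, d)
      colnames(x) <- paste0("f", seq_len(d))
      dplyr::bind_cols(tibble::as_tibble(x), tibble::tibble(stage = lab))
    }))
  })
}

test_that("fit validates k, labels and feature variance", {
  data <- make_blobs(3)
  expect_s3_class(knn_fit(data, k = 3), "knn_model")
  expect_error(knn_fit(data, k = 10), "exceed")
  expect_error(knn_fit(data, k = 0), "positive")
  bad <- data
  bad$f1 <- 1
  expect_error(knn_fit(bad, k = 1), "f1")
  expect_error(knn_fit(data[0, ], k = 1), "empty")
  # k = n is accepted (4 points, k = 3)
  expect_s3_class(knn_fit(make_blobs(2, centers = list(a = 0, b = 5)), k = 3),
                  "knn_model")
})

test_that("k = 1 classifies every training point as its own label", {
  data <- make_blobs(5)
  model <- knn_fit(data, k = 1)
  preds <- predict(model, data)
  expect_equal(as.character(preds$pred), data$stage)
  expect_true(all(preds[paste0("vote_", data$stage[1])][data$stage == data$stage[1], ] == 1))
})

test_that("a single-class training set always predicts that class", {
  data <- make_blobs(6, centers = list(only = 0))
  model <- knn_fit(data, k = 3)
  preds <- predict(model, make_blobs(4, centers = list(x = 100)))
  expect_true(all(preds$pred == "only"))
})

test_that("majority vote and vote fractions follow the k nearest", {
  train <- tibble::tibble(
    f1 = c(1, 2, 3), f2 = c(0, 0.1, -0.1),
    stage = c("A", "B", "B")
  )
  model <- knn_fit(train, k = 3)
  pred <- predict(model, tibble::tibble(f1 = 0.9, f2 = 0))
  expect_equal(as.character(pred$pred), "B")
  expect_equal(pred$vote_A, 1 / 3)
  expect_equal(pred$vote_B, 2 / 3)
})

test_that("vote ties break toward the class of the nearest neighbour", {
  train <- tibble::tibble(
    f1 = c(1, 2, 10, 20), f2 = c(0, 0.1, -0.2, 0.3),
    stage = c("A", "B", "A", "B")
  )
  model <- knn_fit(train, k = 2)
  pred <- predict(model, tibble::tibble(f1 = 0, f2 = 0))
  expect_equal(as.character(pred$pred), "A") # nearest among the tied classes
})

test_that("predictions match a brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(6:50, 1)
    k <- sample(c(1, 3, 5), 1)
    n_classes <- sample(2:4, 1)
    train_x <- matrix(rnorm(n * 10), n, 10)
    colnames(train_x) <- paste0("f", 1:10)
    labs <- sample(letters[seq_len(n_classes)], n, replace = TRUE)
    # every class at least once, k within bounds
    labs[seq_len(n_classes)] <- letters[seq_len(n_classes)]
    test_x <- matrix(rnorm(3 * 10), 3, 10)
    colnames(test_x) <- colnames(train_x)
    if (any(apply(train_x, 2, sd) == 0) || k > n) next
    model <- knn_fit(
      dplyr::bind_cols(tibble::as_tibble(train_x), tibble::tibble(stage = labs)),
      k = k
    )
    got <- as.character(predict(model, tibble::as_tibble(test_x))$pred)
    want <- knn_oracle(train_x, labs, test_x, k)
    expect_identical(got, unname(want))
  }
})

test_that("training-row permutation cannot change distinct-distance predictions", {
  data <- make_blobs(8, seed = 7)
  q <- tibble::tibble(f1 = 2.5, f2 = 3.1, f3 = 1.7)
  p1 <- predict(knn_fit(data, k = 5), q)
  perm <- data[sample(nrow(data)), ]
  p2 <- predict(knn_fit(perm, k = 5), q)
  expect_equal(as.character(p1$pred), as.character(p2$pred))
  expect_equal(p1$vote_a, p2$vote_a)
})

test_that("standardization absorbs affine rescaling of a raw feature", {
  data <- make_blobs(8, seed = 3)
  q <- tibble::tibble(f1 = 1.2, f2 = 5.4, f3 = 0.3)
  p1 <- predict(knn_fit(data, k = 3), q)
  scaled <- data
  scaled$f2 <- scaled$f2 * 1000 + 77
  q2 <- q
  q2$f2 <- q2$f2 * 1000 + 77
  p2 <- predict(knn_fit(scaled, k = 3), q2)
  expect_equal(as.character(p1$pred), as.character(p2$pred))
  expect_equal(p1$vote_b, p2$vote_b, tolerance = 1e-9)
})

test_that("evaluate_split is reproducible and perfect on separated classes", {
  data <- make_blobs(20, centers = list(a = 0, b = 50, c = 100), sd = 0.5)
  ev1 <- knn_evaluate_split(data, n_train_per_class = 12, n_test_per_class = 5,
                            k = 3, n_runs = 2, seed = 11)
  expect_equal(ev1$summary$mean_accuracy, 100)
  ev2 <- knn_evaluate_split(data, n_train_per_class = 12, n_test_per_class = 5,
                            k = 3, n_runs = 2, seed = 11)
  expect_identical(ev1$runs, ev2$runs)
  expect_identical(ev1$class_metrics, ev2$class_metrics)
  expect_error(
    knn_evaluate_split(data, n_train_per_class = 19, n_test_per_class = 5),
    "at least"
  )
})

test_that("model round-trips through the plain-text bundle", {
  data <- make_blobs(6, seed = 5)
  model <- knn_fit(data, k = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_knn_model(model, path)
  back <- read_knn_model(path)
  expect_equal(back$k, model$k)
  expect_equal(back$center, model$center)
  q <- make_blobs(2, seed = 9)
  expect_equal(predict(back, q), predict(model, q), tolerance = 1e-12)
})

test_that("tidy and glance expose model and evaluation summaries", {
  data <- make_blobs(8)
  model <- knn_fit(data, k = 3)
  expect_named(tidy(model), c("feature", "center", "scale"))
  expect_equal(glance(model)$n_train, 24)
  ev <- knn_evaluate_split(data, n_train_per_class = 5, n_test_per_class = 2,
                           k = 3, n_runs = 2, seed = 1)
  expect_true(all(c("run", "class", "sensitivity") %in% names(tidy(ev))))
  expect_true("mean_accuracy" %in% names(glance(ev)))
})
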