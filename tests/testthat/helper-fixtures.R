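# Shared fixtures, generated in code at test time.

# canonical unequal cascade weights with closed-form spectra
cascade_weights <- c(0.4, 0.3, 0.2, 0.1)

# a small bimodal image: left half dark, right half bright
bimodal_image <- function(lo = 0.1, hi = 0.9, n = 16) {
  gray_image(cbind(
    matrix(lo, n, n / 2),
    matrix(hi, n, n / 2)
  ))
}

# write a matrix (or HxWx3 array) as a temporary PNG, return the path
write_png_tmp <- function(x, name = "img.png") {
  path <- withr::local_tempfile(fileext = ".png", .local_envir = parent.frame())
  png::writePNG(x, path)
  path
}

# independently written brute-force KNN oracle: full distance sort on
# standardized features, same published tie rules
knn_oracle <- function(train_x, train_lab, test_x, k) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, sd)
  tz <- sweep(sweep(train_x, 2, mu), 2, sdv, `/`)
  qz <- sweep(sweep(test_x, 2, mu), 2, sdv, `/`)
  classes <- levels(factor(train_lab))
  apply(qz, 1, function(z) {
    d <- sqrt(rowSums(sweep(tz, 2, z)^2))
    nn <- order(d)[1:k]
    counts <- table(factor(train_lab[nn], levels = classes))
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) {
      winners
    } else {
      lab_sorted <- as.character(train_lab[nn])
      lab_sorted[lab_sorted %in% winners][1]
    }
  })
}

# Mann-Whitney pair statistic (ties counted 1/2): independent AUC oracle
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
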