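test_that("measure_from_mask normalizes foreground mass", {
  mk <- function(m) structure(
    list(pixels = m, pixel_spacing = 1, threshold = 0.5, method = "fixed"),
    class = "binary_mask"
  )
  expect_equal(measure_from_mask(mk(rbind(c(1L, 1L), c(0L, 0L)))),
               rbind(c(0.5, 0.5), c(0, 0)))
  expect_equal(measure_from_mask(mk(matrix(1L, 4, 4))),
               matrix(1 / 16, 4, 4))
  point <- matrix(0L, 3, 3); point[2, 2] <- 1L
  expect_equal(sum(measure_from_mask(mk(point)) == 1), 1)
})

test_that("box_partition counts boxes and stores exact moment sums", {
  u <- matrix(1 / 64, 8, 8)
  tbl <- box_partition(u, scales = c(2, 4), q = default_q_grid())
  summ <- attr(tbl, "scale_summary")
  expect_equal(summ$n_boxes, c(16L, 4L))
  # r = 4: four boxes of probability 1/4 each
  q2 <- tbl$log_moment[tbl$scale == 4 & abs(tbl$q - 2) < 1e-9]
  expect_equal(q2, log(4 * 0.25^2), tolerance = 1e-12)

  point <- matrix(0, 8, 8); point[3, 5] <- 1
  tp <- box_partition(point, scales = c(2, 4))
  expect_true(all(abs(tp$log_moment) < 1e-12))
  expect_equal(attr(tp, "scale_summary")$n_boxes, c(1L, 1L))

  two <- rbind(c(0.5, 0.5), c(0, 0))
  t2 <- box_partition(two, scales = 1)
  expect_equal(attr(t2, "scale_summary")$n_boxes, 2L)
  expect_equal(exp(t2$log_moment[abs(t2$q - 2) < 1e-9]), 0.5)
})

test_that("box_partition validates scales and occupied-box counts shrink", {
  u <- matrix(1 / 64, 8, 8)
  expect_error(box_partition(u, scales = 16), "exceeds")
  expect_error(box_partition(u, scales = 0), "positive")
  m <- cascade_measure(cascade_weights, 6)
  nb <- attr(box_partition(m), "scale_summary")$n_boxes
  expect_true(all(diff(nb) <= 0))
})

test_that("uniform measures give Dq = 2 at machine precision", {
  u <- matrix(1 / 64^2, 64, 64)
  spec <- generalized_dimensions(box_partition(u))
  expect_lt(max(abs(spec$Dq - 2)), 1e-6)
  expect_true(all(spec$r_squared >= 1 - 1e-12))
})

test_that("cascade dimensions match the closed form", {
  m <- cascade_measure(cascade_weights, 7)
  spec <- generalized_dimensions(box_partition(m))
  cf <- cascade_closed_form(cascade_weights)
  sel <- spec$q >= -3 & spec$q <= 3
  expect_lt(max(abs(spec$Dq - cf$Dq)[sel]), 0.05)
  nd <- named_dimensions(spec)
  expect_equal(nd[["D1"]], 1.846, tolerance = 0.05)
  expect_equal(nd[["D2"]], 1.737, tolerance = 0.05)
  # multifractal ordering on unequal weights
  expect_true(nd[["D0"]] > nd[["D1"]] && nd[["D1"]] > nd[["D2"]])
  # Dq non-increasing in q within tolerance
  expect_true(all(diff(spec$Dq) < 0.02))
})

test_that("uniform measures are monofractal: D0, D1, D2 agree", {
  u <- matrix(1 / 64^2, 64, 64)
  nd <- named_dimensions(generalized_dimensions(box_partition(u)))
  expect_lt(abs(nd[["D0"]] - nd[["D1"]]), 0.01)
  expect_lt(abs(nd[["D1"]] - nd[["D2"]]), 0.01)
})

test_that("regression preconditions are enforced", {
  m <- cascade_measure(cascade_weights, 5)
  tbl <- box_partition(m, scales = c(2, 4))
  expect_error(generalized_dimensions(tbl), "3 scales")
  tbl3 <- box_partition(m)
  expect_error(generalized_dimensions(tbl3, fit_range = c(2, 2)), "3 scales")
})

test_that("mass exponent follows tau = (q - 1) Dq with tau(1) = 0", {
  plane <- generalized_dimensions(box_partition(matrix(1 / 32^2, 32, 32)))
  tau <- mass_exponent(plane)
  expect_equal(tau$tau[abs(tau$q) < 1e-9], -2, tolerance = 1e-6)
  expect_identical(tau$tau[abs(tau$q - 1) < 1e-9], 0)
  expect_equal(tau$tau, (tau$q - 1) * tau$Dq, tolerance = 1e-9)

  casc <- generalized_dimensions(box_partition(cascade_measure(cascade_weights, 7)))
  tc <- mass_exponent(casc)
  expect_equal(tc$tau[abs(tc$q - 2) < 1e-9], 1.737, tolerance = 0.05)
})

test_that("Legendre transform recovers monofractal and cascade exponents", {
  plane <- legendre_spectrum(mass_exponent(
    generalized_dimensions(box_partition(matrix(1 / 32^2, 32, 32)))
  ))
  expect_lt(max(abs(plane$alpha - 2)), 1e-6)
  expect_lt(max(abs(plane$f_alpha - 2)), 1e-6)

  spec <- mf_spectrum(cascade_measure(cascade_weights, 7))
  s <- spec$singularity
  a0 <- s$alpha[abs(s$q) < 1e-9]
  expect_equal(a0, -mean(log2(cascade_weights)), tolerance = 0.05)
  # f(alpha(0)) = D0 is forced by the transform
  d0 <- named_dimensions(spec$dimensions)[["D0"]]
  expect_equal(s$f_alpha[abs(s$q) < 1e-9], d0, tolerance = 1e-9)
})

test_that("legendre_spectrum rejects short or non-uniform grids", {
  gen <- generalized_dimensions(
    box_partition(matrix(1 / 32^2, 32, 32), q = c(-1, 0, 1, 2))
  )
  expect_error(legendre_spectrum(mass_exponent(gen)), "5 moment orders")
  tau <- mass_exponent(generalized_dimensions(
    box_partition(matrix(1 / 32^2, 32, 32), q = c(-2, -1, 0, 1, 2, 4))
  ))
  expect_error(legendre_spectrum(tau), "uniform")
})

test_that("f(alpha) on cascades is capped by D0 and peaks at q = 0", {
  spec <- mf_spectrum(cascade_measure(cascade_weights, 7))
  s <- spec$singularity
  d0 <- named_dimensions(spec$dimensions)[["D0"]]
  expect_true(all(s$f_alpha <= d0 + 0.02))
  expect_equal(s$q[which.max(s$f_alpha)], 0)
})

test_that("zero-mass padding leaves all moment sums unchanged", {
  m <- cascade_measure(cascade_weights, 5) # 32 x 32
  pad <- matrix(0, 64, 64)
  pad[1:32, 1:32] <- m
  t1 <- box_partition(m, scales = c(2, 4, 8))
  t2 <- box_partition(pad, scales = c(2, 4, 8))
  expect_lt(max(abs(t1$log_moment - t2$log_moment)), 1e-9)
})

test_that("offset averaging stays near the anchored grid for positive q", {
  m <- cascade_measure(cascade_weights, 6)
  s1 <- generalized_dimensions(box_partition(m))
  # offsets = 1 must reproduce the anchored grid exactly
  s1b <- generalized_dimensions(box_partition(m, offsets = 1))
  expect_identical(s1$Dq, s1b$Dq)
  s2 <- suppressWarnings(
    generalized_dimensions(box_partition(m, offsets = 4), r2_warn = 0)
  )
  # dyadic cascade scaling is exact only on the anchored grid; shifted grids
  # split cells, so the averaged estimate drifts, most at negative q where
  # the split-off rarefied boxes dominate
  sel <- s1$q >= 0 & s1$q <= 2
  expect_lt(max(abs(s1$Dq - s2$Dq)[sel]), 0.2)
  expect_true(all(is.finite(s2$Dq)))
})

test_that("default q grid must contain 0, 1 and 2", {
  expect_error(default_q_grid(0.5, 5, 1), "must contain")
  expect_silent(default_q_grid(-3, 3, 0.25))
})

test_that("tidy and glance summarize an mf_spectrum", {
  spec <- mf_spectrum(cascade_measure(cascade_weights, 6))
  td <- tidy(spec)
  expect_true(all(c("q", "Dq", "r_squared", "tau", "alpha", "f_alpha")
                  %in% names(td)))
  gl <- glance(spec)
  expect_equal(nrow(gl), 1)
  expect_true(gl$alpha_max > gl$alpha_min)
})
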