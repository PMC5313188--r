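# Rim path, opening-circle fit, and the acetabular axis.

circle_points <- function(n = 20, center = c(10, -5, 3), radius = 25,
                          normal = c(0.3, 0.5, -0.8), arc = 2 * pi) {
  n0 <- normal / sqrt(sum(normal^2))
  B <- acetabulometry:::orthobasis(n0)
  phi <- arc * (seq_len(n) - 1) / n
  sweep(outer(cos(phi), B[, 1] * radius) + outer(sin(phi), B[, 2] * radius),
        2, -center)
}

norm_angle <- function(a, b) {
  ang <- acetabulometry:::vector_angle(a, b)
  min(ang, 180 - ang)
}

test_that("rim path interpolates exact circle points and resamples near the circle", {
  pts <- circle_points(20)
  rp <- build_rim_path(pts)
  # interpolation: the path passes through every pick
  at_knots <- rp$evaluate(rp$knots[-length(rp$knots)])
  expect_equal(at_knots, rp$points, tolerance = 1e-9)
  # resampled points stay within 0.05 mm of the true circle
  rs <- rp$resample(200)
  d <- sweep(rs, 2, c(10, -5, 3))
  n0 <- c(0.3, 0.5, -0.8) / sqrt(sum(c(0.3, 0.5, -0.8)^2))
  h <- d %*% n0
  rad <- sqrt(rowSums(d^2) - h^2)
  expect_lt(max(sqrt((rad - 25)^2 + h^2)), 0.05)
})

test_that("rim path accepts the 6-point minimum and rejects duplicates", {
  expect_s3_class(build_rim_path(circle_points(6)), "rim_path")
  bad <- circle_points(8)
  bad[4, ] <- bad[3, ]
  expect_error(build_rim_path(bad), "duplicate|coincident")
  expect_error(build_rim_path(circle_points(5)), "at least 6")
})

test_that("opening circle is exact on noiseless coplanar points", {
  pts <- circle_points(20)
  fc <- fit_opening_circle(pts)
  expect_equal(fc$center, c(10, -5, 3), tolerance = 1e-9)
  expect_equal(fc$radius, 25, tolerance = 1e-9)
  n0 <- c(0.3, 0.5, -0.8) / sqrt(sum(c(0.3, 0.5, -0.8)^2))
  expect_lt(norm_angle(fc$normal, n0), 1e-7)
  expect_error(fit_opening_circle(cbind(1:9, 2 * (1:9), 3 * (1:9))), "collinear")
})

test_that("opening circle is accurate under isotropic noise (Monte Carlo)", {
  set.seed(21)
  pts <- circle_points(20)
  n0 <- c(0.3, 0.5, -0.8) / sqrt(sum(c(0.3, 0.5, -0.8)^2))
  errs <- replicate(300, {
    f <- fit_opening_circle(pts + matrix(rnorm(60, 0, 0.5), ncol = 3))
    c(sqrt(sum((f$center - c(10, -5, 3))^2)), norm_angle(f$normal, n0))
  })
  expect_lt(mean(errs[1, ]), 0.3)   # mean center error, mm
  expect_lt(mean(errs[2, ]), 0.6)   # mean normal error, degrees
})

test_that("a 120-degree notch gap does not bias the circle normal", {
  pts <- circle_points(20, arc = 2 * pi * 240 / 360)
  fc <- fit_opening_circle(pts)
  n0 <- c(0.3, 0.5, -0.8) / sqrt(sum(c(0.3, 0.5, -0.8)^2))
  expect_lt(norm_angle(fc$normal, n0), 1)
  expect_equal(fc$radius, 25, tolerance = 1e-6)
})

test_that("circle fit matches a brute-force grid-search oracle", {
  # small noiseless instance in a known plane
  pts <- circle_points(9, center = c(2, -1, 4), radius = 12,
                       normal = c(0.1, -0.2, 1))
  fc <- fit_opening_circle(pts)
  n0 <- c(0.1, -0.2, 1) / sqrt(sum(c(0.1, -0.2, 1)^2))
  B <- acetabulometry:::orthobasis(n0)
  p2 <- sweep(pts, 2, c(2, -1, 4)) %*% B
  f2 <- sweep(matrix(fc$center, 1), 2, c(2, -1, 4)) %*% B
  oracle <- circle_grid_oracle(p2, center0 = c(0.5, -0.5), r0 = 11)
  expect_equal(as.numeric(f2), oracle[1:2], tolerance = 1e-6)
  expect_equal(fc$radius, oracle[3], tolerance = 1e-6)
})

test_that("axis orientation follows the outward-lateral rule", {
  ph <- coarse_phantom()
  m <- measure_acetabulum(ph$mesh, ph$landmarks)
  frame <- m$frame
  circ_x <- list(center = c(0, 0, 0), radius = 25, normal = frame$axes[, "X"])
  class(circ_x) <- "opening_circle"
  expect_equal(make_axis(circ_x, frame, "right")$direction, c(1, 0, 0),
               tolerance = 1e-9)
  circ_neg <- circ_x; circ_neg$normal <- -frame$axes[, "X"]
  expect_equal(make_axis(circ_neg, frame, "right")$direction, c(1, 0, 0),
               tolerance = 1e-9)
  expect_equal(make_axis(circ_x, frame, "left")$direction, c(1, 0, 0) * c(1, 1, 1),
               tolerance = 1e-9)  # flipped to outward for the left side
})

test_that("phantom cup axis is recovered to under 0.1 degree", {
  ph <- default_phantom()
  m <- measure_acetabulum(ph$mesh, ph$landmarks)
  for (side in c("left", "right")) {
    tr <- ph$truth$angles[[side]]$anatomic
    ax_true <- angles_to_axis("anatomic", tr$anteversion, tr$inclination)
    expect_lt(acetabulometry:::vector_angle(m$hips[[side]]$axis$direction, ax_true), 0.1)
  }
})

test_that("axis is stable under rim-point subsets and spline resampling", {
  ph <- default_phantom()
  m <- measure_acetabulum(ph$mesh, ph$landmarks)
  frame <- m$frame
  rim <- ph$landmarks$rim_right
  base_axis <- m$hips$right$axis$direction
  set.seed(22)
  for (i in 1:8) {
    sub <- sort(sample(nrow(rim), sample(12:20, 1)))
    ax <- make_axis(fit_opening_circle(rim[sub, ]), frame, "right")$direction
    expect_lt(acetabulometry:::vector_angle(ax, base_axis), 0.2)
  }
  # resampling the spline path before fitting barely moves the axis
  rs <- build_rim_path(rim)$resample(60)
  ax_rs <- make_axis(fit_opening_circle(rs), frame, "right")$direction
  expect_lt(acetabulometry:::vector_angle(ax_rs, base_axis), 0.1)
})
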