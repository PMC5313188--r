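# APP refinement, ICP mid-sagittal plane, frame construction, posture.

test_that("initial APP passes through the picks with an anterior normal", {
  lmk <- pelvic_landmarks(c(-120, 0, 0), c(120, 0, 0),
                          c(-25, 0, -90), c(25, 0, -90))
  pl <- initial_app(lmk, centroid = c(0, -30, -30))
  expect_equal(abs(pl$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_gt(pl$normal[2], 0)       # anterior, away from the posterior centroid
  expect_equal(pl$offset, 0, tolerance = 1e-12)
  # collinear defining points
  bad <- pelvic_landmarks(c(-120, 0, 0), c(120, 0, 0), c(-25, 0, 0), c(25, 0, 0))
  expect_error(initial_app(bad), "collinear")
})

test_that("APP refinement recovers the exact apex vertices from displaced picks", {
  ph <- default_phantom()
  exact <- refine_app(ph$mesh, ph$landmarks)
  # displace every pick ~5 mm tangentially and re-run
  set.seed(31)
  vn <- acetabulometry:::vertex_normals(ph$mesh)
  for (rep in 1:5) {
    lmk2 <- acetabulometry:::perturb_landmarks(ph, vn, 5, 0)
    ref <- refine_app(ph$mesh, lmk2)
    expect_true(ref$converged)
    for (nm in names(ref$points))
      expect_equal(ref$points[[nm]], exact$points[[nm]], tolerance = 1e-12)
  }
})

test_that("APP refinement is idempotent on its own output", {
  ph <- default_phantom()
  r1 <- refine_app(ph$mesh, ph$landmarks)
  lmk2 <- pelvic_landmarks(r1$points$asis_left, r1$points$asis_right,
                           r1$points$pt_left, r1$points$pt_right)
  r2 <- refine_app(ph$mesh, lmk2)
  expect_equal(r2$plane$normal, r1$plane$normal, tolerance = 1e-12)
  expect_equal(r2$plane$offset, r1$plane$offset, tolerance = 1e-12)
  expect_lte(r2$iterations, 2)
})

test_that("refinement result is pick-independent within the basin", {
  ph <- coarse_phantom()
  base <- refine_app(ph$mesh, ph$landmarks)
  set.seed(32)
  vn <- acetabulometry:::vertex_normals(ph$mesh)
  for (rep in 1:20) {
    lmk2 <- acetabulometry:::perturb_landmarks(ph, vn, 4, 0)
    ref <- refine_app(ph$mesh, lmk2)
    expect_equal(ref$plane$normal, base$plane$normal, tolerance = 1e-12)
    expect_equal(ref$plane$offset, base$plane$offset, tolerance = 1e-12)
  }
})

test_that("off-mesh landmarks are rejected", {
  ph <- coarse_phantom()
  lmk <- ph$landmarks
  lmk$asis_left <- lmk$asis_left + c(0, 50, 0)
  expect_error(refine_app(ph$mesh, lmk), "region radius")
})

test_that("MSP of a mirror-symmetric phantom is the exact symmetry plane", {
  ph <- default_phantom()
  app <- refine_app(ph$mesh, ph$landmarks)
  msp <- fit_msp(ph$mesh, app$points)
  expect_gt(abs(sum(msp$normal * c(1, 0, 0))), 0.99999)
  expect_lt(abs(msp$offset), 0.01)
})

test_that("a small asymmetric bump moves the MSP by less than a degree", {
  ph <- default_phantom()
  mesh <- ph$mesh
  # raise a 2 mm bump on the right wing near the ASIS region
  target <- c(110, -10, 10)
  d <- sqrt(colSums((t(mesh$vertices) - target)^2))
  sel <- d < 8
  mesh$vertices[sel, 2] <- mesh$vertices[sel, 2] + 2 * exp(-(d[sel] / 4)^2)
  app <- refine_app(mesh, ph$landmarks)
  msp <- fit_msp(mesh, app$points)
  ang <- acetabulometry:::vector_angle(msp$normal, c(1, 0, 0))
  expect_lt(min(ang, 180 - ang), 1)
})

test_that("undersized ASIS clouds are rejected", {
  ph <- coarse_phantom()
  app <- refine_app(ph$mesh, ph$landmarks)
  expect_error(fit_msp(ph$mesh, app$points, region_radius_mm = 2),
               "at least 50 vertices")
})

test_that("frame axes are orthonormal, right-handed, and pose-equivariant", {
  ph <- coarse_phantom()
  app <- refine_app(ph$mesh, ph$landmarks)
  msp <- fit_msp(ph$mesh, app$points)
  fr <- build_frame(app$plane, msp, app$points)
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:4) {
    R <- acetabulometry:::random_rotation()
    pose <- rigid3(R, rnorm(3, 0, 20))
    ph2 <- make_standard_pelvis(phantom_spec(mesh_resolution = 2, pelvis_pose = pose))
    app2 <- refine_app(ph2$mesh, ph2$landmarks)
    msp2 <- fit_msp(ph2$mesh, app2$points)
    fr2 <- build_frame(app2$plane, msp2, app2$points)
    for (k in 1:3)
      expect_lt(acetabulometry:::vector_angle(fr2$axes[, k], R %*% fr$axes[, k]), 0.05)
  }
})

test_that("near-parallel APP and MSP are rejected", {
  app <- plane3(c(0, 1, 0), 0)
  msp <- plane3(c(0, 0.99, 0.12), 0)
  pts <- list(asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
              pt_left = c(-25, 0, -90), pt_right = c(25, 0, -90))
  expect_error(build_frame(app, msp, pts), "near-parallel")
})

test_that("posture angles follow the scanner-frame conventions", {
  ph0 <- coarse_phantom()
  m0 <- measure_acetabulum(ph0$mesh, ph0$landmarks)
  expect_equal(unname(m0$posture), c(0, 0, 0), tolerance = 1e-6)
  # pure sagittal rotation: tilt only (plus matching obliqueness of Z)
  pose_x <- rigid3(rotation_about("x", 7))
  ph1 <- make_standard_pelvis(phantom_spec(mesh_resolution = 2, pelvis_pose = pose_x))
  m1 <- measure_acetabulum(ph1$mesh, ph1$landmarks)
  expect_equal(abs(unname(m1$posture["tilt"])), 7, tolerance = 0.01)
  expect_equal(unname(m1$posture["rotation"]), 0, tolerance = 0.01)
  expect_equal(unname(m1$posture["obliqueness"]), 7, tolerance = 0.01)
  # pure axial rotation: rotation only
  pose_z <- rigid3(rotation_about("z", 5))
  ph2 <- make_standard_pelvis(phantom_spec(mesh_resolution = 2, pelvis_pose = pose_z))
  m2 <- measure_acetabulum(ph2$mesh, ph2$landmarks)
  expect_equal(unname(m2$posture["rotation"]), 5, tolerance = 0.01)
  expect_equal(unname(m2$posture["tilt"]), 0, tolerance = 0.01)
})

test_that("MSP recovery stays under 0.1 degree over a 50-pose ensemble", {
  set.seed(34)
  worst <- 0
  for (rep in 1:50) {
    R <- acetabulometry:::random_rotation()
    pose <- rigid3(R, rnorm(3, 0, 30))
    ph <- make_standard_pelvis(phantom_spec(mesh_resolution = 2, pelvis_pose = pose))
    app <- refine_app(ph$mesh, ph$landmarks)
    msp <- fit_msp(ph$mesh, app$points)
    true_n <- ph$truth$msp$normal
    ang <- acetabulometry:::vector_angle(msp$normal, true_n)
    worst <- max(worst, min(ang, 180 - ang))
  }
  expect_lt(worst, 0.1)
})
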