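# Synthetic phantom generator: ground truth, voxel phantom, populations,
# simulated raters.

test_that("symmetric identity-pose phantom has the expected ground truth", {
  ph <- coarse_phantom()
  expect_equal(abs(ph$truth$msp$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ph$truth$msp$offset, 0, tolerance = 1e-12)
  expect_equal(unname(ph$truth$posture), c(0, 0, 0), tolerance = 1e-12)
  # stored angles are self-consistent with the stored rim normal
  for (side in c("left", "right")) {
    rc <- ph$truth$rim_circle[[side]]
    lat <- if (side == "right") 1 else -1
    las <- c(lat * rc$normal[1], rc$normal[2], rc$normal[3])
    got <- axis_to_angles(las, "anatomic")
    tr <- ph$truth$angles[[side]]$anatomic
    expect_equal(got$anteversion, tr$anteversion, tolerance = 1e-9)
    expect_equal(got$inclination, tr$inclination, tolerance = 1e-9)
  }
})

test_that("ground-truth radiographic anteversion matches the closed form and oracle", {
  spec <- phantom_spec(true_anatomic_left = c(20.1, 53.6),
                       true_anatomic_right = c(20.1, 53.6),
                       mesh_resolution = 3)
  ph <- make_standard_pelvis(spec)
  ra <- ph$truth$angles$right$radiographic$anteversion
  expect_equal(ra, asin(sin(20.1 * pi / 180) * sin(53.6 * pi / 180)) * 180 / pi,
               tolerance = 1e-9)
  orc <- angles_oracle(angles_to_axis("anatomic", 20.1, 53.6))
  expect_equal(ra, orc$radiographic[1], tolerance = 1e-9)
  expect_equal(round(ra, 2), 16.06)
})

test_that("phantom mesh is watertight with exact landmark apexes", {
  ph <- default_phantom()
  expect_true(acetabulometry:::mesh_is_closed_manifold(ph$mesh))
  # the picked ASIS/PT initial landmarks coincide with mesh vertices
  for (nm in c("asis_left", "asis_right", "pt_left", "pt_right")) {
    d <- min(sqrt(colSums((t(ph$mesh$vertices) - ph$landmarks[[nm]])^2)))
    expect_lt(d, 1e-9)
  }
  # rim picks lie exactly on the true rim circles
  for (side in c("left", "right")) {
    rc <- ph$truth$rim_circle[[side]]
    rim <- ph$landmarks[[paste0("rim_", side)]]
    d <- sweep(rim, 2, rc$center)
    h <- d %*% rc$normal
    expect_lt(max(abs(h)), 1e-9)
    expect_equal(sqrt(rowSums(d^2)), rep(rc$radius, nrow(rim)), tolerance = 1e-9)
  }
})

test_that("rigid pose changes posture but not the six acetabular angles", {
  ph0 <- default_phantom()
  m0 <- measure_acetabulum(ph0$mesh, ph0$landmarks)
  set.seed(41)
  for (rep in 1:2) {
    R <- acetabulometry:::random_rotation()
    pose <- rigid3(R, rnorm(3, 0, 25))
    ph <- make_standard_pelvis(phantom_spec(mesh_resolution = 1, pelvis_pose = pose))
    m <- measure_acetabulum(ph$mesh, ph$landmarks)
    expect_lt(max(abs(coef(m) - coef(m0))), 0.01)
    expect_gt(max(abs(unname(m$posture))), 1)   # posture did move
    expect_equal(unname(m$posture), unname(ph$truth$posture), tolerance = 0.05)
  }
})

test_that("mirroring a phantom across the MSP swaps left and right exactly", {
  spec <- phantom_spec(true_anatomic_left = c(14, 48),
                       true_anatomic_right = c(26, 60),
                       mesh_resolution = 2)
  ph <- make_standard_pelvis(spec)
  m <- measure_acetabulum(ph$mesh, ph$landmarks)
  mir <- mirror_case(ph$mesh, ph$landmarks)
  m2 <- measure_acetabulum(mir$mesh, mir$landmarks)
  expect_equal(coef(m2)["left", ], coef(m)["right", ], tolerance = 1e-6)
  expect_equal(coef(m2)["right", ], coef(m)["left", ], tolerance = 1e-6)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(cup_radius = -1), "cup_radius")
  expect_error(phantom_spec(true_anatomic_left = c(20, 95)), "inclination")
  # PTs on the ASIS line: APP undefined
  expect_error(phantom_spec(pt_left = c(-25, 0, 0), pt_right = c(25, 0, 0)))
  # cup raised into the iliac slab region
  expect_error(phantom_spec(cup_center_left = c(-90, -25, -20),
                            cup_center_right = c(90, -25, -20)),
               "slab|too high")
  # asymmetric landmarks
  expect_error(phantom_spec(asis_left = c(-110, 0, 0)), "symmetric")
})

test_that("voxel phantom separates ball and pelvis by the requested gap", {
  vp <- default_ct_phantom()
  vol <- vp$volume
  # noiseless: thresholding at the midpoint recovers exactly the bone+ball set
  thr <- vol$intensities > vp$bone / 2
  expect_identical(unname(thr), unname(vol$intensities == vp$bone))
  # ball voxels: within ball radius of the ball center (distance oracle)
  d <- dim(vol$intensities)
  ctr <- vp$ball$center
  # distances on the grid via separable squared terms
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  dist2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`), (zs - ctr[3])^2, `+`)
  ball_vox <- dist2 <= vp$ball$radius^2
  expect_true(all(thr[ball_vox]))
  bone_vox <- vp$bone_mask$intensities & !ball_vox
  # ball and pelvis are disjoint 26-connected components: growing from a
  # cup-wall seed reaches every pelvis voxel and no ball voxel
  ax <- acetabulometry:::anatomic_axis_intrinsic(vp$spec$true_anatomic_right, "right")
  seed_world <- c(90, -25, -60) - 26.5 * ax
  sv <- as.integer(round((seed_world - vol$origin) / vol$spacing)) + 1L
  grown <- region_grow(vol, sv, vp$bone / 2, vp$bone * 2)
  expect_identical(unname(grown$intensities), unname(bone_vox))
  expect_false(any(grown$intensities & ball_vox))
})

test_that("voxel phantom generation is deterministic and validates the gap", {
  spec <- phantom_spec(mesh_resolution = 2)
  a <- make_ct_phantom(spec, gap_mm = 3, noise_sd = 5, spacing = 2, seed = 9)
  b <- make_ct_phantom(spec, gap_mm = 3, noise_sd = 5, spacing = 2, seed = 9)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_error(make_ct_phantom(spec, gap_mm = 1, spacing = 2), "spacing")
})

test_that("simulated population recovers its generating parameters", {
  # law of large numbers against the analytic truncated-normal mean
  params <- population_defaults()
  params$male$av$sd <- 4
  pop <- sample_population(10000, params = params, seed = 5)
  males <- pop[pop$sex == "male", ]
  av_subject <- (males$aa_left + males$aa_right) / 2
  p <- params$male$av
  alpha <- (p$lo - p$mean) / p$sd; beta <- (p$hi - p$mean) / p$sd
  mean_trunc <- p$mean + p$sd * (dnorm(alpha) - dnorm(beta)) /
                                (pnorm(beta) - pnorm(alpha))
  se <- p$sd / sqrt(nrow(males))
  expect_lt(abs(mean(av_subject) - mean_trunc), 3 * se)
  # zero SD collapses to the mean
  params0 <- population_defaults()
  for (sx in c("male", "female")) {
    params0[[sx]]$av$sd <- 0; params0[[sx]]$inc$sd <- 0
  }
  params0$bilateral$av$sd <- 0; params0$bilateral$inc$sd <- 0
  pop0 <- sample_population(5, params = params0, seed = 1)
  m0 <- pop0[pop0$sex == "male", ]
  expect_true(all(abs((m0$aa_left + m0$aa_right) / 2 - 18.8) < 1e-9))
  expect_true(all(abs(m0$aa_left - m0$aa_right - 0.3) < 1e-9))
  # determinism
  expect_identical(sample_population(50, seed = 7), sample_population(50, seed = 7))
})

test_that("zero rater noise gives identical trials and a flagged ICC", {
  specs <- list(phantom_spec(true_anatomic_left = c(15, 50),
                             true_anatomic_right = c(15, 50),
                             mesh_resolution = 2),
                phantom_spec(true_anatomic_left = c(25, 58),
                             true_anatomic_right = c(25, 58),
                             mesh_resolution = 2, seed = 2))
  tr <- simulate_raters(specs, n_raters = 2, n_trials = 1,
                        landmark_noise_mm = 0, rim_noise_mm = 0, seed = 3)
  m <- ratings_matrix(tr, "anatomic")
  expect_equal(m[, 1], m[, 2], tolerance = 1e-12, ignore_attr = TRUE)
  # identical raters but varying targets: ICC is exactly 1
  expect_equal(icc_single(m)$icc, 1, tolerance = 1e-9)
  # a truly degenerate matrix (no variance at all) is flagged
  expect_warning(r0 <- icc_single(matrix(5, 4, 3)), "zero total variance")
  expect_true(r0$degenerate)
})

test_that("increasing rim noise does not increase the anatomic ICC", {
  specs <- lapply(1:4, function(i)
    phantom_spec(true_anatomic_left = c(5 + 8 * i, 40 + 5 * i),
                 true_anatomic_right = c(5 + 8 * i, 40 + 5 * i),
                 mesh_resolution = 2, seed = i))
  models <- lapply(specs, make_standard_pelvis)
  icc_at <- function(noise, seed) {
    tr <- simulate_raters(models, n_raters = 2, n_trials = 1,
                          landmark_noise_mm = 0, rim_noise_mm = noise, seed = seed)
    icc_single(ratings_matrix(tr, "anatomic"))$icc
  }
  for (seed in 1:3) {
    lo <- icc_at(1, seed)
    hi <- icc_at(2, seed)
    expect_lte(hi, lo + 1e-6)
  }
})
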