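# Sphere fit, spherical masking, region growing, surface extraction,
# smoothing.

test_that("sphere fit is exact on noiseless data and robust to noise", {
  c0 <- c(1, 2, 3); r0 <- 10
  pts <- rbind(c0 + c(r0, 0, 0), c0 - c(r0, 0, 0),
               c0 + c(0, r0, 0), c0 - c(0, r0, 0),
               c0 + c(0, 0, r0), c0 - c(0, 0, r0))
  s <- fit_sphere(pts)
  expect_equal(s$center, c0, tolerance = 1e-12)
  expect_equal(s$radius, r0, tolerance = 1e-12)
  set.seed(51)
  u <- matrix(rnorm(600), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  noisy <- sweep(u * r0, 2, -c0) + matrix(rnorm(600, 0, 0.1), ncol = 3)
  s2 <- fit_sphere(noisy)
  expect_lt(sqrt(sum((s2$center - c0)^2)), 0.05)
  # coplanar points are degenerate
  flat <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(fit_sphere(flat), "coplanar|singular|degenerate")
})

test_that("spherical mask removes exactly the voxels inside radius + margin", {
  vp <- default_ct_phantom()
  vol <- vp$volume
  sph <- list(center = vp$ball$center, radius = vp$ball$radius)
  masked <- apply_spherical_mask(vol, sph, margin_mm = 0)
  d <- dim(vol$intensities)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  dist2 <- outer(outer((xs - sph$center[1])^2, (ys - sph$center[2])^2, `+`),
                 (zs - sph$center[3])^2, `+`)
  inside <- dist2 <= sph$radius^2
  # every ball voxel zeroed, everything else untouched
  expect_true(all(masked$intensities[inside] == 0))
  expect_identical(masked$intensities[!inside], vol$intensities[!inside])
  # cup shell voxels are farther than the gap, so none are removed at margin 0
  expect_identical(unname(masked$intensities > 0 & vp$bone_mask$intensities),
                   unname(vp$bone_mask$intensities == TRUE))
  # margin equal to the gap removes the brute-force count of cup voxels
  masked2 <- apply_spherical_mask(vol, sph, margin_mm = vp$gap_mm)
  inside2 <- dist2 <= (sph$radius + vp$gap_mm)^2
  removed_bone <- sum(vp$bone_mask$intensities & inside2)
  expect_gt(removed_bone, 0)
  expect_equal(sum(vp$bone_mask$intensities) - sum(masked2$intensities > 0 &
                                                     vp$bone_mask$intensities),
               removed_bone)
  # sphere entirely outside the grid leaves the volume unchanged
  far <- apply_spherical_mask(vol, list(center = c(1e4, 1e4, 1e4), radius = 5))
  expect_identical(far$intensities, vol$intensities)
})

test_that("region growing selects one 26-connected component, seed-invariantly", {
  arr <- array(0, c(12, 12, 4))
  arr[2:4, 2:4, 2:3] <- 100          # blob A
  arr[8:10, 8:10, 2:3] <- 100        # blob B
  vol <- voxel_volume(arr)
  mA <- region_grow(vol, c(3, 3, 2), 50, 150)
  expect_equal(sum(mA$intensities), 18)
  expect_false(any(mA$intensities[8:10, 8:10, ]))
  # different seed in the same component: identical mask
  mA2 <- region_grow(vol, c(4, 2, 3), 50, 150)
  expect_identical(mA$intensities, mA2$intensities)
  expect_error(region_grow(vol, c(3, 3, 2), 150, 50), "lo")
  expect_error(region_grow(vol, c(6, 6, 2), 50, 150), "seed intensity")
})

test_that("isosurface of a voxelized ball matches the analytic volume", {
  surf <- extract_surface(ball_mask(20))
  expect_true(acetabulometry:::mesh_is_closed_manifold(surf))
  v_true <- 4 / 3 * pi * 20^3
  expect_lt(abs(mesh_volume(surf) - v_true) / v_true, 0.02)
})

test_that("a single voxel yields a closed surface with positive volume", {
  arr <- array(0, c(3, 3, 3)); arr[2, 2, 2] <- 1
  s <- extract_surface(voxel_volume(arr))
  expect_true(acetabulometry:::mesh_is_closed_manifold(s))
  expect_gt(mesh_volume(s), 0)
  expect_error(extract_surface(voxel_volume(array(0, c(3, 3, 3)))), "empty")
})

test_that("mesh back-voxelization overlaps the source mask by 99 percent", {
  vol <- ball_mask(8)
  surf <- extract_surface(vol)
  rv <- voxelize_mesh(surf, spacing = 1, origin = vol$origin,
                      dims = dim(vol$intensities))
  a <- vol$intensities > 0; b <- rv$intensities > 0
  expect_gte(sum(a & b) / sum(a | b), 0.99)
})

test_that("smoothing preserves volume and reduces deviation from the sphere", {
  surf <- extract_surface(ball_mask(20))
  expect_identical(smooth_mesh(surf, 0), surf)
  sm <- smooth_mesh(surf, 20)
  dv <- abs(mesh_volume(sm) - mesh_volume(surf)) / mesh_volume(surf)
  expect_lt(dv, 0.001)
  dev0 <- max(abs(sqrt(rowSums(surf$vertices^2)) - 20))
  dev1 <- max(abs(sqrt(rowSums(sm$vertices^2)) - 20))
  expect_lt(dev1, dev0)
  expect_identical(sm$faces, surf$faces)   # connectivity unchanged
})

test_that("smoothing strictly reduces staircase roughness of a slanted slab", {
  # slanted slab voxelization has staircase normals; kept one voxel away
  # from the grid border so the surface closes
  xs <- seq_len(30); g <- expand.grid(x = xs, y = xs, z = seq_len(24))
  arr <- array(0, c(30, 30, 24))
  core <- g$x >= 2 & g$x <= 29 & g$y >= 2 & g$y <= 29
  arr[core & abs(g$z - 8 - 0.15 * g$x - 0.1 * g$y) <= 1.5] <- 1
  slab <- extract_surface(voxel_volume(arr))
  sm <- smooth_mesh(slab, 10)
  expect_lt(acetabulometry:::surface_roughness(sm),
            acetabulometry:::surface_roughness(slab))
})

test_that("non-manifold meshes are refused by the smoother", {
  tri <- pelvic_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(c(1, 2, 3), 1))
  expect_error(smooth_mesh(tri, 5), "manifold")
})

test_that("segmentation pipeline reproduces ground truth within half a degree", {
  spec <- phantom_spec(mesh_resolution = 1)
  ph <- make_standard_pelvis(spec)
  vp <- make_ct_phantom(spec, gap_mm = 2, noise_sd = 0, spacing = 1)
  set.seed(52)
  u <- matrix(rnorm(450), ncol = 3); u <- u / sqrt(rowSums(u^2))
  head_pts <- sweep(u * vp$ball$radius, 2, -vp$ball$center)
  sph <- fit_sphere(head_pts)
  masked <- apply_spherical_mask(vp$volume, sph, margin_mm = 1)
  ax <- acetabulometry:::anatomic_axis_intrinsic(spec$true_anatomic_right, "right")
  seed_world <- c(90, -25, -60) - (spec$cup_radius + 1.5) * ax
  sv <- as.integer(round((seed_world - masked$origin) / masked$spacing)) + 1L
  mask <- region_grow(masked, sv, 500, 1500)
  mesh <- smooth_mesh(extract_surface(mask), 10)
  m <- measure_acetabulum(mesh, ph$landmarks)
  err <- abs(coef(m) - truth_matrix(ph))
  expect_lt(max(err), 0.5)
})
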