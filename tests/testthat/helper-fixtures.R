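# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default symmetric phantom at 1 mm mesh resolution
default_phantom <- function() {
  cached("phantom_res1", make_standard_pelvis(phantom_spec(mesh_resolution = 1)))
}

# coarse phantom for geometry-only checks
coarse_phantom <- function() {
  cached("phantom_res2", make_standard_pelvis(phantom_spec(mesh_resolution = 2)))
}

# noiseless CT voxel phantom at 1 mm spacing, gap 2 mm
default_ct_phantom <- function() {
  cached("ct_phantom", make_ct_phantom(phantom_spec(mesh_resolution = 2),
                                       gap_mm = 2, noise_sd = 0, spacing = 1))
}

# voxelized ball mask of radius r at unit spacing
ball_mask <- function(r = 20, pad = 4) {
  cached(paste0("ball_", r), {
    xs <- seq(-r - pad, r + pad, by = 1)
    g <- expand.grid(x = xs, y = xs, z = xs)
    arr <- array(0, rep(length(xs), 3))
    arr[g$x^2 + g$y^2 + g$z^2 <= r^2] <- 1
    voxel_volume(arr, spacing = 1, origin = rep(-r - pad, 3))
  })
}

# truth matrix (both sides) for a standard_pelvis
truth_matrix <- function(ph) {
  rbind(left = truth_angles(ph$truth, "left"),
        right = truth_angles(ph$truth, "right"))
}

# independent projection-based oracle for the three angle definitions:
# uses only vector projections and acos, no atan2/asin closed forms
angles_oracle <- function(axis) {
  lat <- c(1, 0, 0); ant <- c(0, 1, 0); inf <- c(0, 0, -1)
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v) /
                                           sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  proj_onto_plane <- function(v, n) v - sum(v * n) * n
  sgn <- function(x) if (x < 0) -1 else 1
  AI <- ang(axis, inf)
  aa_proj <- proj_onto_plane(axis, c(0, 0, 1))          # project to axial plane
  AA <- sgn(axis[2]) * ang(aa_proj, lat)
  RA <- sgn(axis[2]) * (90 - ang(axis, ant * sgn(axis[2])))
  ri_proj <- proj_onto_plane(axis, ant)                 # coronal projection
  RI <- ang(ri_proj, inf)
  OI <- 90 - ang(axis, lat)
  oa_proj <- proj_onto_plane(axis, lat)                 # sagittal projection
  OA <- sgn(axis[2]) * ang(oa_proj, inf)
  list(anatomic = c(AA, AI), radiographic = c(RA, RI), operative = c(OA, OI))
}

# multi-resolution grid-search oracle for the in-plane circle fit
circle_grid_oracle <- function(pts2d, center0, r0, halfwidth = 2) {
  obj <- function(cx, cy, r)
    sum((sqrt((pts2d[, 1] - cx)^2 + (pts2d[, 2] - cy)^2) - r)^2)
  best <- c(center0, r0)
  hw <- halfwidth
  for (round in 1:14) {
    gx <- best[1] + seq(-hw, hw, length.out = 9)
    gy <- best[2] + seq(-hw, hw, length.out = 9)
    gr <- best[3] + seq(-hw, hw, length.out = 9)
    g <- expand.grid(cx = gx, cy = gy, r = gr)
    vals <- mapply(obj, g$cx, g$cy, g$r)
    best <- as.numeric(g[which.min(vals), ])
    hw <- hw * 0.3
  }
  best
}

# reflect a mesh and its landmarks across the scanner x = 0 plane and
# swap side labels (for mirror-symmetry checks)
mirror_case <- function(mesh, lmk) {
  mv <- mesh$vertices; mv[, 1] <- -mv[, 1]
  flipped <- pelvic_mesh(mv, mesh$faces[, c(1, 3, 2)])
  fl <- function(p) { p <- rbind3_(p); p[, 1] <- -p[, 1]; p }
  lm2 <- pelvic_landmarks(fl(lmk$asis_right), fl(lmk$asis_left),
                          fl(lmk$pt_right), fl(lmk$pt_left),
                          rim_left = fl(lmk$rim_right),
                          rim_right = fl(lmk$rim_left))
  list(mesh = flipped, landmarks = lm2)
}

rbind3_ <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else as.matrix(x)
}
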