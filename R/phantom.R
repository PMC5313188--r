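# Standardized synthetic pelvic phantoms with analytic ground truth, the
# voxel ball-in-socket phantom for the segmentation stage, and the
# simulated population / simulated rater generators for the statistics
# stage.  The geometry is deliberately schematic (slabs, bump spheres,
# hemispherical cup shells joined by struts) so that every quantity the
# pipeline measures has an exact closed-form value.

#' Specification of a standardized synthetic pelvis
#'
#' Landmark coordinates are given in the scanner frame before the pose is
#' applied; the generator requires them to be mirror-symmetric about the
#' plane perpendicular to the ASIS line through the mid-ASIS point, with
#' the pubic tubercles lying in the anterior pelvic plane, so that the
#' phantom has an exactly known symmetry plane.
#'
#' @param asis_left,asis_right,pt_left,pt_right landmark coordinates, mm.
#' @param cup_center_left,cup_center_right centers of the acetabular
#'   opening circles (the centers of rotation), mm.
#' @param cup_radius opening-circle radius, mm (> 0).
#' @param true_anatomic_left,true_anatomic_right length-2 vectors
#'   `(anteversion, inclination)` in degrees under the anatomic
#'   definition; inclination in (0, 90), anteversion in (-90, 90).
#' @param pelvis_pose a [rigid3()] applied to the whole model.
#' @param mesh_resolution target triangle edge length, mm.
#' @param shell_mm cup shell wall thickness, mm.
#' @param notch if `TRUE`, rim-point generation skips a 60 degree sector
#'   (emulating the acetabular notch being excluded from the picks).
#' @param n_rim number of rim points generated per hip.
#' @param seed integer seed recorded with the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
                         pt_left = c(-25, 0, -90), pt_right = c(25, 0, -90),
                         cup_center_left = c(-90, -25, -60),
                         cup_center_right = c(90, -25, -60),
                         cup_radius = 25,
                         true_anatomic_left = c(20, 55),
                         true_anatomic_right = c(20, 55),
                         pelvis_pose = rigid3(),
                         mesh_resolution = 1,
                         shell_mm = 3,
                         notch = FALSE,
                         n_rim = 20,
                         seed = 1L) {
  if (cup_radius <= 0) stop("cup_radius must be > 0")
  for (ta in list(true_anatomic_left, true_anatomic_right)) {
    if (ta[2] <= 0 || ta[2] >= 90) stop("inclination must lie in (0, 90)")
    if (ta[1] <= -90 || ta[1] >= 90) stop("anteversion must lie in (-90, 90)")
  }
  if (!inherits(pelvis_pose, "rigid3")) stop("pelvis_pose must be a rigid3")
  if (mesh_resolution <= 0) stop("mesh_resolution must be > 0")
  spec <- structure(list(
    asis_left = as.numeric(asis_left), asis_right = as.numeric(asis_right),
    pt_left = as.numeric(pt_left), pt_right = as.numeric(pt_right),
    cup_center_left = as.numeric(cup_center_left),
    cup_center_right = as.numeric(cup_center_right),
    cup_radius = cup_radius,
    true_anatomic_left = as.numeric(true_anatomic_left),
    true_anatomic_right = as.numeric(true_anatomic_right),
    pelvis_pose = pelvis_pose, mesh_resolution = mesh_resolution,
    shell_mm = shell_mm, notch = isTRUE(notch), n_rim = as.integer(n_rim),
    seed = as.integer(seed)), class = "phantom_spec")
  invisible(phantom_intrinsics(spec))   # validates geometry
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> cup radius %.1f mm, anatomic (AV, AI): ",
                     "left (%.1f, %.1f), right (%.1f, %.1f)\n"),
              x$cup_radius, x$true_anatomic_left[1], x$true_anatomic_left[2],
              x$true_anatomic_right[1], x$true_anatomic_right[2]))
  invisible(x)
}

# Derive the intrinsic frame and intrinsic-coordinate geometry parameters
# from a spec; validates landmark symmetry and cup clearances.
phantom_intrinsics <- function(spec) {
  al <- spec$asis_left; ar <- spec$asis_right
  pl <- spec$pt_left; pr <- spec$pt_right
  origin <- (al + ar) / 2
  X <- unitize(ar - al)
  ptm <- (pl + pr) / 2
  sup <- origin - ptm
  Zr <- sup - sum(sup * X) * X
  if (vnorm(Zr) < 1e-6) stop("ASIS line and PT midpoint are collinear; APP undefined")
  Z <- unitize(Zr)
  Y <- pracma_cross(Z, X)
  axes <- cbind(X, Y, Z)
  to_intr <- function(p) drop(t(axes) %*% (as.numeric(p) - origin))
  # symmetry checks
  if (max(abs(to_intr(al) + to_intr(ar))) > 1e-6)
    stop("ASIS landmarks are not mirror-symmetric about the mid plane")
  pli <- to_intr(pl); pri <- to_intr(pr)
  if (abs(pli[1] + pri[1]) > 1e-6 || max(abs(pli[2:3] - pri[2:3])) > 1e-6)
    stop("PT landmarks are not mirror-symmetric about the mid plane")
  if (max(abs(c(pli[2], pri[2]))) > 1e-6)
    stop("PT landmarks must lie in the anterior pelvic plane of the spec")
  cli <- to_intr(spec$cup_center_left); cri <- to_intr(spec$cup_center_right)
  # mirror of intrinsic (x, y, z) is (-x, y, z)
  if (max(abs(c(cli[1] + cri[1], cli[2] - cri[2], cli[3] - cri[3]))) > 1e-6)
    stop("cup centers are not mirror-symmetric about the mid plane")
  w <- to_intr(ar)[1]
  q <- pri[1]
  h <- -pri[3]
  if (q <= 0 || w <= q) stop("landmarks do not form a valid pelvis (need 0 < PT half-span < ASIS half-span)")
  if (h <= 20) stop("PT drop below the ASIS level must exceed 20 mm")
  r_out <- spec$cup_radius + spec$shell_mm
  # right-side solid boxes in intrinsic coordinates (left is the mirror)
  slab <- rbind(lo = c(w - 65, -40, -30), hi = c(w + 20, -10, 40))
  bar <- rbind(lo = c(-q - 10, -26, -h - 12), hi = c(q + 10, -8, -h + 12))
  ramus <- rbind(lo = c(q, -30, -h - 2), hi = c(q + 35, -12, -h + 14))
  vstrut <- rbind(lo = c(w - 72, -32, -h + 10), hi = c(w - 60, -16, -25))
  cup <- cri
  if (cup[3] + r_out > -26)
    stop("cup sits too high; it would intersect the iliac slab region")
  cupstrut <- rbind(lo = c(cup[1] - 6, cup[2] - 6, cup[3] + r_out - 1),
                    hi = c(cup[1] + 6, cup[2] + 6, -25))
  # cup outer sphere must clear the iliac slab and the free struts
  clear <- function(box, label, allow = 0) {
    d <- point_box_distance(cup, box)
    if (d < r_out - allow) stop("cup intersects the ", label)
  }
  clear(slab, "iliac slab")
  clear(vstrut, "iliac strut")
  clear(ramus, "superior ramus")
  list(origin = origin, axes = axes, w = w, q = q, h = h,
       cup_right = cri, r_out = r_out,
       boxes_right = list(slab = slab, ramus = ramus, vstrut = vstrut,
                          cupstrut = cupstrut),
       bar = bar)
}

point_box_distance <- function(p, box) {
  d <- pmax(box["lo", ] - p, 0, p - box["hi", ])
  sqrt(sum(d^2))
}

# intrinsic-frame unit axis (x, y, z components) for a side given anatomic
# angles; (l, a, s) with l mapped to +x on the right, -x on the left
anatomic_axis_intrinsic <- function(true_anatomic, side) {
  av <- deg2rad(true_anatomic[1]); inc <- deg2rad(true_anatomic[2])
  l <- sin(inc) * cos(av); a <- sin(inc) * sin(av); s <- -cos(inc)
  c(if (side == "right") l else -l, a, s)
}

#' Generate a standardized synthetic pelvis with ground truth
#'
#' Builds the watertight schematic pelvis mesh (two iliac slabs with
#' rounded ASIS prominences, a pubic bar with PT prominences, connecting
#' struts, and two hemispherical cup shells whose opening-plane normals
#' realize exactly the requested anatomic angles), the initial landmark
#' picks plus analytic rim points, and the exact expected measurements.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `standard_pelvis` with elements `mesh`
#'   ([pelvic_mesh()]), `landmarks` ([pelvic_landmarks()], posed), and
#'   `truth` (class `phantom_truth`: planes, per-side rim circles, per-side
#'   per-definition angles, posture).
#' @export
make_standard_pelvis <- function(spec) {
  geo <- phantom_intrinsics(spec)
  res <- spec$mesh_resolution
  # world map: p_world = pose(origin + axes p_intr)
  M <- rigid3(spec$pelvis_pose$R %*% geo$axes,
              drop(spec$pelvis_pose$R %*% geo$origin) + spec$pelvis_pose$t)
  mirror_mesh <- function(m) {
    v <- m$vertices; v[, 1] <- -v[, 1]
    pelvic_mesh(v, m$faces[, c(1, 3, 2)])
  }
  body_right <- c(
    lapply(geo$boxes_right, function(b) box_mesh(b["lo", ], b["hi", ], edge = res)),
    list(asis_bump = uv_sphere_mesh(c(geo$w, -8, 0), 8, edge = res, pole_axis = c(0, 1, 0)),
         pt_bump = uv_sphere_mesh(c(geo$q, -8, -geo$h), 8, edge = res, pole_axis = c(0, 1, 0))))
  body_left <- lapply(body_right, mirror_mesh)
  # the cups are built per side so the two hips can carry different angles;
  # the ASIS-region geometry stays an exact mirror pair regardless
  cup_right <- cup_shell_mesh(geo$cup_right, spec$cup_radius, geo$r_out,
                              anatomic_axis_intrinsic(spec$true_anatomic_right, "right"),
                              edge = res)
  cup_left <- cup_shell_mesh(geo$cup_right * c(-1, 1, 1), spec$cup_radius, geo$r_out,
                             anatomic_axis_intrinsic(spec$true_anatomic_left, "left"),
                             edge = res)
  bar <- box_mesh(geo$bar["lo", ], geo$bar["hi", ], edge = res)
  mesh_intr <- merge_meshes(c(body_right, body_left,
                              list(cup_right = cup_right, cup_left = cup_left,
                                   bar = bar)))
  mesh <- pelvic_mesh(apply_rigid(mesh_intr$vertices, M), mesh_intr$faces)

  rim_points <- function(side) {
    cen <- if (side == "right") geo$cup_right else geo$cup_right * c(-1, 1, 1)
    ax <- anatomic_axis_intrinsic(spec[[paste0("true_anatomic_", side)]], side)
    B <- orthobasis(ax)
    # place the notch sector around the in-plane direction closest to inferior
    if (spec$notch) {
      inf_dir <- c(0, 0, -1) - sum(c(0, 0, -1) * ax) * ax
      phi0 <- atan2(sum(inf_dir * B[, 2]), sum(inf_dir * B[, 1]))
      span <- 2 * pi - deg2rad(60)
      phi <- phi0 + deg2rad(30) + span * (seq_len(spec$n_rim) - 0.5) / spec$n_rim
    } else {
      phi <- 2 * pi * (seq_len(spec$n_rim) - 1) / spec$n_rim
    }
    p <- sweep(outer(cos(phi), B[, 1] * spec$cup_radius) +
               outer(sin(phi), B[, 2] * spec$cup_radius), 2, -cen)
    apply_rigid(p, M)
  }
  lmk <- pelvic_landmarks(
    apply_rigid(spec$asis_left, spec$pelvis_pose),
    apply_rigid(spec$asis_right, spec$pelvis_pose),
    apply_rigid(spec$pt_left, spec$pelvis_pose),
    apply_rigid(spec$pt_right, spec$pelvis_pose),
    rim_left = rim_points("left"), rim_right = rim_points("right"))

  angles_for <- function(side) {
    ta <- spec[[paste0("true_anatomic_", side)]]
    ax_las <- angles_to_axis("anatomic", ta[1], ta[2])
    lapply(stats::setNames(ANGLE_DEFINITIONS, ANGLE_DEFINITIONS),
           function(d) axis_to_angles(ax_las, d, side = side))
  }
  frame_true <- structure(list(origin = apply_rigid(geo$origin, spec$pelvis_pose)[1, ],
                               axes = M$R), class = "pelvic_frame")
  truth <- structure(list(
    app = transform_plane(plane3(c(0, 1, 0), 0), M),
    msp = transform_plane(plane3(c(1, 0, 0), 0), M),
    tpp = transform_plane(plane3(c(0, 0, 1), 0), M),
    rim_circle = list(
      left = list(center = apply_rigid(geo$cup_right * c(-1, 1, 1), M)[1, ],
                  radius = spec$cup_radius,
                  normal = drop(M$R %*% anatomic_axis_intrinsic(spec$true_anatomic_left, "left"))),
      right = list(center = apply_rigid(geo$cup_right, M)[1, ],
                   radius = spec$cup_radius,
                   normal = drop(M$R %*% anatomic_axis_intrinsic(spec$true_anatomic_right, "right")))),
    angles = list(left = angles_for("left"), right = angles_for("right")),
    posture = posture_angles(frame_true)), class = "phantom_truth")
  structure(list(mesh = mesh, landmarks = lmk, truth = truth, spec = spec),
            class = "standard_pelvis")
}

#' @export
print.standard_pelvis <- function(x, ...) {
  cat("<standard_pelvis>\n  ")
  print(x$mesh)
  cat(sprintf("  posture (tilt, rotation, obliqueness): (%.2f, %.2f, %.2f) deg\n",
              x$truth$posture[1], x$truth$posture[2], x$truth$posture[3]))
  invisible(x)
}

#' Six ground-truth angles of a phantom as a named vector
#'
#' @param truth a `phantom_truth` (from [make_standard_pelvis()]).
#' @param side `"left"` or `"right"`.
#' @return named vector of the six angles
#'   (`anatomic_av`, `anatomic_inc`, ..., `operative_inc`), degrees.
#' @export
truth_angles <- function(truth, side = c("left", "right")) {
  side <- match.arg(side)
  a <- truth$angles[[side]]
  out <- unlist(lapply(ANGLE_DEFINITIONS, function(d)
    c(a[[d]]$anteversion, a[[d]]$inclination)))
  stats::setNames(out, c("anatomic_av", "anatomic_inc", "radiographic_av",
                         "radiographic_inc", "operative_av", "operative_inc"))
}

#' Voxel ball-in-socket phantom for the segmentation stage
#'
#' Voxelizes the schematic pelvis solids analytically onto a regular
#' grid and adds a femoral-head ball inside the right cup, separated
#' from the socket surface by a joint-space gap of `gap_mm`.  Bone
#' voxels take intensity `bone`, background 0, plus optional additive
#' Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param gap_mm joint-space width, mm (must be >= the voxel spacing).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param spacing voxel spacing, mm.
#' @param seed RNG seed for the noise.
#' @param bone bone intensity (default 1000).
#' @return list of class `voxel_phantom`: `volume` (a [voxel_volume()]),
#'   `ball` (list `center`, `radius`, world mm), `gap_mm`, `spec`.
#' @export
make_ct_phantom <- function(spec, gap_mm = 2, noise_sd = 0, spacing = 1,
                            seed = spec$seed, bone = 1000) {
  if (gap_mm < spacing)
    stop("joint-space gap must be at least one voxel spacing")
  geo <- phantom_intrinsics(spec)
  M <- rigid3(spec$pelvis_pose$R %*% geo$axes,
              drop(spec$pelvis_pose$R %*% geo$origin) + spec$pelvis_pose$t)
  Minv <- invert_rigid(M)
  # intrinsic bounding box over all solids
  mirror_box <- function(b) rbind(lo = c(-b["hi", 1], b["lo", 2:3]),
                                  hi = c(-b["lo", 1], b["hi", 2:3]))
  boxes <- c(geo$boxes_right, lapply(geo$boxes_right, mirror_box), list(bar = geo$bar))
  spheres <- list(list(c = c(geo$w, -8, 0), r = 8),
                  list(c = c(-geo$w, -8, 0), r = 8),
                  list(c = c(geo$q, -8, -geo$h), r = 8),
                  list(c = c(-geo$q, -8, -geo$h), r = 8))
  cups <- list(
    list(c = geo$cup_right, ax = anatomic_axis_intrinsic(spec$true_anatomic_right, "right")),
    list(c = geo$cup_right * c(-1, 1, 1), ax = anatomic_axis_intrinsic(spec$true_anatomic_left, "left")))
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (b in boxes) { lo <- pmin(lo, b["lo", ]); hi <- pmax(hi, b["hi", ]) }
  for (s in spheres) { lo <- pmin(lo, s$c - s$r); hi <- pmax(hi, s$c + s$r) }
  for (cp in cups) { lo <- pmin(lo, cp$c - geo$r_out); hi <- pmax(hi, cp$c + geo$r_out) }
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  wc <- apply_rigid(corners, M)
  wlo <- floor(apply(wc, 2, min) - 2); whi <- ceiling(apply(wc, 2, max) + 2)
  dims <- as.integer(ceiling((whi - wlo) / spacing)) + 1L
  # voxel centers in intrinsic coordinates, chunked along z to bound memory
  arr <- array(FALSE, dims)
  xs <- wlo[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- wlo[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- wlo[3] + (seq_len(dims[3]) - 1) * spacing
  ball_c_intr <- geo$cup_right
  ball_r <- spec$cup_radius - gap_mm
  if (ball_r <= 0) stop("gap is larger than the cup radius")
  ball_arr <- array(FALSE, dims)
  slab_xy <- as.matrix(expand.grid(x = xs, y = ys))
  for (k in seq_len(dims[3])) {
    pw <- cbind(slab_xy, zs[k])
    p <- apply_rigid(pw, Minv)
    inside <- rep(FALSE, nrow(p))
    for (b in boxes)
      inside <- inside | (p[, 1] >= b["lo", 1] & p[, 1] <= b["hi", 1] &
                          p[, 2] >= b["lo", 2] & p[, 2] <= b["hi", 2] &
                          p[, 3] >= b["lo", 3] & p[, 3] <= b["hi", 3])
    for (s in spheres) {
      d2 <- (p[, 1] - s$c[1])^2 + (p[, 2] - s$c[2])^2 + (p[, 3] - s$c[3])^2
      inside <- inside | d2 <= s$r^2
    }
    for (cp in cups) {
      dx <- p[, 1] - cp$c[1]; dy <- p[, 2] - cp$c[2]; dz <- p[, 3] - cp$c[3]
      d2 <- dx^2 + dy^2 + dz^2
      closed <- dx * cp$ax[1] + dy * cp$ax[2] + dz * cp$ax[3] <= 0
      inside <- inside | (d2 >= spec$cup_radius^2 & d2 <= geo$r_out^2 & closed)
    }
    arr[, , k] <- inside
    d2b <- (p[, 1] - ball_c_intr[1])^2 + (p[, 2] - ball_c_intr[2])^2 +
           (p[, 3] - ball_c_intr[3])^2
    ball_arr[, , k] <- d2b <= ball_r^2
  }
  vals <- array(0, dims)
  vals[arr | ball_arr] <- bone
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + array(stats::rnorm(prod(dims), 0, noise_sd), dims)
  }
  structure(list(volume = voxel_volume(vals, spacing = spacing, origin = wlo),
                 ball = list(center = apply_rigid(ball_c_intr, M)[1, ], radius = ball_r),
                 bone_mask = voxel_volume(array(arr, dims), spacing = spacing, origin = wlo),
                 gap_mm = gap_mm, bone = bone, spec = spec),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom>\n  ")
  print(x$volume)
  cat(sprintf("  femoral head: radius %.1f mm, joint gap %.1f mm\n",
              x$ball$radius, x$gap_mm))
  invisible(x)
}

# truncated-normal sampler by inverse-CDF (vectorized)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  a <- stats::pnorm(lo, mean, sd); b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + (b - a) * stats::runif(n), mean, sd)
}

#' Default population parameters for simulated subjects
#'
#' Per-sex anatomic anteversion/inclination means with truncation at the
#' published cohort ranges and standard deviations set to range/4, plus
#' bilateral (left-minus-right) difference distributions.
#'
#' @return nested list of population parameters (degrees).
#' @export
population_defaults <- function() {
  list(
    male = list(av = list(mean = 18.8, sd = (31.0 - 9.1) / 4, lo = 9.1, hi = 31.0),
                inc = list(mean = 52.8, sd = (60.1 - 45.6) / 4, lo = 45.6, hi = 60.1)),
    female = list(av = list(mean = 21.5, sd = (33.1 - 5.9) / 4, lo = 5.9, hi = 33.1),
                  inc = list(mean = 54.3, sd = (60.5 - 47.8) / 4, lo = 47.8, hi = 60.5)),
    bilateral = list(av = list(mean = 0.3, sd = 9.1 / 3, lo = -9.1, hi = 9.1),
                     inc = list(mean = 0.8, sd = 5.9 / 3, lo = -5.9, hi = 5.9)))
}

#' Simulate a population of subjects with true acetabular angles
#'
#' Per-subject anatomic angles are drawn from truncated normal
#' distributions per sex; the bilateral (left minus right) difference is
#' drawn separately and split evenly between the sides.
#'
#' @param n_per_sex subjects per sex (>= 2).
#' @param params parameter list as in [population_defaults()].
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `sex`, `aa_left`,
#'   `ai_left`, `aa_right`, `ai_right` (degrees).
#' @export
sample_population <- function(n_per_sex, params = population_defaults(), seed = 1L) {
  if (n_per_sex < 2) stop("n_per_sex must be >= 2")
  set.seed(seed)
  one_sex <- function(sex) {
    p <- params[[sex]]
    av <- rtruncnorm(n_per_sex, p$av$mean, p$av$sd, p$av$lo, p$av$hi)
    inc <- rtruncnorm(n_per_sex, p$inc$mean, p$inc$sd, p$inc$lo, p$inc$hi)
    dav <- rtruncnorm(n_per_sex, params$bilateral$av$mean, params$bilateral$av$sd,
                      params$bilateral$av$lo, params$bilateral$av$hi)
    dinc <- rtruncnorm(n_per_sex, params$bilateral$inc$mean, params$bilateral$inc$sd,
                       params$bilateral$inc$lo, params$bilateral$inc$hi)
    data.frame(sex = sex,
               aa_left = av + dav / 2, ai_left = inc + dinc / 2,
               aa_right = av - dav / 2, ai_right = inc - dinc / 2)
  }
  out <- rbind(one_sex("male"), one_sex("female"))
  out <- cbind(subject = seq_len(nrow(out)), out)
  out
}

#' Simulated-rater reliability trials on phantom models
#'
#' For each (model, rater, trial), the four initial landmark picks are
#' perturbed tangentially on the mesh surface within
#' `landmark_noise_mm` (uniform distance, uniform direction, snapped to
#' the nearest mesh vertex) and each rim pick is perturbed along the
#' socket sphere within `rim_noise_mm`; the full measurement pipeline is
#' then run and all six angles recorded per hip.
#'
#' @param models list of `standard_pelvis` objects (or [phantom_spec()]s,
#'   which are generated on the fly).
#' @param n_raters,n_trials number of simulated raters and repeated trials.
#' @param landmark_noise_mm,rim_noise_mm perturbation magnitudes, mm (>= 0).
#' @param seed RNG seed.
#' @param control measurement options, see [measure_control()].
#' @return data.frame with one row per model x rater x trial x hip:
#'   identifiers plus the six angle columns (degrees); failed hips carry
#'   `NA` angles and the error message in `error`.
#' @export
simulate_raters <- function(models, n_raters = 3, n_trials = 1,
                            landmark_noise_mm = 5, rim_noise_mm = 1,
                            seed = 1L, control = measure_control()) {
  if (landmark_noise_mm < 0 || rim_noise_mm < 0)
    stop("noise magnitudes must be >= 0")
  models <- lapply(models, function(m)
    if (inherits(m, "phantom_spec")) make_standard_pelvis(m) else m)
  set.seed(seed)
  rows <- list()
  for (mi in seq_along(models)) {
    mod <- models[[mi]]
    vn <- vertex_normals(mod$mesh)
    for (ri in seq_len(n_raters)) {
      for (ti in seq_len(n_trials)) {
        lmk <- perturb_landmarks(mod, vn, landmark_noise_mm, rim_noise_mm)
        meas <- tryCatch(measure_acetabulum(mod$mesh, lmk, control = control),
                         error = function(e) e)
        for (side in c("left", "right")) {
          base <- data.frame(model = mi, rater = ri, trial = ti, side = side)
          if (inherits(meas, "error")) {
            rows[[length(rows) + 1L]] <- cbind(base, angle_row(NULL),
                                               error = conditionMessage(meas))
          } else if (is.null(meas$hips[[side]])) {
            rows[[length(rows) + 1L]] <- cbind(base, angle_row(NULL),
                                               error = "hip not measured")
          } else {
            rows[[length(rows) + 1L]] <- cbind(base, angle_row(meas$hips[[side]]),
                                               error = NA_character_)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

angle_row <- function(hip) {
  nm <- c("anatomic_av", "anatomic_inc", "radiographic_av",
          "radiographic_inc", "operative_av", "operative_inc")
  if (is.null(hip)) {
    out <- as.data.frame(as.list(stats::setNames(rep(NA_real_, 6), nm)))
    return(out)
  }
  vals <- unlist(lapply(ANGLE_DEFINITIONS, function(d)
    c(hip$angles[[d]]$anteversion, hip$angles[[d]]$inclination)))
  as.data.frame(as.list(stats::setNames(vals, nm)))
}

# tangential perturbation of landmark and rim picks for one trial
perturb_landmarks <- function(model, vnormals, landmark_noise_mm, rim_noise_mm) {
  mesh <- model$mesh; lmk <- model$landmarks
  perturb_pick <- function(p) {
    if (landmark_noise_mm == 0) return(p)
    i <- nearest_neighbours(matrix(p, 1), mesh$vertices)
    n <- vnormals[i, ]
    B <- orthobasis(n)
    th <- stats::runif(1, 0, 2 * pi)
    dmm <- stats::runif(1, 0, landmark_noise_mm)
    q <- mesh$vertices[i, ] + dmm * (cos(th) * B[, 1] + sin(th) * B[, 2])
    j <- nearest_neighbours(matrix(q, 1), mesh$vertices)
    mesh$vertices[j, ]
  }
  perturb_rim <- function(points, side) {
    if (rim_noise_mm == 0) return(points)
    cen <- model$truth$rim_circle[[side]]$center
    r <- vnorm(points[1, ] - cen)
    t(apply(points, 1, function(p) {
      radial <- unitize(p - cen)
      B <- orthobasis(radial)
      th <- stats::runif(1, 0, 2 * pi)
      dmm <- stats::runif(1, 0, rim_noise_mm)
      cen + r * unitize(radial + (dmm / r) * (cos(th) * B[, 1] + sin(th) * B[, 2]))
    }))
  }
  pelvic_landmarks(perturb_pick(lmk$asis_left), perturb_pick(lmk$asis_right),
                   perturb_pick(lmk$pt_left), perturb_pick(lmk$pt_right),
                   rim_left = perturb_rim(lmk$rim_left, "left"),
                   rim_right = perturb_rim(lmk$rim_right, "right"))
}
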