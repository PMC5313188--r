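# Voxel-volume container and the segmentation stage: spherical masking of
# the femoral head, region growing, and isosurface extraction.

#' Scalar voxel volume
#'
#' Regular-grid scalar volume.  The world position of voxel `(i, j, k)`
#' is `origin + (i-1, j-1, k-1) * spacing` (mm, scanner frame).
#'
#' @param intensities 3D numeric array.
#' @param spacing voxel spacing, mm (scalar or length-3).
#' @param origin world position of voxel `[1,1,1]`, mm.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3) stop("intensities must be a 3D array")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# world coordinates of all voxel centers (n x 3); heavy, use sparingly
voxel_centers <- function(vol) {
  d <- dim(vol$intensities)
  cbind(vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
        rep(vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2], each = d[1]),
        rep(vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3],
            each = d[1] * d[2]))[rep_len(TRUE, prod(d)), , drop = FALSE]
}

#' Read and write volumes as NIfTI
#'
#' Spacing is stored in `pixdim` and the origin in the sform affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [voxel_volume()].
#' @return `read_volume`: a [voxel_volume()]; `write_volume`: the path.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- RNifti::xform(im)
  voxel_volume(array(as.numeric(im), dim = dim(im)),
               spacing = RNifti::pixdim(im)[1:3],
               origin = aff[1:3, 4])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$intensities)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  im <- RNifti::asNifti(im, reference = list(pixdim = c(-1, vol$spacing, 1, 1, 1, 1)))
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Least-squares sphere fit
#'
#' Algebraic fit by the linearized normal equations, minimizing
#' `sum((|p - c|^2 - r^2)^2)`; exact on noiseless spherical data.
#'
#' @param points n x 3 matrix of surface points (n >= 4, non-coplanar).
#' @return list with `center` (3-vector, mm) and `radius` (mm), class `sphere3`.
#' @export
fit_sphere <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_ <- qr(A)
  if (qr_$rank < 4) stop("degenerate (coplanar) points: sphere fit singular")
  beta <- qr.coef(qr_, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate points: non-positive squared radius")
  structure(list(center = unname(center), radius = sqrt(r2)), class = "sphere3")
}

#' @export
print.sphere3 <- function(x, ...) {
  cat(sprintf("<sphere3> center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Erase a spherical region from a volume
#'
#' Voxels whose centers lie within `radius + margin_mm` of the sphere
#' center are set to the background intensity; all others are unchanged.
#' Used to remove the femoral head before segmenting the pelvis.
#'
#' @param vol a [voxel_volume()].
#' @param sphere a fitted sphere (list with `center`, `radius`).
#' @param margin_mm extra radial margin, mm.
#' @param background intensity written inside the mask (default 0).
#' @return the masked [voxel_volume()].
#' @export
apply_spherical_mask <- function(vol, sphere, margin_mm = 0, background = 0) {
  d <- dim(vol$intensities)
  r <- sphere$radius + margin_mm
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  dx2 <- (xs - sphere$center[1])^2
  dy2 <- (ys - sphere$center[2])^2
  dz2 <- (zs - sphere$center[3])^2
  ix <- which(dx2 <= r^2); iy <- which(dy2 <= r^2); iz <- which(dz2 <= r^2)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  sub <- outer(dx2[ix], dy2[iy], `+`)
  sub <- outer(sub, dz2[iz], `+`) <= r^2
  block <- vol$intensities[ix, iy, iz, drop = FALSE]
  block[sub] <- background
  vol$intensities[ix, iy, iz] <- block
  vol
}

#' Region growing segmentation
#'
#' Returns the maximal 26-connected component of voxels with intensity in
#' `[lo, hi]` that contains the seed voxel.
#'
#' @param vol a [voxel_volume()].
#' @param seed_voxel integer (i, j, k) voxel index (1-based).
#' @param lo,hi inclusive intensity window.
#' @return a [voxel_volume()] whose intensities are a logical mask.
#' @export
region_grow <- function(vol, seed_voxel, lo, hi) {
  if (lo > hi) stop("lo must be <= hi")
  d <- dim(vol$intensities)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3 || any(seed_voxel < 1) || any(seed_voxel > d))
    stop("seed voxel outside the grid")
  sv <- vol$intensities[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  if (sv < lo || sv > hi) stop("seed intensity outside [lo, hi]")
  in_range <- vol$intensities >= lo & vol$intensities <= hi
  visited <- array(FALSE, d)
  lin <- function(ijk) ijk[, 1] + (ijk[, 2] - 1L) * d[1] + (ijk[, 3] - 1L) * d[1] * d[2]
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  frontier <- matrix(seed_voxel, 1)
  visited[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
      sweep(frontier, 2, -offs[r, ])))
    ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
          cand[, 2] >= 1L & cand[, 2] <= d[2] &
          cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    li <- lin(cand)
    keep <- !duplicated(li)
    cand <- cand[keep, , drop = FALSE]; li <- li[keep]
    new <- in_range[li] & !visited[li]
    visited[li[new]] <- TRUE
    frontier <- cand[new, , drop = FALSE]
  }
  voxel_volume(array(visited, d), spacing = vol$spacing, origin = vol$origin)
}

# ---- marching tetrahedra isosurface ----------------------------------------

# Kuhn/Freudenthal 6-tetrahedron cube split; corner numbering of the cube:
# 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) 5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
.kuhn_tets <- rbind(
  c(1, 2, 4, 8),   # x, y, z
  c(1, 2, 6, 8),   # x, z, y
  c(1, 3, 4, 8),   # y, x, z
  c(1, 3, 7, 8),   # y, z, x
  c(1, 5, 6, 8),   # z, x, y
  c(1, 5, 7, 8))   # z, y, x

.cube_corner_delta <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

#' Extract a surface mesh from a volume
#'
#' Isosurface of the scalar field at `level` (default 0.5, the midlevel of
#' a binarized mask), using a marching-tetrahedra traversal of the
#' Freudenthal 6-tetrahedron cube decomposition.  The decomposition is
#' translation-invariant, so the surface is watertight for solid masks.
#' Vertices are returned in mm with spacing and origin applied; triangle
#' winding is outward (away from the super-level set).
#'
#' @param vol a [voxel_volume()]; typically a binary mask from [region_grow()].
#' @param level iso level (default 0.5).
#' @return a [pelvic_mesh()].
#' @export
extract_surface <- function(vol, level = 0.5) {
  arr <- vol$intensities
  d <- dim(arr)
  inside <- arr >= level
  if (!any(inside)) stop("empty mask: no voxels at or above the iso level")
  if (all(inside)) stop("mask fills the whole grid; no surface")
  storage.mode(arr) <- "double"
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # count inside corners per cube (vectorized over the cube grid)
  cs <- function(dx, dy, dz)
    inside[(1 + dx):(nx - 1 + dx), (1 + dy):(ny - 1 + dy), (1 + dz):(nz - 1 + dz)]
  cnt <- array(0L, d - 1L)
  for (r in seq_len(8)) {
    dd <- .cube_corner_delta[r, ]
    cnt <- cnt + cs(dd[1], dd[2], dd[3])
  }
  mixed <- which(cnt > 0L & cnt < 8L)
  if (!length(mixed)) stop("no iso crossings found")
  ijk <- arrayInd(mixed, d - 1L)
  base_lin <- ijk[, 1] + (ijk[, 2] - 1L) * nx + (ijk[, 3] - 1L) * nx * ny
  corner_off <- .cube_corner_delta %*% c(1L, nx, nx * ny)
  flags <- vals <- NULL
  flags <- matrix(FALSE, length(mixed), 8)
  vals <- matrix(0, length(mixed), 8)
  for (r in seq_len(8)) {
    li <- base_lin + corner_off[r]
    flags[, r] <- inside[li]
    vals[, r] <- arr[li]
  }
  # corner world coordinates
  corner_xyz <- function(r) {
    dd <- .cube_corner_delta[r, ]
    cbind(vol$origin[1] + (ijk[, 1] - 1L + dd[1]) * vol$spacing[1],
          vol$origin[2] + (ijk[, 2] - 1L + dd[2]) * vol$spacing[2],
          vol$origin[3] + (ijk[, 3] - 1L + dd[3]) * vol$spacing[3])
  }
  cxyz <- lapply(1:8, corner_xyz)

  tri_v <- list()   # each element: n x 9 matrix (three vertices per row)
  ref_p <- list()   # reference inside point per triangle for orientation
  edge_point <- function(sel, ci, cj) {
    # interpolated iso point on edge corner ci -> cj for cube rows `sel`
    vi <- vals[cbind(sel, ci)]; vj <- vals[cbind(sel, cj)]
    t <- (level - vi) / (vj - vi)
    t[!is.finite(t)] <- 0.5
    t <- pmin(1, pmax(0, t))
    pi_ <- cxyz[[ci]][sel, , drop = FALSE]
    pj_ <- cxyz[[cj]][sel, , drop = FALSE]
    pi_ + t * (pj_ - pi_)
  }
  for (tt in seq_len(nrow(.kuhn_tets))) {
    tc <- .kuhn_tets[tt, ]
    fl <- flags[, tc, drop = FALSE]
    code <- fl[, 1] + 2L * fl[, 2] + 4L * fl[, 3] + 8L * fl[, 4]
    for (case in 1:14) {
      sel <- which(code == case)
      if (!length(sel)) next
      ins <- which(bitwAnd(case, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      # reference inside point: mean of inside corners
      rp <- Reduce(`+`, lapply(ins, function(i) cxyz[[tc[i]]][sel, , drop = FALSE])) / length(ins)
      if (length(ins) == 1 || length(ins) == 3) {
        if (length(ins) == 1) { a <- ins; bcd <- outs } else { a <- outs; bcd <- ins }
        p1 <- edge_point(sel, tc[a], tc[bcd[1]])
        p2 <- edge_point(sel, tc[a], tc[bcd[2]])
        p3 <- edge_point(sel, tc[a], tc[bcd[3]])
        tri_v[[length(tri_v) + 1L]] <- cbind(p1, p2, p3)
        ref_p[[length(ref_p) + 1L]] <- rp
      } else {  # 2 inside, 2 outside: quad
        a <- ins[1]; b <- ins[2]; c_ <- outs[1]; dd <- outs[2]
        pac <- edge_point(sel, tc[a], tc[c_])
        pad <- edge_point(sel, tc[a], tc[dd])
        pbc <- edge_point(sel, tc[b], tc[c_])
        pbd <- edge_point(sel, tc[b], tc[dd])
        tri_v[[length(tri_v) + 1L]] <- cbind(pac, pad, pbd)
        ref_p[[length(ref_p) + 1L]] <- rp
        tri_v[[length(tri_v) + 1L]] <- cbind(pac, pbd, pbc)
        ref_p[[length(ref_p) + 1L]] <- rp
      }
    }
  }
  TV <- do.call(rbind, tri_v)
  RP <- do.call(rbind, ref_p)
  p1 <- TV[, 1:3, drop = FALSE]; p2 <- TV[, 4:6, drop = FALSE]
  p3 <- TV[, 7:9, drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cen <- (p1 + p2 + p3) / 3
  flip <- rowSums(n * (cen - RP)) < 0
  tmp <- p2[flip, , drop = FALSE]
  p2[flip, ] <- p3[flip, , drop = FALSE]
  p3[flip, ] <- tmp
  # drop degenerate (zero-area) triangles produced when an iso point falls
  # exactly on a corner (cannot happen for binary masks)
  area2 <- rowSums(n^2)
  keep <- area2 > 0
  nt <- sum(keep)
  V <- matrix(0, nt * 3, 3)
  V[seq(1, nt * 3, by = 3), ] <- p1[keep, , drop = FALSE]
  V[seq(2, nt * 3, by = 3), ] <- p2[keep, , drop = FALSE]
  V[seq(3, nt * 3, by = 3), ] <- p3[keep, , drop = FALSE]
  F_ <- matrix(seq_len(nt * 3), ncol = 3, byrow = TRUE)
  weld_vertices(pelvic_mesh(V, F_), digits = 6)
}
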