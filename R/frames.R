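# Intrinsic pelvic coordinate system: anterior pelvic plane (APP) with
# iterative landmark refinement, mid-sagittal plane (MSP) as the ICP
# mirror plane of the ASIS regions, transverse pelvic plane (TPP), and
# pelvic posture angles against the scanner frame.

#' Pelvic landmarks
#'
#' Initial manual picks: bilateral anterior superior iliac spines (ASIS),
#' bilateral pubic tubercles (PT), and per-hip acetabular rim point lists
#' (about 20 points each, picked excluding the acetabular notch).
#'
#' @param asis_left,asis_right,pt_left,pt_right numeric 3-vectors, mm.
#' @param rim_left,rim_right optional n x 3 matrices of rim points
#'   (>= 6 points when present).
#' @return object of class `pelvic_landmarks`.
#' @export
pelvic_landmarks <- function(asis_left, asis_right, pt_left, pt_right,
                             rim_left = NULL, rim_right = NULL) {
  al <- as.numeric(asis_left); ar <- as.numeric(asis_right)
  pl <- as.numeric(pt_left); pr <- as.numeric(pt_right)
  if (vnorm(al - ar) < 1e-6) stop("ASIS points must be distinct")
  if (vnorm(pl - pr) < 1e-6) stop("PT points must be distinct")
  chk_rim <- function(r, side) {
    if (is.null(r)) return(NULL)
    r <- rbind3(r)
    if (nrow(r) < 6) stop("rim point list for ", side, " hip needs >= 6 points")
    r
  }
  structure(list(asis_left = al, asis_right = ar, pt_left = pl, pt_right = pr,
                 rim_left = chk_rim(rim_left, "left"),
                 rim_right = chk_rim(rim_right, "right")),
            class = "pelvic_landmarks")
}

#' Read and write landmarks as JSON
#'
#' Schema: `{"asis_left":[x,y,z], "asis_right":[...], "pt_left":[...],
#' "pt_right":[...], "rim_left":[[...],...], "rim_right":[[...],...]}`,
#' units mm, scanner frame.
#'
#' @param path JSON file path.
#' @param landmarks a [pelvic_landmarks()].
#' @return `read_landmarks`: a [pelvic_landmarks()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.null(x)) NULL else rbind3(x)
  pelvic_landmarks(j$asis_left, j$asis_right, j$pt_left, j$pt_right,
                   rim_left = as_mat(j$rim_left), rim_right = as_mat(j$rim_right))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  x <- unclass(landmarks)
  x <- x[!vapply(x, is.null, TRUE)]
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# transform all landmark coordinates by a rigid pose
transform_landmarks <- function(landmarks, pose) {
  tr <- function(x) if (is.null(x)) NULL else apply_rigid(x, pose)
  pelvic_landmarks(tr(landmarks$asis_left), tr(landmarks$asis_right),
                   tr(landmarks$pt_left), tr(landmarks$pt_right),
                   rim_left = tr(landmarks$rim_left),
                   rim_right = tr(landmarks$rim_right))
}

#' Initial anterior pelvic plane from manual picks
#'
#' Plane through the two ASIS picks and the midpoint of the PT picks,
#' normal oriented anteriorly (away from the mesh centroid).
#'
#' @param landmarks a [pelvic_landmarks()].
#' @param centroid optional mesh centroid used to orient the normal; if
#'   missing, the normal is oriented away from the PT side of the ASIS
#'   line's perpendicular (callers with a mesh should pass its centroid).
#' @return a [plane3()].
#' @export
initial_app <- function(landmarks, centroid = NULL) {
  ptm <- (landmarks$pt_left + landmarks$pt_right) / 2
  plane_from_points(landmarks$asis_left, landmarks$asis_right, ptm,
                    anterior_hint = centroid)
}

#' Iterative refinement of the anterior pelvic plane
#'
#' Fixed-point iteration on the APP: given the current plane normal,
#' within each landmark's neighbourhood of radius `region_radius_mm` the
#' mesh vertex with the largest projection along the normal (the most
#' ventral point) is selected; the plane is refit through the two ASIS
#' vertices and the PT-vertex midpoint; iteration stops when consecutive
#' iterations select the same four vertices.  Ties in the extremal-vertex
#' search are broken by the lowest vertex index, so the refinement is
#' deterministic.  A revisited (cyclic) state falls back to the iterate
#' whose own selected vertices have the largest summed projection, with a
#' warning.
#'
#' @param mesh a [pelvic_mesh()].
#' @param landmarks a [pelvic_landmarks()] with the initial picks.
#' @param region_radius_mm search radius around each current landmark
#'   (default 10 mm).
#' @param max_iter iteration cap.
#' @return list with `plane` (a [plane3()]), `points` (refined
#'   `asis_left`, `asis_right`, `pt_left`, `pt_right` as a named list),
#'   `iterations`, and `converged`.
#' @export
refine_app <- function(mesh, landmarks, region_radius_mm = 10, max_iter = 50) {
  v <- mesh$vertices
  centroid <- colMeans(v)
  cur <- list(asis_left = landmarks$asis_left, asis_right = landmarks$asis_right,
              pt_left = landmarks$pt_left, pt_right = landmarks$pt_right)
  for (nm in names(cur)) {
    d2 <- colSums((t(v) - cur[[nm]])^2)
    if (min(d2) > region_radius_mm^2)
      stop("landmark ", nm, " is farther than the region radius from the mesh")
  }
  pick_extremal <- function(center, normal) {
    d2 <- colSums((t(v) - center)^2)
    cand <- which(d2 <= region_radius_mm^2)
    proj <- v[cand, , drop = FALSE] %*% normal
    cand[which.max(proj)]           # which.max: first (lowest) index on ties
  }
  history <- character()
  states <- list()
  idx <- NULL
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    ptm <- (cur$pt_left + cur$pt_right) / 2
    pl <- plane_from_points(cur$asis_left, cur$asis_right, ptm,
                            anterior_hint = centroid)
    new_idx <- vapply(names(cur), function(nm) pick_extremal(cur[[nm]], pl$normal), 1L)
    key <- paste(new_idx, collapse = ",")
    if (!is.null(idx) && identical(new_idx, idx)) { converged <- TRUE; break }
    if (key %in% history) {
      warning("APP refinement entered a cycle; returning the best iterate")
      break
    }
    history <- c(history, key)
    idx <- new_idx
    cur <- list(asis_left = v[idx[1], ], asis_right = v[idx[2], ],
                pt_left = v[idx[3], ], pt_right = v[idx[4], ])
    states[[length(states) + 1L]] <- cur
    if (it >= max_iter) {
      warning("APP refinement hit the iteration cap; returning the best iterate")
      break
    }
  }
  if (!converged && length(states) > 1) {
    # best iterate: largest summed projection of its points on its own plane normal
    score <- vapply(states, function(s) {
      p <- plane_from_points(s$asis_left, s$asis_right,
                             (s$pt_left + s$pt_right) / 2, anterior_hint = centroid)
      sum(vapply(s, function(q) sum(q * p$normal), 0))
    }, 0)
    cur <- states[[which.max(score)]]
  }
  ptm <- (cur$pt_left + cur$pt_right) / 2
  plane <- plane_from_points(cur$asis_left, cur$asis_right, ptm,
                             anterior_hint = centroid)
  list(plane = plane, points = cur, iterations = it, converged = converged)
}

#' Mid-sagittal plane as the ICP mirror plane of the ASIS regions
#'
#' Collects the mesh vertices within `region_radius_mm` of each refined
#' ASIS point, reflects the combined cloud across an initial candidate
#' plane (through the mid-ASIS point, normal along the ASIS line), and
#' registers the reflected cloud back onto the original cloud with a
#' point-to-point iterative closest-point (ICP) loop (nearest-neighbour
#' matching, SVD rigid update).  The composition of the reflection and
#' the recovered rigid transform is an improper orthogonal map whose
#' invariant plane is returned as the mid-sagittal plane.
#'
#' @param mesh a [pelvic_mesh()].
#' @param asis_points list with `asis_left`, `asis_right` (refined picks).
#' @param region_radius_mm radius of the ASIS point clouds (default 25 mm).
#' @param max_iter,tol ICP iteration cap and RMS-change tolerance (mm).
#' @param max_source_points the reflected (moving) cloud is deterministically
#'   subsampled to at most this many points to bound the cost of
#'   nearest-neighbour matching; the target cloud is kept whole.
#' @param rms_threshold registration is declared divergent if the final
#'   RMS residual exceeds this value, mm.
#' @return a [plane3()] (normal oriented from left ASIS towards right).
#' @export
fit_msp <- function(mesh, asis_points, region_radius_mm = 25,
                    max_iter = 100, tol = 1e-6,
                    max_source_points = 800, rms_threshold = 10) {
  v <- mesh$vertices
  al <- as.numeric(asis_points$asis_left); ar <- as.numeric(asis_points$asis_right)
  d2l <- colSums((t(v) - al)^2); d2r <- colSums((t(v) - ar)^2)
  sel_l <- which(d2l <= region_radius_mm^2)
  sel_r <- which(d2r <= region_radius_mm^2)
  if (length(sel_l) < 50 || length(sel_r) < 50)
    stop("ASIS regions must each contain at least 50 vertices (have ",
         length(sel_l), " / ", length(sel_r), ")")
  cloud <- v[union(sel_l, sel_r), , drop = FALSE]
  mid <- (al + ar) / 2
  u <- unitize(ar - al)
  p0 <- plane3(u, point = mid)
  src0 <- reflect_points(cloud, p0)
  if (nrow(src0) > max_source_points) {
    stride <- seq(1, nrow(src0), length.out = max_source_points)
    src_idx <- unique(round(stride))
  } else src_idx <- seq_len(nrow(src0))
  src <- src0[src_idx, , drop = FALSE]
  # accumulate rigid transform T with src_cur = R src + t
  R_tot <- diag(3); t_tot <- c(0, 0, 0)
  cur <- src
  rms_prev <- Inf
  for (it in seq_len(max_iter)) {
    nn <- nearest_neighbours(cur, cloud)
    fit <- kabsch(cur, cloud[nn, , drop = FALSE])
    cur <- apply_rigid(cur, fit)
    R_tot <- fit$R %*% R_tot
    t_tot <- drop(fit$R %*% t_tot) + fit$t
    rms <- sqrt(mean(rowSums((cur - cloud[nn, , drop = FALSE])^2)))
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
  }
  if (rms > rms_threshold)
    stop(sprintf("ICP failed to register the mirrored ASIS cloud (RMS %.2f mm)", rms))
  # total improper map F(x) = R_tot (H x + 2 d0 u) + t_tot,  H = I - 2 u u'
  H <- diag(3) - 2 * outer(u, u)
  A <- R_tot %*% H
  cvec <- drop(R_tot %*% (2 * p0$offset * u)) + t_tot
  eg <- eigen(A)
  k <- which.min(abs(Re(eg$values) + 1))
  n <- Re(eg$vectors[, k])
  n <- unitize(n)
  if (sum(n * u) < 0) n <- -n
  plane3(n, offset = sum(n * cvec) / 2)
}

# brute-force nearest neighbour indices of each row of `q` in `ref`
nearest_neighbours <- function(q, ref) {
  nq <- nrow(q)
  out <- integer(nq)
  reft <- t(ref)
  ref2 <- colSums(reft^2)
  chunk <- max(1L, floor(2e6 / nrow(ref)))
  for (s in seq(1, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    qq <- q[s:e, , drop = FALSE]
    d <- outer(rowSums(qq^2), ref2, `+`) - 2 * qq %*% reft
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Intrinsic pelvic coordinate frame
#'
#' Builds the orthonormal right-handed pelvic frame: `Y` is the APP
#' normal (anterior), `Z` the APP-MSP intersection direction pointing
#' superiorly (away from the PT midpoint), `X = Y x Z` (towards the
#' subject's right).  The origin is the mid-ASIS point.  The transverse
#' pelvic plane (TPP) passes through the origin with normal `Z`; the MSP
#' is re-orthogonalized against the APP by the minimal rotation so the
#' triad is exactly orthonormal.
#'
#' @param app,msp [plane3()] objects (APP normal anterior; MSP normal
#'   roughly lateral).
#' @param asis_points list with refined `asis_left`, `asis_right`,
#'   `pt_left`, `pt_right`.
#' @return object of class `pelvic_frame`: `origin`, 3 x 3 `axes` matrix
#'   with columns X, Y, Z, and planes `app`, `msp`, `tpp`.
#' @export
build_frame <- function(app, msp, asis_points) {
  if (vector_angle(app$normal, msp$normal) < 10 ||
      vector_angle(app$normal, msp$normal) > 170)
    stop("APP and MSP are near-parallel; frame undefined")
  Y <- app$normal
  zdir <- pracma_cross(Y, msp$normal)
  zdir <- unitize(zdir - sum(zdir * Y) * Y)
  origin <- (as.numeric(asis_points$asis_left) + as.numeric(asis_points$asis_right)) / 2
  ptm <- (as.numeric(asis_points$pt_left) + as.numeric(asis_points$pt_right)) / 2
  sup <- origin - ptm
  if (sum(zdir * sup) < 0) zdir <- -zdir
  Z <- zdir
  X <- pracma_cross(Y, Z)
  axes <- cbind(X = X, Y = Y, Z = Z)
  msp2 <- plane3(X, point = origin)
  structure(list(origin = origin, axes = axes,
                 app = plane3(Y, point = origin),
                 msp = msp2,
                 tpp = plane3(Z, point = origin)),
            class = "pelvic_frame")
}

#' @export
print.pelvic_frame <- function(x, ...) {
  cat("<pelvic_frame>\n")
  cat(sprintf("  origin (mid-ASIS): (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (nm in c("X", "Y", "Z"))
    cat(sprintf("  %s: (%+.4f, %+.4f, %+.4f)\n", nm,
                x$axes[1, nm], x$axes[2, nm], x$axes[3, nm]))
  invisible(x)
}

#' Pelvic posture angles against the scanner frame
#'
#' Scanner convention: +X subject-right, +Y anterior, +Z superior;
#' coronal = XZ, sagittal = YZ, axial = XY planes.  Tilt is the signed
#' angle between the APP and the coronal plane seen in the sagittal
#' projection (the clinical pelvic tilt: positive when the anterior APP
#' normal gains a superior component), so a pure axial rotation of the
#' pelvis leaves tilt at zero.  Rotation and obliqueness are the
#' unsigned acute angles between the MSP and the sagittal plane and
#' between the TPP and the axial plane.
#'
#' @param frame a [pelvic_frame()].
#' @return named numeric vector `c(tilt, rotation, obliqueness)`, degrees.
#' @export
posture_angles <- function(frame) {
  nap <- frame$axes[, "Y"]
  if (nap[2] < 0) nap <- -nap
  tilt <- rad2deg(atan2(nap[3], nap[2]))
  rotation <- min(vector_angle(frame$axes[, "X"], c(1, 0, 0)),
                  vector_angle(-frame$axes[, "X"], c(1, 0, 0)))
  obliq <- min(vector_angle(frame$axes[, "Z"], c(0, 0, 1)),
               vector_angle(-frame$axes[, "Z"], c(0, 0, 1)))
  c(tilt = tilt, rotation = rotation, obliqueness = obliq)
}
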