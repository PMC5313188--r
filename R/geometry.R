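# Low-level 3D geometry: vectors, planes, rigid transforms.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 100)
    stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Angle between two vectors
#'
#' @param a,b numeric 3-vectors.
#' @param degrees return degrees (default) or radians.
#' @return acute-or-obtuse angle in `[0, 180]` degrees (or radians).
#' @keywords internal
vector_angle <- function(a, b, degrees = TRUE) {
  ca <- sum(unitize(a) * unitize(b))
  ang <- acos(max(-1, min(1, ca)))
  if (degrees) ang * 180 / pi else ang
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Construct a plane from a unit normal and offset
#'
#' A plane is the point set `{x : n . x = d}` with `|n| = 1`.
#'
#' @param normal numeric 3-vector; normalized internally.
#' @param offset scalar `d`, or alternatively `point`, a point on the plane.
#' @param point optional point on the plane (used if `offset` missing).
#' @return object of class `plane3` with elements `normal`, `offset`.
#' @export
plane3 <- function(normal, offset = NULL, point = NULL) {
  n <- unitize(as.numeric(normal))
  if (is.null(offset)) {
    if (is.null(point)) stop("give either `offset` or `point`")
    offset <- sum(n * as.numeric(point))
  }
  structure(list(normal = n, offset = as.numeric(offset)), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> n = (%.4f, %.4f, %.4f), d = %.4f\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Plane through three points
#'
#' @param p1,p2,p3 numeric 3-vectors, non-collinear.
#' @param anterior_hint optional point; the normal is oriented away from it.
#' @return a [plane3()].
#' @export
plane_from_points <- function(p1, p2, p3, anterior_hint = NULL) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- pracma_cross(p2 - p1, p3 - p1)
  if (vnorm(n) < 1e-9 * max(1, vnorm(p2 - p1)))
    stop("points are collinear; plane undefined")
  n <- unitize(n)
  if (!is.null(anterior_hint)) {
    # orient away from the hint point (e.g. the mesh centroid -> anterior)
    if (sum(n * (p1 - as.numeric(anterior_hint))) < 0) n <- -n
  }
  plane3(n, point = p1)
}

# cross product (kept dependency-free)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed distances of points from a plane
#'
#' @param points n x 3 matrix.
#' @param plane a [plane3()].
#' @return numeric vector of signed distances (positive on the normal side).
#' @export
plane_distance <- function(points, plane) {
  points <- rbind3(points)
  drop(points %*% plane$normal) - plane$offset
}

#' Reflect points across a plane
#'
#' @param points n x 3 matrix.
#' @param plane a [plane3()].
#' @return n x 3 matrix of mirrored points.
#' @export
reflect_points <- function(points, plane) {
  points <- rbind3(points)
  d <- plane_distance(points, plane)
  points - 2 * outer(d, plane$normal)
}

# coerce a vector or matrix to an n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3)
  else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation numeric 3-vector.
#' @return object of class `rigid3`.
#' @export
rigid3 <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det = +1)")
  structure(list(R = rotation, t = as.numeric(translation)), class = "rigid3")
}

#' Rotation about a coordinate axis
#'
#' @param axis one of "x", "y", "z".
#' @param angle_deg angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  th <- deg2rad(angle_deg); c_ <- cos(th); s <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3),
    y = matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3),
    z = matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3))
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix (or 3-vector).
#' @param pose a [rigid3()].
#' @return transformed points, same shape convention (n x 3 matrix).
#' @export
apply_rigid <- function(points, pose) {
  points <- rbind3(points)
  sweep(points %*% t(pose$R), 2, -pose$t)
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(pose) {
  rigid3(t(pose$R), -drop(t(pose$R) %*% pose$t))
}

# transform a plane3 by a rigid pose: n' = R n, d' = d + n' . t
transform_plane <- function(plane, pose) {
  n2 <- drop(pose$R %*% plane$normal)
  plane3(n2, offset = plane$offset + sum(n2 * pose$t))
}

#' Best-fit rigid transform between matched point sets (Kabsch)
#'
#' Least-squares rotation + translation mapping `source` onto `target`
#' via SVD of the cross-covariance.
#'
#' @param source,target n x 3 matrices of matched points (n >= 3).
#' @return a [rigid3()] with `apply_rigid(source, fit) ~ target`.
#' @export
kabsch <- function(source, target) {
  source <- rbind3(source); target <- rbind3(target)
  stopifnot(nrow(source) == nrow(target), nrow(source) >= 3)
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid3(R, ct - drop(R %*% cs))
}

# random proper rotation (uniform via QR of gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
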