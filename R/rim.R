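# Acetabular rim: closed B-spline rim path, least-squares opening circle,
# and the acetabular axis.

#' Closed cubic rim path through picked rim points
#'
#' Orders the points by angle about their centroid in the best-fit plane
#' and interpolates them with a closed periodic cubic spline (one
#' periodic spline per coordinate, parameterized by cumulative chord
#' length).  The path is retained for visualization and diagnostics; the
#' opening circle is fitted to the raw picked points.
#'
#' @param points n x 3 matrix of rim picks (n >= 6).
#' @return object of class `rim_path`: `points` (ordered), `evaluate(t)`
#'   returning path positions for parameters `t` in `[0, 1)`, and
#'   `resample(n)` returning `n` points evenly spaced in parameter.
#' @export
build_rim_path <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 6) stop("need at least 6 rim points")
  ctr <- colMeans(points)
  x0 <- sweep(points, 2, ctr)
  sv <- svd(x0)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  ang <- atan2(x0 %*% e2, x0 %*% e1)
  ord <- order(ang)
  p <- points[ord, , drop = FALSE]
  if (any(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2) < 1e-12))
    stop("duplicate consecutive rim points")
  # self-intersection check in the projection plane: ordered polygon edges
  # must not cross (angular ordering about the centroid guarantees a
  # star-shaped polygon, so equality of ranks suffices)
  if (anyDuplicated(round(ang[ord], 12)))
    stop("rim points project onto coincident directions; ordering ambiguous")
  # closed periodic cubic interpolation per coordinate via stats::spline
  seg <- sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2))
  tk <- c(0, cumsum(seg))           # knot parameters, length n+1 (closed)
  total <- tk[length(tk)]
  tk01 <- tk / total
  pp <- rbind(p, p[1, , drop = FALSE])
  evaluate <- function(t) {
    t <- t %% 1
    out <- sapply(1:3, function(k)
      stats::spline(tk01, pp[, k], xout = t, method = "periodic")$y)
    rbind3(out)
  }
  structure(list(points = p, knots = tk01, evaluate = evaluate,
                 resample = function(n) evaluate(seq(0, 1, length.out = n + 1)[-(n + 1)])),
            class = "rim_path")
}

#' @export
print.rim_path <- function(x, ...) {
  cat(sprintf("<rim_path> closed cubic spline through %d points\n", nrow(x$points)))
  invisible(x)
}

#' Least-squares opening circle of the acetabulum
#'
#' Three stages: (1) best-fit plane through the points (centroid plus
#' smallest-variance singular direction); (2) algebraic least-squares 2D
#' circle fit to the in-plane projections; (3) geometric refinement
#' minimizing the sum of squared 3D distances to the circle, iterated to
#' parameter changes below `tol`.
#'
#' @param points n x 3 matrix of rim points (n >= 4, not collinear).
#' @param tol convergence tolerance on the parameter vector.
#' @return object of class `opening_circle`: `center` (mm), `radius`
#'   (mm), `normal` (unit), and `rms` (mm, residual).
#' @export
fit_opening_circle <- function(points, tol = 1e-10) {
  points <- rbind3(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  ctr <- colMeans(points)
  x0 <- sweep(points, 2, ctr)
  sv <- svd(x0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("rim points are collinear; circle undefined")
  n0 <- sv$v[, 3]
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  u <- drop(x0 %*% e1); w <- drop(x0 %*% e2)
  # algebraic (Kasa) fit: |p|^2 = 2 a u + 2 b w + c
  A <- cbind(2 * u, 2 * w, 1)
  beta <- qr.coef(qr(A), u^2 + w^2)
  c2d <- beta[1:2]
  r0 <- sqrt(max(beta[3] + sum(c2d^2), .Machine$double.eps))
  center0 <- ctr + c2d[1] * e1 + c2d[2] * e2
  # geometric refinement: parameters (center, normal angles, radius)
  base <- orthobasis(n0)
  par0 <- c(center0, 0, 0, r0)
  objective <- function(par) {
    cen <- par[1:3]
    n <- unitize(n0 + par[4] * base[, 1] + par[5] * base[, 2])
    r <- par[6]
    d <- sweep(points, 2, cen)
    h <- drop(d %*% n)
    rad <- sqrt(pmax(rowSums(d^2) - h^2, 0))
    sum((rad - r)^2 + h^2)
  }
  opt <- stats::optim(par0, objective, method = "BFGS",
                      control = list(reltol = tol, maxit = 500))
  # polish with Nelder-Mead if BFGS got stuck on a flat spot
  opt2 <- stats::optim(opt$par, objective, control = list(reltol = tol, maxit = 2000))
  if (opt2$value < opt$value) opt <- opt2
  cen <- opt$par[1:3]
  n <- unitize(n0 + opt$par[4] * base[, 1] + opt$par[5] * base[, 2])
  r <- abs(opt$par[6])
  # re-center onto the circle plane (projection of optimum is exact here)
  structure(list(center = cen, radius = r, normal = n,
                 rms = sqrt(opt$value / nrow(points))),
            class = "opening_circle")
}

# two unit vectors orthogonal to n (and each other)
orthobasis <- function(n) {
  n <- unitize(n)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- unitize(pracma_cross(n, a))
  cbind(u, pracma_cross(n, u))
}

#' @export
print.opening_circle <- function(x, ...) {
  cat(sprintf("<opening_circle> center (%.2f, %.2f, %.2f) mm, radius %.2f mm, rms %.3g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms))
  invisible(x)
}

#' Acetabular axis from the opening circle
#'
#' Expresses the opening-circle normal in intrinsic pelvic-frame
#' coordinates and orients it out of the socket: the component along the
#' side's outward lateral direction (+X for the subject's right hip, -X
#' for the left) is made positive.  The returned direction components
#' are `(l, a, s)` = (outward-lateral, anterior, superior), ready for
#' [axis_to_angles()].
#'
#' @param circle an [fit_opening_circle()] result.
#' @param frame a [build_frame()] result.
#' @param side `"left"` or `"right"`.
#' @return object of class `acetabular_axis`: `direction` (unit `(l, a, s)`),
#'   `side`, `origin` (circle center, mm, scanner frame).
#' @export
make_axis <- function(circle, frame, side = c("left", "right")) {
  side <- match.arg(side)
  v <- drop(t(frame$axes) %*% circle$normal)   # components along X, Y, Z
  lat_sign <- if (side == "right") 1 else -1
  l <- lat_sign * v[1]
  if (abs(l) < 1e-12) {
    # lateral component zero: orient by positive anterior component
    if (abs(v[2]) < 1e-12) stop("axis orientation undefined (zero lateral and anterior components)")
    if (v[2] < 0) v <- -v
  } else if (l < 0) v <- -v
  dir <- unname(c(lat_sign * v[1], v[2], v[3]))
  structure(list(direction = unitize(dir), side = side,
                 origin = circle$center), class = "acetabular_axis")
}

#' @export
print.acetabular_axis <- function(x, ...) {
  cat(sprintf("<acetabular_axis> %s hip: (l, a, s) = (%.4f, %.4f, %.4f)\n",
              x$side, x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}
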