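# Triangle-mesh container, primitive builders, and mesh file IO.

#' Triangulated surface mesh
#'
#' Minimal triangle-mesh container used throughout the package: vertex
#' coordinates in millimetres in the scanner frame (+X subject-right,
#' +Y anterior, +Z superior) and 1-based triangle indices with outward
#' counter-clockwise winding.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `pelvic_mesh`.
#' @export
pelvic_mesh <- function(vertices, faces) {
  vertices <- rbind3(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "pelvic_mesh")
}

#' @export
print.pelvic_mesh <- function(x, ...) {
  cat(sprintf("<pelvic_mesh> %d vertices, %d faces, volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin tetrahedra; exact for watertight meshes with
#' consistent outward winding.
#'
#' @param mesh a [pelvic_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

# merge several meshes into one (concatenation, no welding)
merge_meshes <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "pelvic_mesh")) parts <- parts[[1]]
  vs <- lapply(parts, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, 1L)))
  fs <- mapply(function(m, o) m$faces + o, parts, off[-length(off)],
               SIMPLIFY = FALSE)
  pelvic_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

# deduplicate vertices coincident to `digits` decimals; drops degenerate faces
weld_vertices <- function(mesh, digits = 6) {
  key <- apply(round(mesh$vertices, digits), 1, paste, collapse = "/")
  idx <- match(key, key)              # first occurrence per coordinate
  keep <- sort(unique(idx))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  f <- matrix(remap[idx[mesh$faces]], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  pelvic_mesh(mesh$vertices[keep, , drop = FALSE], f[ok, , drop = FALSE])
}

# area-weighted vertex normals (outward for consistently wound meshes)
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + rowsum_fast(fn[, 1], f[, k], nrow(v))
    n[, 2] <- n[, 2] + rowsum_fast(fn[, 2], f[, k], nrow(v))
    n[, 3] <- n[, 3] + rowsum_fast(fn[, 3], f[, k], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

rowsum_fast <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# face normals as unit vectors
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn / len
}

# ---- primitive builders (analytic phantoms) --------------------------------

# axis-aligned box with faces gridded at ~`edge` spacing; welded, watertight
box_mesh <- function(lo, hi, edge = 2) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  verts <- list(); faces <- list(); off <- 0L
  grid_face <- function(origin, du, dv, nu, nv) {
    # returns quad grid vertices + CCW faces as seen from outside
    us <- seq(0, 1, length.out = nu + 1)
    vs <- seq(0, 1, length.out = nv + 1)
    g <- expand.grid(u = us, v = vs)
    V <- cbind(origin[1] + g$u * du[1] + g$v * dv[1],
               origin[2] + g$u * du[2] + g$v * dv[2],
               origin[3] + g$u * du[3] + g$v * dv[3])
    id <- function(i, j) (j - 1L) * (nu + 1L) + i
    i <- rep(seq_len(nu), nv); j <- rep(seq_len(nv), each = nu)
    f1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    f2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
    list(V = V, F = rbind(f1, f2))
  }
  d <- hi - lo
  n <- pmax(1L, ceiling(d / edge))
  # six faces: (origin, du, dv) chosen so du x dv points outward
  specs <- list(
    list(o = c(lo[1], lo[2], lo[3]), du = c(0, d[2], 0), dv = c(0, 0, d[3]), nu = n[2], nv = n[3], out = -1), # x = lo
    list(o = c(hi[1], lo[2], lo[3]), du = c(0, 0, d[3]), dv = c(0, d[2], 0), nu = n[3], nv = n[2], out = +1), # x = hi
    list(o = c(lo[1], lo[2], lo[3]), du = c(0, 0, d[3]), dv = c(d[1], 0, 0), nu = n[3], nv = n[1], out = -1), # y = lo
    list(o = c(lo[1], hi[2], lo[3]), du = c(d[1], 0, 0), dv = c(0, 0, d[3]), nu = n[1], nv = n[3], out = +1), # y = hi
    list(o = c(lo[1], lo[2], lo[3]), du = c(d[1], 0, 0), dv = c(0, d[2], 0), nu = n[1], nv = n[2], out = -1), # z = lo
    list(o = c(lo[1], lo[2], hi[3]), du = c(0, d[2], 0), dv = c(d[1], 0, 0), nu = n[2], nv = n[1], out = +1)) # z = hi
  for (s in specs) {
    gf <- grid_face(s$o, s$du, s$dv, s$nu, s$nv)
    verts[[length(verts) + 1L]] <- gf$V
    faces[[length(faces) + 1L]] <- gf$F + off
    off <- off + nrow(gf$V)
  }
  m <- weld_vertices(pelvic_mesh(do.call(rbind, verts), do.call(rbind, faces)))
  if (signed_volume_about(m, (lo + hi) / 2) < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# UV sphere with poles along `pole_axis`; pole vertex lies exactly at
# center + radius * pole_axis.  Welded, watertight, outward winding.
uv_sphere_mesh <- function(center, radius, edge = 2, pole_axis = c(0, 1, 0)) {
  center <- as.numeric(center)
  pole <- unitize(pole_axis)
  n_ring <- max(8L, ceiling(pi * radius / edge))          # latitudinal steps
  n_seg  <- max(12L, ceiling(2 * pi * radius / edge))     # longitudinal steps
  # local frame: w = pole
  w <- pole
  u <- unitize(if (abs(w[1]) < 0.9) pracma_cross(w, c(1, 0, 0)) else pracma_cross(w, c(0, 0, 1)))
  u <- unitize(pracma_cross(u, w))
  v <- pracma_cross(w, u)
  th <- seq(0, pi, length.out = n_ring + 1)[-c(1, n_ring + 1)]
  ph <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring <- function(t) {
    s <- sin(t); c_ <- cos(t)
    sweep(outer(cos(ph), u * (radius * s)) + outer(sin(ph), v * (radius * s)),
          2, -c(center + w * radius * c_))
  }
  V <- rbind(center + w * radius,                       # vertex 1: +pole
             do.call(rbind, lapply(th, ring)),
             center - w * radius)                       # last: -pole
  nth <- length(th)
  idx <- function(i, j) 1L + (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
  F1 <- do.call(rbind, lapply(seq_len(n_seg), function(j)
    c(1L, idx(1L, j), idx(1L, j + 1L))))
  Fm <- NULL
  if (nth > 1) {
    jj <- rep(seq_len(n_seg), nth - 1L)
    ii <- rep(seq_len(nth - 1L), each = n_seg)
    Fm <- rbind(cbind(idx(ii, jj), idx(ii + 1L, jj), idx(ii + 1L, jj + 1L)),
                cbind(idx(ii, jj), idx(ii + 1L, jj + 1L), idx(ii, jj + 1L)))
  }
  last <- nrow(V)
  F2 <- do.call(rbind, lapply(seq_len(n_seg), function(j)
    c(last, idx(nth, j + 1L), idx(nth, j))))
  m <- pelvic_mesh(V, rbind(F1, Fm, F2))
  # ensure outward orientation (positive volume wrt center): flip if needed
  if (signed_volume_about(m, center) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

signed_volume_about <- function(mesh, center) {
  v <- sweep(mesh$vertices, 2, as.numeric(center))
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# hemispherical cup shell: solid between radii r_in and r_out over the
# half-space (p - center) . axis <= 0, closed by a flat annulus in the
# opening plane.  `notch_deg` > 0 removes nothing from the solid (the
# notch only affects rim-point generation elsewhere).
cup_shell_mesh <- function(center, r_in, r_out, axis, edge = 2) {
  center <- as.numeric(center); a <- unitize(axis)
  u <- unitize(if (abs(a[1]) < 0.9) pracma_cross(a, c(1, 0, 0)) else pracma_cross(a, c(0, 0, 1)))
  u <- unitize(pracma_cross(u, a)); v <- pracma_cross(a, u)
  n_seg <- max(16L, ceiling(2 * pi * r_out / edge))
  n_lat <- max(6L, ceiling((pi / 2) * r_out / edge))
  ph <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  # hemisphere on the closed side: polar angle t in [pi/2, pi] from +axis
  hemi <- function(r, inward) {
    th <- seq(pi / 2, pi, length.out = n_lat + 1)
    Vs <- list(); Fs <- list()
    ring_id <- function(i, j) (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
    for (t in th[-length(th)]) {
      s <- sin(t); c_ <- cos(t)
      Vs[[length(Vs) + 1L]] <-
        sweep(outer(cos(ph), u * (r * s)) + outer(sin(ph), v * (r * s)),
              2, -c(center + a * (r * c_)))
    }
    V <- do.call(rbind, Vs)
    pole <- center - a * r
    V <- rbind(V, pole)
    jj <- rep(seq_len(n_seg), n_lat - 1L)
    ii <- rep(seq_len(n_lat - 1L), each = n_seg)
    Fm <- rbind(cbind(ring_id(ii, jj), ring_id(ii + 1L, jj), ring_id(ii + 1L, jj + 1L)),
                cbind(ring_id(ii, jj), ring_id(ii + 1L, jj + 1L), ring_id(ii, jj + 1L)))
    last <- nrow(V)
    Fp <- do.call(rbind, lapply(seq_len(n_seg), function(j)
      c(last, ring_id(n_lat, j), ring_id(n_lat, j + 1L))))
    F_ <- rbind(Fm, Fp)
    if (inward) F_ <- F_[, c(1, 3, 2)]
    list(V = V, F = F_)
  }
  ho <- hemi(r_out, inward = FALSE)
  hi_ <- hemi(r_in, inward = TRUE)
  no <- nrow(ho$V)
  V <- rbind(ho$V, hi_$V)
  F_ <- rbind(ho$F, hi_$F + no)
  # annulus joining the two equator rings (first ring of each hemi)
  outer_ring <- seq_len(n_seg)
  inner_ring <- no + seq_len(n_seg)
  nxt <- function(j) (j %% n_seg) + 1L
  ann <- do.call(rbind, lapply(seq_len(n_seg), function(j) rbind(
    c(outer_ring[j], outer_ring[nxt(j)], inner_ring[j]),
    c(outer_ring[nxt(j)], inner_ring[nxt(j)], inner_ring[j]))))
  m <- pelvic_mesh(V, rbind(F_, ann))
  if (signed_volume_about(m, center) < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# ---- mesh file IO ----------------------------------------------------------

#' Read and write triangle meshes (ASCII STL / PLY / OBJ)
#'
#' `read_mesh` dispatches on the file extension (`.stl`, `.ply`, `.obj`);
#' `write_mesh` supports ASCII STL and PLY.
#'
#' @param path file path.
#' @param mesh a [pelvic_mesh()].
#' @return `read_mesh`: a [pelvic_mesh()]. `write_mesh`: the path, invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = read_stl_ascii(path),
    ply = read_ply_ascii(path),
    obj = read_obj(path),
    stop("unsupported mesh format: .", ext))
}

#' @rdname read_mesh
#' @param format "stl" or "ply"; default from the file extension.
#' @export
write_mesh <- function(mesh, path, format = tolower(tools::file_ext(path))) {
  switch(format,
    stl = write_stl_ascii(mesh, path),
    ply = write_ply_ascii(mesh, path),
    stop("unsupported mesh format: .", format))
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  tri <- function(i) {
    p <- v[f[i, ], , drop = FALSE]
    c(sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
      "  outer loop",
      sprintf("    vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
      "  endloop", "endfacet")
  }
  writeLines(unlist(lapply(seq_len(nrow(f)), tri)), con)
  writeLines("endsolid mesh", con)
}

read_stl_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(s) as.numeric(s[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed STL: vertex count not multiple of 3")
  f <- matrix(seq_len(nrow(xyz)), ncol = 3, byrow = TRUE)
  weld_vertices(pelvic_mesh(xyz, f), digits = 9)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_ply_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  hend <- match("end_header", trimws(ln))
  if (is.na(hend)) stop("not an ASCII PLY file")
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", ln, value = TRUE)[1]))
  vlines <- ln[(hend + 1):(hend + nv)]
  flines <- ln[(hend + nv + 1):(hend + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                             function(s) as.numeric(s[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                             function(s) as.integer(s[2:4]) + 1L))
  pelvic_mesh(v, f)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", ln, value = TRUE)
  fl <- grep("^f\\s", ln, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(s) as.numeric(s[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(s) {
    as.integer(sub("/.*", "", s[2:4]))
  }))
  pelvic_mesh(v, f)
}

#' Voxelize a closed mesh by parity ray casting
#'
#' Marks grid cells whose centers lie inside the mesh, by counting
#' triangle crossings along +x rays per (y, z) grid row.  Intended for
#' small meshes (round-trip checks); cost is O(rows x triangles).
#'
#' @param mesh a watertight [pelvic_mesh()].
#' @param spacing voxel edge, mm.
#' @param origin grid origin (center of voxel `[1,1,1]`); default from the
#'   mesh bounding box with one voxel of margin.
#' @param dims integer grid dimensions; default to cover the mesh.
#' @return a [voxel_volume()] with intensities 1 inside, 0 outside.
#' @export
voxelize_mesh <- function(mesh, spacing = 1, origin = NULL, dims = NULL) {
  v <- mesh$vertices
  if (is.null(origin))
    origin <- floor(apply(v, 2, min) / spacing) * spacing - spacing
  if (is.null(dims))
    dims <- ceiling((apply(v, 2, max) - origin) / spacing) + 2
  dims <- as.integer(dims)
  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]; B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  arr <- array(0, dims)
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  # rays are offset by distinct irrational sub-voxel amounts so they cannot
  # pass exactly through mesh vertices or grid-aligned/diagonal edges
  eps_y <- spacing * (sqrt(2) - 1.4) * 0.1
  eps_z <- spacing * (sqrt(3) - 1.7) * 0.1
  for (jz in seq_len(dims[3])) {
    z <- zs[jz] + eps_z
    for (jy in seq_len(dims[2])) {
      y <- ys[jy] + eps_y
      # 2D point-in-triangle test in (y, z): barycentric
      d  <- (B[, 2] - C[, 2]) * (A[, 3] - C[, 3]) - (B[, 3] - C[, 3]) * (A[, 2] - C[, 2])
      w1 <- ((B[, 2] - C[, 2]) * (z - C[, 3]) - (B[, 3] - C[, 3]) * (y - C[, 2])) / d
      w2 <- ((C[, 2] - A[, 2]) * (z - A[, 3]) - (C[, 3] - A[, 3]) * (y - A[, 2])) / d
      w3 <- 1 - w1 - w2
      hit <- which(is.finite(w1) & w1 >= 0 & w1 <= 1 & w2 >= 0 & w2 <= 1 & w3 >= 0 & w3 <= 1)
      if (!length(hit)) next
      xhit <- w1[hit] * A[hit, 1] + w2[hit] * B[hit, 1] + w3[hit] * C[hit, 1]
      cnt <- vapply(xs, function(x) sum(xhit > x), 1L)
      arr[, jy, jz] <- as.numeric(cnt %% 2L == 1L)
    }
  }
  voxel_volume(arr, spacing = rep(spacing, 3), origin = origin)
}
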