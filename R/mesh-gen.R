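# Parametric test meshes: a triangulated rectangular grid (the substrate of
# the synthetic supratemporal patch) and a subdivided icosahedron sphere
# (used to check curvature and area estimators against closed forms).

#' Triangulated regular grid patch
#'
#' Builds an `nx` x `ny` vertex grid over `[0, lx] x [0, ly]` in the XY
#' plane, with an optional per-vertex height added as the Z coordinate.
#' Vertices are stored row-major in x (vertex `(i, j)` has index
#' `(j - 1) * nx + i`). Each grid cell is split into two triangles wound so
#' that face normals point towards +Z on a flat patch.
#'
#' @param nx,ny vertex counts along x and y (both >= 2).
#' @param lx,ly patch extent in mm.
#' @param height numeric vector of `nx * ny` Z values, or a single value.
#' @param hemisphere,kind passed to [fs_surface()].
#' @return An [fs_surface] with `nx * ny` vertices.
#' @export
grid_surface <- function(nx, ny, lx = nx - 1, ly = ny - 1, height = 0,
                         hemisphere = "left", kind = "synthetic") {
  if (nx < 2L || ny < 2L) stop("grid must be at least 2 x 2")
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  coords <- cbind(rep(xs, times = ny), rep(ys, each = nx),
                  rep_len(height, nx * ny))
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (j - 1L) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  fs_surface(coords, faces, hemisphere = hemisphere, kind = kind)
}

#' Subdivided icosahedron sphere
#'
#' Starts from a unit icosahedron, applies `subdivisions` rounds of 4-way
#' triangle splitting with reprojection to the sphere, then scales to the
#' requested radius. Faces are wound with outward normals, so
#' [discrete_curvatures()] reports negative (convex) mean curvature of
#' about `-1/radius`.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of subdivision rounds (0 = icosahedron).
#' @return An [fs_surface] (closed manifold).
#' @export
icosphere <- function(radius = 10, subdivisions = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # Enforce outward winding on the base solid (preserved by subdivision).
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  nrm <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  flip <- rowSums(nrm * ctr) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  for (s in seq_len(subdivisions)) {
    n <- nrow(v)
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ue <- unique(e)
    key <- (as.numeric(ue[, 1]) - 1) * n + ue[, 2]
    mid <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- n + seq_len(nrow(ue))
    lookup <- function(a, b) {
      k <- (as.numeric(pmin(a, b)) - 1) * n + pmax(a, b)
      midx[match(k, key)]
    }
    m12 <- lookup(f[, 1], f[, 2])
    m23 <- lookup(f[, 2], f[, 3])
    m31 <- lookup(f[, 3], f[, 1])
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    v <- rbind(v, mid)
  }
  fs_surface(v * radius, f, kind = "synthetic")
}
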