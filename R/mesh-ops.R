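# Vertex-graph primitives. The segmentation works entirely on subsets of
# mesh vertices ("vertex sets", sorted 1-based index vectors) and on the
# adjacency graph induced by mesh edges. Morphology is defined in hop
# (graph-edge) layers, not millimetre geodesics: the structuring element of
# depth d is the hop-distance-d ball around a vertex.

#' Build the vertex adjacency graph of a surface
#'
#' Two vertices are adjacent iff they share a mesh edge. The graph is kept
#' both as a sparse logical adjacency matrix (used for layer-wise
#' morphology) and as an igraph object (used for connected components).
#'
#' @param surface an [fs_surface].
#' @return Object of class `vertex_graph`: list with `n`, `edges`
#'   (2-column matrix), `adjacency` (sparse symmetric logical matrix) and
#'   `graph` (igraph).
#' @export
build_adjacency <- function(surface) {
  validate_surface(surface)
  n <- nrow(surface$coords)
  e <- surface_edges(surface$faces)
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = TRUE, dims = c(n, n))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  structure(list(n = n, edges = e, adjacency = adj, graph = g),
            class = "vertex_graph")
}

#' @export
print.vertex_graph <- function(x, ...) {
  cat(sprintf("vertex_graph: %d vertices, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

as_vset <- function(members, n) {
  members <- as.integer(members)
  if (length(members) && (min(members) < 1L || max(members) > n))
    stop("vertex indices out of range [1, ", n, "]")
  sort(unique(members))
}

logical_of <- function(set, n) {
  x <- logical(n)
  x[set] <- TRUE
  x
}

# One hop of dilation of a logical membership vector.
hop_expand <- function(x, adj) {
  x | (as.vector(adj %*% x) > 0)
}

#' Morphological erosion / dilation / opening on the vertex graph
#'
#' `erode_vertices()` removes every member whose hop distance to the
#' nearest non-member is at most `depth`; `dilate_vertices()` adds every
#' vertex within hop distance `depth` of the set. `morphological_open()`
#' composes the two with the same depth. Because erosion and dilation with
#' the same structuring ball form an adjunction, the opening is
#' anti-extensive (result is a subset of the input), increasing and
#' idempotent; with the default `depth = 3` it removes three boundary
#' layers and discards attached thin formations up to six vertices wide,
#' while the dilation restores the eroded rim of any retained blob without
#' reinstating the removed strips.
#'
#' @param set integer vector of member vertex indices.
#' @param graph a [build_adjacency()] graph.
#' @param depth positive integer, structuring-element radius in hop layers.
#' @return Sorted integer vertex set.
#' @export
morphological_open <- function(set, graph, depth = 3L) {
  core <- erode_vertices(set, graph, depth)
  intersect(dilate_vertices(core, graph, depth), as_vset(set, graph$n))
}

#' @rdname morphological_open
#' @export
erode_vertices <- function(set, graph, depth = 3L) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth must be a positive integer")
  m <- logical_of(as_vset(set, graph$n), graph$n)
  reach <- !m
  for (i in seq_len(depth)) reach <- hop_expand(reach, graph$adjacency)
  which(m & !reach)
}

#' @rdname morphological_open
#' @export
dilate_vertices <- function(set, graph, depth = 3L) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth must be a positive integer")
  x <- logical_of(as_vset(set, graph$n), graph$n)
  for (i in seq_len(depth)) x <- hop_expand(x, graph$adjacency)
  which(x)
}

#' Connected components of a vertex set
#'
#' Partitions `set` into maximal subsets connected through edges whose both
#' endpoints lie in `set`. Output order is deterministic: components are
#' sorted by their smallest member index.
#'
#' @param set integer vertex set.
#' @param graph a [build_adjacency()] graph.
#' @return List of sorted integer vertex sets (possibly empty).
#' @export
connected_components <- function(set, graph) {
  set <- as_vset(set, graph$n)
  if (length(set) == 0L) return(list())
  sg <- igraph::induced_subgraph(graph$graph, set)
  comp <- igraph::components(sg)$membership
  parts <- split(set, comp)
  parts <- lapply(parts, function(p) sort(as.integer(p)))
  names(parts) <- NULL
  parts[order(vapply(parts, min, integer(1)))]
}

#' Region growing from seeds inside an allowed set
#'
#' Returns the union of connected components of `allowed` that intersect
#' `seeds`: the transitive closure of adjacency from the seeds, never
#' leaving `allowed`.
#'
#' @param seeds integer vertex set, must be a subset of `allowed`.
#' @param allowed integer vertex set delimiting the growth.
#' @param graph a [build_adjacency()] graph.
#' @return Sorted integer vertex set.
#' @export
region_grow <- function(seeds, allowed, graph) {
  seeds <- as_vset(seeds, graph$n)
  allowed_l <- logical_of(as_vset(allowed, graph$n), graph$n)
  if (!all(allowed_l[seeds]))
    stop("seeds must lie within the allowed set")
  if (length(seeds) == 0L) return(integer(0))
  x <- logical_of(seeds, graph$n)
  repeat {
    x2 <- hop_expand(x, graph$adjacency) & allowed_l
    if (sum(x2) == sum(x)) break
    x <- x2
  }
  which(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

face_geometry <- function(surface) {
  f <- surface$faces
  p1 <- surface$coords[f[, 1], , drop = FALSE]
  p2 <- surface$coords[f[, 2], , drop = FALSE]
  p3 <- surface$coords[f[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)      # length = 2 * face area
  list(p1 = p1, p2 = p2, p3 = p3, normal = nrm, area = 0.5 * row_norms(nrm))
}

#' Per-vertex (barycentric) areas
#'
#' Each vertex receives one third of the area of every incident triangle,
#' so the vertex areas sum exactly to the total mesh area. Degenerate
#' (zero-area) faces contribute nothing.
#'
#' @param surface an [fs_surface].
#' @return An [fs_field] of areas in mm^2.
#' @export
vertex_areas <- function(surface) {
  fg <- face_geometry(surface)
  if (all(fg$area == 0)) stop("all faces are degenerate")
  n <- nrow(surface$coords)
  a <- fg$area / 3
  av <- numeric(n)
  for (k in 1:3) {
    add <- rowsum(a, surface$faces[, k])
    av[as.integer(rownames(add))] <- av[as.integer(rownames(add))] + add
  }
  fs_field(av, "generic")
}

# Outward vertex normals: sum of (area-weighted) incident face normals,
# normalized. Orientation follows the face winding.
vertex_normals <- function(surface) {
  fg <- face_geometry(surface)
  n <- nrow(surface$coords)
  vn <- matrix(0, n, 3)
  for (k in 1:3) {
    add <- rowsum(fg$normal, surface$faces[, k])
    ridx <- as.integer(rownames(add))
    vn[ridx, ] <- vn[ridx, ] + add
  }
  len <- row_norms(vn)
  len[len == 0] <- 1
  vn / len
}

boundary_vertices <- function(surface) {
  e <- surface_edges(surface$faces, unique = FALSE)
  n <- nrow(surface$coords)
  key <- (as.numeric(e[, 1]) - 1) * n + e[, 2]
  cnt <- table(key)
  bkey <- as.numeric(names(cnt)[cnt == 1L])
  sort(unique(c((bkey - 1) %/% n + 1, (bkey - 1) %% n + 1)))
}

#' Discrete mean and Gaussian curvature
#'
#' Mean curvature comes from the cotangent mean-curvature-normal operator
#' with barycentric vertex areas, signed by the outward vertex normal so
#' that locally convex (outward-bulging, gyral) vertices are NEGATIVE and
#' concave (sulcal) ones positive -- the FreeSurfer sign convention.
#' Gaussian curvature uses the angle deficit (2 pi minus the summed
#' incident angles; pi at boundary vertices) divided by the vertex area.
#'
#' @param surface an [fs_surface]; must be edge-manifold.
#' @return List with `mean` and `gaussian`, both [fs_field]s (1/mm and
#'   1/mm^2).
#' @export
discrete_curvatures <- function(surface) {
  validate_surface(surface)
  f <- surface$faces
  fg <- face_geometry(surface)
  ok <- fg$area > 0
  n <- nrow(surface$coords)

  # Corner angles and cotangents, per face.
  e12 <- fg$p2 - fg$p1; e13 <- fg$p3 - fg$p1; e23 <- fg$p3 - fg$p2
  ang <- function(u, v) {
    c_ <- rowSums(u * v) / pmax(row_norms(u) * row_norms(v), .Machine$double.eps)
    acos(pmin(1, pmax(-1, c_)))
  }
  a1 <- ang(e12, e13); a2 <- ang(-e12, e23); a3 <- ang(-e13, -e23)

  # Angle-deficit Gaussian curvature.
  deficit <- rep(2 * pi, n)
  deficit[boundary_vertices(surface)] <- pi
  for (k in 1:3) {
    aa <- list(a1, a2, a3)[[k]]
    add <- rowsum(ifelse(ok, aa, 0), f[, k])
    ridx <- as.integer(rownames(add))
    deficit[ridx] <- deficit[ridx] - add
  }
  areas <- field_values(vertex_areas(surface))
  areas_safe <- pmax(areas, .Machine$double.eps)
  gaussian <- deficit / areas_safe

  # Cotangent Laplacian of the coordinates: L x_i = sum_j w_ij (x_j - x_i),
  # w_ij = cot(alpha) + cot(beta) over the faces incident to edge (i, j).
  cot_ <- function(a) cos(a) / pmax(sin(a), .Machine$double.eps)
  wi <- c(f[ok, 2], f[ok, 3], f[ok, 1])
  wj <- c(f[ok, 3], f[ok, 1], f[ok, 2])
  wv <- c(cot_(a1[ok]), cot_(a2[ok]), cot_(a3[ok]))
  W <- Matrix::sparseMatrix(i = c(wi, wj), j = c(wj, wi), x = c(wv, wv),
                            dims = c(n, n))
  lap <- as.matrix(W %*% surface$coords) -
    Matrix::rowSums(W) * surface$coords
  lap <- lap / (2 * areas_safe)
  vn <- vertex_normals(surface)
  h_signed <- rowSums(lap * vn) / 2     # convex => negative (FreeSurfer)
  list(mean = fs_field(h_signed, "mean_curvature"),
       gaussian = fs_field(gaussian, "generic"))
}

#' Area-weighted centroid of a vertex set
#'
#' The surface-native stand-in for a gyrus' volumetric centre: the mean of
#' member vertex coordinates weighted by their vertex areas.
#'
#' @param set non-empty integer vertex set.
#' @param surface an [fs_surface].
#' @param areas per-vertex areas ([fs_field] or numeric); computed from
#'   `surface` when `NULL`.
#' @return Numeric length-3 coordinate (mm).
#' @export
weighted_centroid <- function(set, surface, areas = NULL) {
  set <- as_vset(set, nrow(surface$coords))
  if (length(set) == 0L) stop("cannot take the centroid of an empty set")
  if (is.null(areas)) areas <- vertex_areas(surface)
  a <- field_values(areas)[set]
  if (sum(a) == 0) a <- rep(1, length(set))
  colSums(surface$coords[set, , drop = FALSE] * a) / sum(a)
}
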