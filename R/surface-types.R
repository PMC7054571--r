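#' Cortical surface and related in-memory containers
#'
#' `fs_surface()` builds a triangle-mesh cortical surface in surface RAS
#' millimetre coordinates (+X right, +Y anterior, +Z superior). Faces are
#' 1-based vertex index triples. Real FreeSurfer surfaces are closed
#' 2-manifolds; synthetic patches may have a boundary, so edges shared by
#' more than two faces are rejected but boundary edges are allowed.
#'
#' @param coords numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @param kind `"white"`, `"pial"` or `"synthetic"`.
#' @param validate check mesh invariants (index range, no degenerate face
#'   index triples, every edge in at most two faces). Default `TRUE`.
#' @return An object of class `fs_surface`: a list with elements `coords`,
#'   `faces`, `hemisphere`, `kind`.
#' @export
fs_surface <- function(coords, faces, hemisphere = "left", kind = "synthetic",
                       validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(coords) <- NULL
  dimnames(faces) <- NULL
  if (ncol(coords) != 3L || ncol(faces) != 3L)
    stop("coords and faces must both have 3 columns")
  if (nrow(coords) < 3L || nrow(faces) < 1L)
    stop("a surface needs at least 3 vertices and 1 face")
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  kind <- match.arg(kind, c("white", "pial", "synthetic"))
  s <- structure(list(coords = coords, faces = faces,
                      hemisphere = hemisphere, kind = kind),
                 class = "fs_surface")
  if (validate) validate_surface(s)
  s
}

validate_surface <- function(s) {
  n <- nrow(s$coords)
  f <- s$faces
  if (any(f < 1L) || any(f > n))
    stop("face indices must lie in [1, ", n, "]")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("faces must not repeat a vertex")
  e <- surface_edges(f, unique = FALSE)
  key <- (as.numeric(e[, 1]) - 1) * n + e[, 2]  # numeric: avoids int overflow
  if (any(tabulate(match(key, unique(key))) > 2L))
    stop("non-manifold mesh: an edge is shared by more than 2 faces")
  invisible(s)
}

# All face edges as (min, max) index pairs; optionally deduplicated.
surface_edges <- function(faces, unique = TRUE) {
  e <- rbind(faces[, 1:2, drop = FALSE],
             faces[, 2:3, drop = FALSE],
             faces[, c(3L, 1L), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (unique) e <- unique(e)
  e
}

#' @export
print.fs_surface <- function(x, ...) {
  cat(sprintf("fs_surface: %d vertices, %d faces (%s, %s hemisphere)\n",
              nrow(x$coords), nrow(x$faces), x$kind, x$hemisphere))
  invisible(x)
}

#' Per-vertex scalar field bound to a surface
#'
#' A length-N vector of per-vertex values such as FreeSurfer mean curvature
#' (units 1/mm; negative = locally convex = gyral) or cortical thickness
#' (mm, non-negative).
#'
#' @param values numeric vector, one value per surface vertex.
#' @param kind `"mean_curvature"`, `"thickness"` or `"generic"`.
#' @param n_vertices optional expected vertex count to check against.
#' @return Object of class `fs_field` with elements `values` and `kind`.
#' @export
fs_field <- function(values, kind = "generic", n_vertices = NULL) {
  kind <- match.arg(kind, c("mean_curvature", "thickness", "generic"))
  values <- as.numeric(values)
  if (!is.null(n_vertices) && length(values) != n_vertices)
    stop("field has ", length(values), " values but surface has ",
         n_vertices, " vertices")
  if (kind == "thickness" && any(values < 0))
    stop("thickness fields must be non-negative")
  structure(list(values = values, kind = kind), class = "fs_field")
}

#' Extract the numeric values of a per-vertex field
#'
#' @param x an [fs_field] or bare numeric vector.
#' @return Numeric vector of per-vertex values.
#' @export
field_values <- function(x) {
  if (inherits(x, "fs_field")) x$values else as.numeric(x)
}

#' Destrieux-style cortical parcellation
#'
#' Per-vertex ROI assignment plus an ROI table with unique names and RGB
#' colours. Unassigned vertices carry the sentinel id `-1L`, mirroring the
#' "unknown" convention of annotation files.
#'
#' @param vertex_roi integer vector of ROI ids (`-1` = unassigned); ids
#'   index rows of `roi_table` by its `id` column.
#' @param roi_table data frame with columns `id`, `name`, `R`, `G`, `B`.
#' @return Object of class `fs_parcellation`.
#' @export
fs_parcellation <- function(vertex_roi, roi_table) {
  vertex_roi <- as.integer(vertex_roi)
  roi_table <- as.data.frame(roi_table)
  stopifnot(all(c("id", "name", "R", "G", "B") %in% names(roi_table)))
  if (anyDuplicated(roi_table$name))
    stop("ROI names must be unique")
  used <- unique(vertex_roi[vertex_roi >= 0L])
  if (!all(used %in% roi_table$id))
    stop("vertex_roi contains ids absent from roi_table")
  structure(list(vertex_roi = vertex_roi, roi_table = roi_table),
            class = "fs_parcellation")
}

#' Vertices assigned to a named ROI
#'
#' @param parc an [fs_parcellation].
#' @param name ROI name (exact, case-sensitive).
#' @return Sorted integer vector of 1-based vertex indices (possibly empty).
#' @export
roi_vertices <- function(parc, name) {
  hit <- parc$roi_table$id[parc$roi_table$name == name]
  if (length(hit) == 0L)
    stop("ROI '", name, "' not found; available: ",
         paste(parc$roi_table$name, collapse = ", "))
  which(parc$vertex_roi == hit)
}

#' Surface label: a vertex subset with coordinates and a stat value
#'
#' The working output type of the segmentation: a strictly increasing set of
#' vertex indices, each with a copy of its surface RAS coordinates and a
#' per-vertex stat value (default 0), matching FreeSurfer's ASCII label
#' format.
#'
#' @param vertices integer vector of 1-based vertex indices (deduplicated
#'   and sorted).
#' @param coords numeric matrix of per-listed-vertex coordinates (mm); rows
#'   must match `vertices`. Zero-filled when omitted.
#' @param stat per-vertex stat value(s), recycled; default 0.
#' @param name label name string.
#' @return Object of class `fs_label`.
#' @export
fs_label <- function(vertices, coords = NULL, stat = 0, name = "label") {
  o <- order(vertices)
  vertices <- as.integer(vertices[o])
  if (anyDuplicated(vertices)) stop("label vertices must be unique")
  n <- length(vertices)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  else {
    coords <- as.matrix(coords)[o, , drop = FALSE]
    if (nrow(coords) != n || ncol(coords) != 3L)
      stop("coords must be a ", n, " x 3 matrix")
  }
  stat <- as.numeric(stat)
  stat <- if (length(stat) == n) stat[o] else rep_len(stat, n)
  structure(list(vertices = vertices, coords = coords, stat = stat,
                 name = name), class = "fs_label")
}

#' @export
print.fs_label <- function(x, ...) {
  cat(sprintf("fs_label '%s': %d vertices\n", x$name, length(x$vertices)))
  invisible(x)
}
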