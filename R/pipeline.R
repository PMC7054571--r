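# The segmentation algorithm: from a Destrieux-style parcellation and a
# mean-curvature field to the final Heschl's gyrus label.
#
# Two parallel streams are derived from the atlas ROIs. The "auditory
# complex" (transverse temporal gyrus + transverse temporal sulcus + planum
# temporale) is curvature-thresholded, opened, and searched for gyral
# crowns (curvature < -0.1). The "expansion mask" additionally includes the
# posterior segment of the lateral sulcus -- the region the atlas tends to
# mis-assign the medial end of the gyrus to -- and is likewise thresholded
# and opened. Crowns are then regrown inside the expansion mask, connected
# candidates are filtered by size, and the most anterior candidate (largest
# centroid coordinate on the anterior axis) becomes the final label.

#' Pipeline configuration
#'
#' Houses the segmentation constants: the four Destrieux ROI names, the
#' gyral and crown curvature thresholds (both strict `<` cutoffs, in 1/mm,
#' with the negative-is-convex sign convention), the opening depth in hop
#' layers, the minimum candidate cluster size in vertices, and which RAS
#' coordinate axis is anterior (2 = +Y).
#'
#' @param roi_gyrus,roi_sulcus,roi_planum,roi_lateral the four atlas ROI
#'   names: transverse temporal gyrus, transverse temporal sulcus, planum
#'   temporale, posterior segment of the lateral sulcus.
#' @param gyral_threshold curvature cutoff selecting gyral vertices
#'   (default 0: keep strictly negative curvature).
#' @param crown_threshold curvature cutoff selecting gyral crowns
#'   (default -0.1); must be below `gyral_threshold`.
#' @param opening_depth erosion/dilation depth in hop layers (default 3:
#'   removes three boundary layers, discards strips up to six vertices
#'   wide).
#' @param min_cluster_vertices candidates smaller than this are dropped
#'   (default 100).
#' @param anterior_axis coordinate column whose larger values are anterior
#'   (default 2, surface RAS +Y).
#' @return Object of class `hg_config`.
#' @export
hg_config <- function(roi_gyrus = "G_temp_sup-G_T_transv",
                      roi_sulcus = "S_temporal_transverse",
                      roi_planum = "G_temp_sup-Plan_tempo",
                      roi_lateral = "Lat_Fis-post",
                      gyral_threshold = 0,
                      crown_threshold = -0.1,
                      opening_depth = 3L,
                      min_cluster_vertices = 100L,
                      anterior_axis = 2L) {
  opening_depth <- as.integer(opening_depth)
  min_cluster_vertices <- as.integer(min_cluster_vertices)
  anterior_axis <- as.integer(anterior_axis)
  if (opening_depth < 1L) stop("opening_depth must be >= 1")
  if (min_cluster_vertices < 1L) stop("min_cluster_vertices must be >= 1")
  if (!anterior_axis %in% 1:3) stop("anterior_axis must be 1, 2 or 3")
  if (!(crown_threshold < gyral_threshold))
    stop("crown_threshold must be below gyral_threshold")
  structure(list(roi_names = c(gyrus = roi_gyrus, sulcus = roi_sulcus,
                               planum = roi_planum, lateral = roi_lateral),
                 gyral_threshold = gyral_threshold,
                 crown_threshold = crown_threshold,
                 opening_depth = opening_depth,
                 min_cluster_vertices = min_cluster_vertices,
                 anterior_axis = anterior_axis),
            class = "hg_config")
}

#' Merge atlas ROIs into the raw auditory complex and expansion mask
#'
#' The raw auditory complex is the union of the transverse temporal gyrus,
#' transverse temporal sulcus and planum temporale ROIs; the raw expansion
#' mask additionally includes the posterior segment of the lateral sulcus.
#' Missing ROI *names* are a configuration error; an ROI that resolves but
#' is empty only warns (a hemisphere can lack a distinct transverse
#' temporal sulcus).
#'
#' @param parc an [fs_parcellation].
#' @param config an [hg_config].
#' @return List with integer vertex sets `raw_complex` and `raw_expansion`.
#' @export
assemble_masks <- function(parc, config = hg_config()) {
  sets <- lapply(config$roi_names, function(nm) roi_vertices(parc, nm))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    warning("empty ROI(s): ",
            paste(config$roi_names[empty], collapse = ", "))
  raw_complex <- sort(unique(c(sets$gyrus, sets$sulcus, sets$planum)))
  list(raw_complex = raw_complex,
       raw_expansion = sort(unique(c(raw_complex, sets$lateral))))
}

#' Keep the gyral (negative-curvature) vertices of a set
#'
#' Strict threshold: vertices with curvature exactly at the cutoff are
#' excluded.
#'
#' @param set integer vertex set.
#' @param curv mean-curvature [fs_field] (or numeric vector).
#' @param threshold strict upper cutoff (default 0).
#' @return Sorted integer vertex set.
#' @export
gyral_mask <- function(set, curv, threshold = 0) {
  v <- field_values(curv)
  set <- sort(unique(as.integer(set)))
  set[v[set] < threshold]
}

#' Open a curvature-filtered mask
#'
#' Thin wrapper applying [morphological_open()] at the configured depth;
#' used to turn the raw gyral masks into the final auditory complex and
#' final expansion mask, discarding thin formations running along the
#' superior temporal gyrus.
#'
#' @param set integer vertex set (already curvature-filtered).
#' @param graph a [build_adjacency()] graph.
#' @param config an [hg_config].
#' @return Sorted integer vertex set.
#' @export
refine_mask <- function(set, graph, config = hg_config()) {
  morphological_open(set, graph, config$opening_depth)
}

#' Identify gyral crowns within the final auditory complex
#'
#' Retains vertices with mean curvature strictly below the crown threshold
#' (default -0.1/mm). An empty result is an error: with no crown there is
#' nothing to regrow.
#'
#' @param final_complex refined auditory complex vertex set.
#' @param curv mean-curvature field.
#' @param config an [hg_config].
#' @return Sorted integer vertex set.
#' @export
identify_crowns <- function(final_complex, curv, config = hg_config()) {
  crowns <- gyral_mask(final_complex, curv, config$crown_threshold)
  if (length(crowns) == 0L)
    stop("no gyral crown found (no vertex with curvature < ",
         config$crown_threshold, " in the final auditory complex)")
  crowns
}

#' Regrow crowns inside the expansion mask and split into candidates
#'
#' Crowns are expanded to the full extent of their gyri by taking every
#' vertex of the final expansion mask connected to a crown. Each connected
#' component of the grown set becomes a candidate gyrus with its
#' area-weighted centroid and anterior coordinate. Crowns that fall outside
#' the expansion mask (possible because the two masks are opened
#' independently) are intersected into it with a warning.
#'
#' @param crowns crown vertex set.
#' @param final_expansion refined expansion mask vertex set.
#' @param graph a [build_adjacency()] graph.
#' @param surface the white surface (for centroids).
#' @param areas optional precomputed [vertex_areas()].
#' @param config an [hg_config].
#' @return List of candidates; each is a list with `vertices`, `size`,
#'   `centroid`, `anterior_coord`.
#' @export
delineate_gyri <- function(crowns, final_expansion, graph, surface,
                           areas = NULL, config = hg_config()) {
  inside <- intersect(crowns, final_expansion)
  if (length(inside) < length(crowns))
    warning(length(crowns) - length(inside),
            " crown vertices fell outside the expansion mask and were dropped")
  if (length(inside) == 0L)
    stop("no crown vertex lies inside the final expansion mask")
  if (is.null(areas)) areas <- vertex_areas(surface)
  grown <- region_grow(inside, final_expansion, graph)
  lapply(connected_components(grown, graph), function(comp) {
    ctr <- weighted_centroid(comp, surface, areas)
    list(vertices = comp, size = length(comp), centroid = ctr,
         anterior_coord = ctr[config$anterior_axis])
  })
}

#' Filter candidate gyri by size and select the most anterior
#'
#' Drops candidates below `min_cluster_vertices`, then returns the
#' candidate whose centroid lies furthest along the anterior axis. Ties are
#' broken deterministically: larger candidate first, then smaller lowest
#' vertex index.
#'
#' @param candidates list from [delineate_gyri()].
#' @param config an [hg_config].
#' @return The selected candidate (list).
#' @export
filter_and_select <- function(candidates, config = hg_config()) {
  if (length(candidates) == 0L) stop("no candidate gyrus to select from")
  sizes <- vapply(candidates, `[[`, numeric(1), "size")
  keep <- candidates[sizes >= config$min_cluster_vertices]
  if (length(keep) == 0L)
    stop("no candidate gyrus has >= ", config$min_cluster_vertices,
         " vertices")
  ant <- vapply(keep, `[[`, numeric(1), "anterior_coord")
  sz <- vapply(keep, `[[`, numeric(1), "size")
  lo <- vapply(keep, function(c) min(c$vertices), integer(1))
  keep[[order(-ant, -sz, lo)[1]]]
}

#' Segment Heschl's gyrus on one hemisphere
#'
#' Runs the full pipeline: ROI merging, curvature thresholding, opening,
#' crown identification, regrowth within the expansion mask, cluster
#' filtering and anterior selection. Deterministic: identical inputs give
#' identical labels.
#'
#' @param white the white (grey-white boundary) [fs_surface].
#' @param curv mean-curvature [fs_field] on `white` (FreeSurfer sign
#'   convention: negative = convex = gyral).
#' @param parc an [fs_parcellation] providing the four auditory ROIs.
#' @param config an [hg_config].
#' @param keep_intermediates retain every intermediate vertex set in the
#'   result (for audit/plotting).
#' @param verbose log stage set sizes with `message()`.
#' @return Object of class `hg_segmentation`: list with `hg_label`
#'   ([fs_label]), `candidates`, `stage_sizes`, `config`, and (optionally)
#'   `intermediates`.
#' @export
segment_hg <- function(white, curv, parc, config = hg_config(),
                       keep_intermediates = FALSE, verbose = FALSE) {
  n <- nrow(white$coords)
  if (length(field_values(curv)) != n)
    stop("curvature field does not match the surface vertex count")
  if (length(parc$vertex_roi) != n)
    stop("parcellation does not match the surface vertex count")
  graph <- build_adjacency(white)
  areas <- vertex_areas(white)

  masks <- assemble_masks(parc, config)
  complex_gyral <- gyral_mask(masks$raw_complex, curv, config$gyral_threshold)
  final_complex <- refine_mask(complex_gyral, graph, config)
  crowns <- identify_crowns(final_complex, curv, config)
  expansion_gyral <- gyral_mask(masks$raw_expansion, curv,
                                config$gyral_threshold)
  final_expansion <- refine_mask(expansion_gyral, graph, config)
  candidates <- delineate_gyri(crowns, final_expansion, graph, white,
                               areas, config)
  selected <- filter_and_select(candidates, config)

  stage_sizes <- c(raw_complex = length(masks$raw_complex),
                   raw_expansion = length(masks$raw_expansion),
                   complex_gyral = length(complex_gyral),
                   final_complex = length(final_complex),
                   crowns = length(crowns),
                   expansion_gyral = length(expansion_gyral),
                   final_expansion = length(final_expansion),
                   n_candidates = length(candidates),
                   hg_label = selected$size)
  if (verbose)
    message(paste(sprintf("%s: %d", names(stage_sizes), stage_sizes),
                  collapse = " | "))
  res <- list(hg_label = fs_label(selected$vertices,
                                  coords = white$coords[selected$vertices, ,
                                                        drop = FALSE],
                                  name = "HG"),
              candidates = candidates,
              stage_sizes = stage_sizes,
              config = config)
  if (keep_intermediates)
    res$intermediates <- list(raw_complex = masks$raw_complex,
                              raw_expansion = masks$raw_expansion,
                              complex_gyral = complex_gyral,
                              final_complex = final_complex,
                              crowns = crowns,
                              expansion_gyral = expansion_gyral,
                              final_expansion = final_expansion)
  class(res) <- "hg_segmentation"
  res
}

#' @export
print.hg_segmentation <- function(x, ...) {
  cat("hg_segmentation\n")
  cat(sprintf("  label: %d vertices (from %d candidate gyri)\n",
              length(x$hg_label$vertices), length(x$candidates)))
  cat("  stages:", paste(sprintf("%s=%d", names(x$stage_sizes),
                                 x$stage_sizes), collapse = " "), "\n")
  invisible(x)
}
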