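# Native-space anatomical quantification of a surface label: grey matter
# volume, surface area, thickness moments and integrated curvature
# measures, in the spirit of FreeSurfer's per-label anatomical stats.

#' Anatomical measures of a surface label
#'
#' Over the label's vertices, with white-surface vertex areas `a_w`, pial
#' areas `a_p`, thickness `t`, and signed mean / Gaussian curvature `H`,
#' `K` from the white surface:
#' \itemize{
#'   \item `surface_area = sum(a_w)` (mm^2)
#'   \item `gray_volume = sum(t * (a_w + a_p) / 2)` (mm^3): a per-vertex
#'     prism between the corresponding white and pial patches
#'   \item `thickness_mean`, `thickness_sd`: unweighted over vertices
#'   \item `mean_curvature_index = (1/4 pi) sum(|H| a_w)` and
#'     `gaussian_curvature_index = (1/4 pi) sum(|K| a_w)` (rectified,
#'     dimensionless)
#'   \item `intrinsic_curvature_index = (1/4 pi) sum(max(K, 0) a_w)`
#'   \item `folding_index = (1/4 pi) sum(|k1| (|k1| - |k2|) a_w)` with
#'     principal curvatures `k = H +/- sqrt(max(H^2 - K, 0))`, `|k1| >=
#'     |k2|`
#' }
#'
#' @param label an [fs_label] (or bare vertex index vector).
#' @param white,pial corresponding [fs_surface]s with identical vertex
#'   counts and vertex correspondence.
#' @param thickness thickness [fs_field] (mm) on the same vertices.
#' @param curvatures optional precomputed [discrete_curvatures()] of
#'   `white`.
#' @return One-row data frame with columns `n_vertices`, `surface_area`,
#'   `gray_volume`, `thickness_mean`, `thickness_sd`,
#'   `mean_curvature_index`, `gaussian_curvature_index`,
#'   `intrinsic_curvature_index`, `folding_index`. An empty label yields a
#'   zero row with a warning.
#' @export
compute_label_stats <- function(label, white, pial, thickness,
                                curvatures = NULL) {
  v <- if (inherits(label, "fs_label")) label$vertices else
    sort(unique(as.integer(label)))
  n <- nrow(white$coords)
  if (nrow(pial$coords) != n)
    stop("white and pial surfaces have different vertex counts (",
         n, " vs ", nrow(pial$coords), ")")
  th <- field_values(thickness)
  if (length(th) != n)
    stop("thickness field does not match the surface vertex count")
  zero <- data.frame(n_vertices = 0L, surface_area = 0, gray_volume = 0,
                     thickness_mean = 0, thickness_sd = 0,
                     mean_curvature_index = 0, gaussian_curvature_index = 0,
                     intrinsic_curvature_index = 0, folding_index = 0)
  if (length(v) == 0L) {
    warning("empty label: returning all-zero stats")
    return(zero)
  }
  if (min(v) < 1L || max(v) > n)
    stop("label references vertices outside [1, ", n, "]")
  aw <- field_values(vertex_areas(white))[v]
  ap <- field_values(vertex_areas(pial))[v]
  if (is.null(curvatures)) curvatures <- discrete_curvatures(white)
  H <- field_values(curvatures$mean)[v]
  K <- field_values(curvatures$gaussian)[v]
  disc <- sqrt(pmax(H^2 - K, 0))
  k1 <- H + disc; k2 <- H - disc
  k_hi <- pmax(abs(k1), abs(k2)); k_lo <- pmin(abs(k1), abs(k2))
  tv <- th[v]
  data.frame(n_vertices = length(v),
             surface_area = sum(aw),
             gray_volume = sum(tv * (aw + ap) / 2),
             thickness_mean = mean(tv),
             thickness_sd = if (length(v) > 1L) stats::sd(tv) else 0,
             mean_curvature_index = sum(abs(H) * aw) / (4 * pi),
             gaussian_curvature_index = sum(abs(K) * aw) / (4 * pi),
             intrinsic_curvature_index = sum(pmax(K, 0) * aw) / (4 * pi),
             folding_index = sum(k_hi * (k_hi - k_lo) * aw) / (4 * pi))
}
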