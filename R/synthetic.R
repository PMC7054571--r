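# Deterministic generator of supratemporal-plane-like folded patches with
# ground truth. The patch is a triangulated grid over x (medial -> lateral)
# and y (posterior -> anterior; +y is the anterior axis used for gyrus
# selection). Transverse gyri are oblique Gaussian ridges running
# mediolaterally. Three morphotypes are emulated:
#   single -- one ridge (plain Heschl's gyrus);
#   csd    -- two ridges joined over the medial (1 - span) of their length
#             by a common stem, with a sulcus intermedius laterally;
#   fpd    -- two fully separated ridges (the posterior one belongs to the
#             planum temporale).
# Labelling errors of the kind an atlas parcellation commits (excluding
# medial HG, spilling into the adjacent sulcus, pushing a duplication into
# the planum) are injected into the parcellation only -- never into the
# geometry.

#' Specification of a synthetic supratemporal patch
#'
#' @param morphotype `"single"`, `"csd"` or `"fpd"`.
#' @param grid integer (nx, ny) vertex resolution; at least 20 x 20.
#' @param extent patch extent (mm) along x (mediolateral) and y
#'   (posteroanterior). The default 120 x 90 grid over 60 x 45 mm gives
#'   ~0.5 mm vertex spacing, comparable to a FreeSurfer mesh.
#' @param ridge_amplitude gyral height (mm).
#' @param ridge_width Gaussian ridge sigma (mm); the convex band of a ridge
#'   extends to about one sigma either side of its crest, and crest mean
#'   curvature is about `-amplitude / (2 width^2)` (1/mm).
#' @param ridge_obliquity slant of the transverse ridges in degrees
#'   (anterolateral for positive values).
#' @param crest_separation distance between the two crest lines (mm);
#'   ignored for `single`.
#' @param sulcus_intermedius_span csd only: fraction (0, 1) of the gyrus
#'   length, from the lateral end, split by the sulcus intermedius.
#' @param thin_strip `NULL`, or `list(width_vertices =, amplitude =)`: a
#'   narrow gyral appendage attached to the lateral end of the first ridge
#'   and running posteriorly along the patch edge (emulating thin
#'   formations along the superior temporal gyrus that the opening step
#'   must discard).
#' @param error_flags logical flags `exclude_medial_hg`,
#'   `spill_into_sulcus`, `split_csd_to_pt` (see [synth_subject()]).
#' @param thickness_mean,thickness_sd cortical thickness (mm): mean and SD
#'   of the smooth spatial variation.
#' @param noise_sd SD (mm) of the smooth vertical jitter added to the
#'   height field (correlation length ~2 mm, so curvature noise stays an
#'   order of magnitude below the crown threshold).
#' @param roi_halfwidth half-width (mm) of the gyral atlas ROI bands.
#' @param medial_cut mm of the medial edge used by the
#'   `exclude_medial_hg` error (and the extent of the posterior lateral
#'   sulcus ROI).
#' @param seed integer RNG seed; identical specs and seeds give
#'   bit-identical subjects.
#' @param hemisphere `"left"` or `"right"`.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(morphotype = c("single", "csd", "fpd"),
                       grid = c(120L, 90L),
                       extent = c(60, 45),
                       ridge_amplitude = 5,
                       ridge_width = 4,
                       ridge_obliquity = 15,
                       crest_separation = 12,
                       sulcus_intermedius_span = 0.5,
                       thin_strip = NULL,
                       error_flags = list(),
                       thickness_mean = 2.5,
                       thickness_sd = 0.25,
                       noise_sd = 0.15,
                       roi_halfwidth = 5.5,
                       medial_cut = 10,
                       seed = 1L,
                       hemisphere = "left") {
  morphotype <- match.arg(morphotype)
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 20L))
    stop("grid must be two integers >= 20")
  if (any(extent <= 0) || ridge_amplitude <= 0 || ridge_width <= 0 ||
      crest_separation <= 0 || thickness_mean <= 0)
    stop("all lengths must be positive")
  if (morphotype == "csd" &&
      !(sulcus_intermedius_span > 0 && sulcus_intermedius_span < 1))
    stop("sulcus_intermedius_span must lie strictly in (0, 1) for csd")
  flags <- list(exclude_medial_hg = FALSE, spill_into_sulcus = FALSE,
                split_csd_to_pt = FALSE)
  if (length(error_flags)) {
    bad <- setdiff(names(error_flags), names(flags))
    if (length(bad)) stop("unknown error flag(s): ", paste(bad, collapse = ", "))
    flags[names(error_flags)] <- lapply(error_flags, isTRUE)
  }
  if (!is.null(thin_strip)) {
    thin_strip <- utils::modifyList(list(width_vertices = 5L, amplitude = 1.2),
                                    as.list(thin_strip))
    if (thin_strip$width_vertices < 1L) stop("thin strip width must be >= 1")
  }
  structure(list(morphotype = morphotype, grid = grid, extent = extent,
                 ridge_amplitude = ridge_amplitude, ridge_width = ridge_width,
                 ridge_obliquity = ridge_obliquity,
                 crest_separation = crest_separation,
                 sulcus_intermedius_span = sulcus_intermedius_span,
                 thin_strip = thin_strip, error_flags = flags,
                 thickness_mean = thickness_mean, thickness_sd = thickness_sd,
                 noise_sd = noise_sd, roi_halfwidth = roi_halfwidth,
                 medial_cut = medial_cut, seed = as.integer(seed),
                 hemisphere = hemisphere),
            class = "synth_spec")
}

# Separable Gaussian smoothing of a grid field (nx x ny matrix), sigma in
# grid units, clamp-padded at the boundary. With `standardize = TRUE` the
# output is divided by its exact per-position standard deviation under iid
# unit-variance input (the clamped kernel weights are known), so a white
# noise input yields a correlated field with unit variance everywhere,
# including edges.
smooth_grid <- function(m, sigma, standardize = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_apply <- function(mat) {
    nr <- nrow(mat)
    idx <- pmin(pmax(seq(1 - r, nr + r), 1L), nr)   # clamp-pad
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, nr, ncol(mat))
    for (o in seq_along(k))
      out <- out + k[o] * padded[seq(o, o + nr - 1L), , drop = FALSE]
    out
  }
  out <- t(pad_apply(t(pad_apply(m))))
  if (standardize) {
    sq_weights <- function(n) vapply(seq_len(n), function(i) {
      idx <- pmin(pmax(i + (-r):r, 1L), n)
      sum(tapply(k, idx, sum)^2)
    }, numeric(1))
    out <- out / sqrt(outer(sq_weights(nrow(m)), sq_weights(ncol(m))))
  }
  out
}

# Deterministic local RNG: run expr with a seeded generator, restoring any
# pre-existing RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Analytic height field machinery shared by generation and ground truth.
synth_fields <- function(spec) {
  nx <- spec$grid[1]; ny <- spec$grid[2]
  lx <- spec$extent[1]; ly <- spec$extent[2]
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  x <- rep(xs, times = ny)
  y <- rep(ys, each = nx)
  m <- tan(spec$ridge_obliquity * pi / 180)
  sc <- sqrt(1 + m^2)
  y1 <- (ly / 2 + spec$crest_separation / 2) + m * (x - lx / 2)
  y2 <- y1 - spec$crest_separation
  s1 <- (y - y1) / sc                     # signed perp. distance, >0 anterior
  s2 <- (y - y2) / sc
  w <- spec$ridge_width
  A <- spec$ridge_amplitude
  g <- function(s) exp(-s^2 / (2 * w^2))
  h <- A * g(s1)
  two <- spec$morphotype != "single"
  if (two) h <- h + A * g(s2)
  stem <- rep(FALSE, nx * ny)
  if (spec$morphotype == "csd") {
    smid <- (s1 + s2) / 2
    xcut <- (1 - spec$sulcus_intermedius_span) * lx
    wnd <- stats::plogis((xcut - x) / 4)  # ~1 medial of the cut, ~0 lateral
    h <- h + A * g(smid) * wnd
    stem <- wnd >= 0.5 & s1 < 0 & s2 > 0
  }
  strip <- rep(FALSE, nx * ny)
  if (!is.null(spec$thin_strip)) {
    dx <- lx / (nx - 1)
    ws <- spec$thin_strip$width_vertices * dx / 2
    xsrp <- lx - 6 * dx                   # strip spine near the lateral edge
    ds <- x - xsrp
    ywin <- stats::plogis((y1 - y) / 1.5) *
      stats::plogis((y - (y2 - 10)) / 1.5)
    h <- h + spec$thin_strip$amplitude * exp(-ds^2 / (2 * ws^2)) * ywin
    strip <- abs(ds) <= 2 * ws & ywin >= 0.5
  }
  list(x = x, y = y, s1 = s1, s2 = s2, h = h, stem = stem, strip = strip,
       nx = nx, ny = ny, lx = lx, ly = ly, two = two)
}

# Base 4-ROI parcellation from patch geometry (before error injection).
synth_parcellation <- function(spec, fl, config = hg_config()) {
  b <- spec$roi_halfwidth
  n <- fl$nx * fl$ny
  roi <- rep(-1L, n)
  in_hg <- abs(fl$s1) <= b
  if (spec$morphotype == "csd") in_hg <- in_hg | abs(fl$s2) <= b | fl$stem
  in_hg <- in_hg | fl$strip               # thin artifacts ride in the gyrus ROI
  between <- fl$s1 < 0 & fl$s2 > 0 & fl$two
  s_post <- if (fl$two) fl$s2 else fl$s1  # distance past the last crest
  in_hs <- switch(spec$morphotype,
    single = fl$s1 >= -b - 4 & fl$s1 < -b,
    csd = (fl$s2 >= -b - 4 & fl$s2 < -b) | (between & !fl$stem & !in_hg),
    fpd = between & !(abs(fl$s2) <= b))
  in_pt <- switch(spec$morphotype,
    single = fl$s1 >= -b - 16 & fl$s1 < -b - 4,
    csd = fl$s2 >= -b - 16 & fl$s2 < -b - 4,
    fpd = (abs(fl$s2) <= b) | (fl$s2 >= -b - 12 & fl$s2 < -b))
  in_pls <- fl$x < 6 & fl$s1 <= b + 2 & s_post >= -b - 16
  # Priority: the gyrus band wins everywhere (erroneously excluding medial
  # HG is an injectable error, not baseline), then the medial lateral-
  # sulcus strip, then the sulcus band, then the planum.
  roi[in_pt] <- 3L
  roi[in_hs] <- 2L
  roi[in_pls] <- 4L
  roi[in_hg] <- 1L
  tab <- data.frame(id = 1:4,
                    name = unname(config$roi_names),
                    R = c(40L, 80L, 160L, 220L),
                    G = c(120L, 40L, 160L, 180L),
                    B = c(200L, 60L, 40L, 20L))
  list(parc = fs_parcellation(roi, tab), in_hg = in_hg, in_hs = in_hs)
}

#' Generate a synthetic subject
#'
#' Builds the white surface (grid + ridges + smooth jitter), the pial
#' surface (white offset along vertex normals by the thickness field), the
#' discrete mean-curvature field, a 4-ROI parcellation with optional
#' injected labelling errors, and ground truth. Ground truth is computed on
#' the noise-free geometry with the same discrete curvature operator used
#' by the pipeline, so truth and input share one curvature definition.
#'
#' @param spec a [synth_spec()].
#' @return List of class `synth_subject` with elements `white`, `pial`,
#'   `curv`, `thickness`, `parc`, `truth` and `spec`. `truth` holds
#'   `gyrus_id` (0 none, 1 anterior gyrus/stem, 2 posterior gyrus),
#'   `true_hg` (the Heschl's gyrus definition: anterior gyrus plus the
#'   duplication for csd, excluding it for fpd), `crest1`/`crest2`, and
#'   `injected` (vertex sets altered by each requested error flag).
#' @export
synth_subject <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop("spec must be a synth_spec")
  fl <- synth_fields(spec)
  nx <- fl$nx; ny <- fl$ny
  noise <- with_seed(spec$seed, {
    nz <- smooth_grid(matrix(stats::rnorm(nx * ny), nx, ny),
                      sigma = 2 / (fl$lx / (nx - 1)), standardize = TRUE)
    th <- smooth_grid(matrix(stats::rnorm(nx * ny), nx, ny),
                      sigma = 4 / (fl$lx / (nx - 1)), standardize = TRUE)
    list(z = as.vector(nz) * spec$noise_sd,
         th = as.vector(th) * spec$thickness_sd)
  })
  white <- grid_surface(nx, ny, fl$lx, fl$ly, height = fl$h + noise$z,
                        hemisphere = spec$hemisphere, kind = "white")
  thickness <- pmax(spec$thickness_mean + noise$th, 0.5)
  vn <- vertex_normals(white)
  pial <- fs_surface(white$coords + vn * thickness, white$faces,
                     hemisphere = spec$hemisphere, kind = "pial",
                     validate = FALSE)
  curv <- discrete_curvatures(white)$mean

  # Ground truth from the noise-free geometry.
  white0 <- grid_surface(nx, ny, fl$lx, fl$ly, height = fl$h,
                         hemisphere = spec$hemisphere, kind = "white")
  curv0 <- field_values(discrete_curvatures(white0)$mean)
  gyral0 <- curv0 < 0
  b <- spec$roi_halfwidth
  gyrus_id <- integer(nx * ny)
  band1 <- abs(fl$s1) <= b
  band2 <- fl$two & abs(fl$s2) <= b
  gyrus_id[gyral0 & band1 & !fl$strip] <- 1L
  gyrus_id[gyral0 & band2 & !band1 & !fl$strip] <- 2L
  gyrus_id[gyral0 & fl$stem & gyrus_id == 0L] <- 1L
  true_hg <- if (spec$morphotype == "csd") which(gyrus_id > 0L)
             else which(gyrus_id == 1L)
  crest1 <- which(gyral0 & abs(fl$s1) <= 0.5 * spec$ridge_width)
  crest2 <- if (fl$two)
    which(gyral0 & abs(fl$s2) <= 0.5 * spec$ridge_width) else integer(0)

  pb <- synth_parcellation(spec, fl)
  parc <- pb$parc
  roi <- parc$vertex_roi
  injected <- list()
  if (spec$error_flags$exclude_medial_hg) {
    sel <- which(roi == 1L & fl$x < spec$medial_cut & !fl$strip)
    roi[sel] <- 4L
    injected$exclude_medial_hg <- sel
  }
  if (spec$error_flags$spill_into_sulcus) {
    spost <- if (fl$two) fl$s2 else fl$s1
    sel <- which(roi == 2L & spost >= -b - 2 & spost < -b)
    roi[sel] <- 1L
    injected$spill_into_sulcus <- sel
  }
  if (spec$error_flags$split_csd_to_pt && spec$morphotype == "csd") {
    sel <- which(roi == 1L & abs(fl$s2) <= b & abs(fl$s2) < abs(fl$s1))
    roi[sel] <- 3L
    injected$split_csd_to_pt <- sel
  }
  parc <- fs_parcellation(roi, parc$roi_table)

  structure(list(white = white, pial = pial, curv = curv,
                 thickness = fs_field(thickness, "thickness"),
                 parc = parc,
                 truth = list(gyrus_id = gyrus_id, true_hg = true_hg,
                              crest1 = crest1, crest2 = crest2,
                              gyral0 = which(gyral0), injected = injected),
                 spec = spec),
            class = "synth_subject")
}

#' Write a synthetic subject as a FreeSurfer-style directory
#'
#' Creates `surf/` (`?h.white`, `?h.pial`, `?h.curv`, `?h.thickness`) and
#' `label/` (`?h.aparc.a2009s.annot`, ground-truth `?h.HG_truth.label`)
#' under `dir`, all readable back with the package readers.
#'
#' @param subject a [synth_subject()].
#' @param dir subject directory to create.
#' @return `dir`, invisibly.
#' @export
write_subject_dir <- function(subject, dir) {
  hemi <- if (subject$spec$hemisphere == "right") "rh" else "lh"
  surf <- file.path(dir, "surf"); lab <- file.path(dir, "label")
  dir.create(surf, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab, recursive = TRUE, showWarnings = FALSE)
  nf <- nrow(subject$white$faces)
  write_surface(subject$white, file.path(surf, paste0(hemi, ".white")))
  write_surface(subject$pial, file.path(surf, paste0(hemi, ".pial")))
  write_scalar_field(subject$curv, file.path(surf, paste0(hemi, ".curv")),
                     n_faces = nf)
  write_scalar_field(subject$thickness,
                     file.path(surf, paste0(hemi, ".thickness")), n_faces = nf)
  write_annotation(subject$parc,
                   file.path(lab, paste0(hemi, ".aparc.a2009s.annot")))
  tv <- subject$truth$true_hg
  write_label(fs_label(tv, coords = subject$white$coords[tv, , drop = FALSE],
                       name = "HG_truth"),
              file.path(lab, paste0(hemi, ".HG_truth.label")))
  invisible(dir)
}

#' Dice overlap between two vertex sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 for two empty sets.
#'
#' @param a,b integer vertex sets (or [fs_label]s).
#' @return Numeric in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  if (inherits(a, "fs_label")) a <- a$vertices
  if (inherits(b, "fs_label")) b <- b$vertices
  if (length(a) + length(b) == 0L) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
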