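# FreeSurfer on-disk formats. Everything here is big-endian 32-bit,
# regardless of host. Only the "new" formats are supported: the triangle
# surface format (magic 0xFF 0xFF 0xFE), the new per-vertex scalar ("curv")
# format (magic 0xFF 0xFF 0xFF), annotation files with an embedded
# version-2 colour table, and the ASCII label format. Legacy quad surfaces
# and inline colour tables are rejected with explicit errors.

SURF_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))
CURV_MAGIC <- as.raw(c(0xff, 0xff, 0xff))

read_magic3 <- function(con) readBin(con, "raw", n = 3L)

magic_str <- function(m) paste(sprintf("0x%02X", as.integer(m)), collapse = " ")

read_be_int <- function(con, n = 1L) {
  x <- readBin(con, "integer", n = n, size = 4L, endian = "big")
  if (length(x) != n) stop("truncated file: expected ", n, " integers")
  x
}

read_be_float <- function(con, n) {
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "big")
  if (length(x) != n) stop("truncated file: expected ", n, " float values")
  x
}

write_be_int <- function(x, con) writeBin(as.integer(x), con, size = 4L, endian = "big")
write_be_float <- function(x, con) writeBin(as.numeric(x), con, size = 4L, endian = "big")

# Comment line(s) of a triangle surface file end with two newline bytes.
read_surface_comment <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("truncated file: unterminated comment")
    bytes <- c(bytes, b)
    nb <- length(bytes)
    if (nb >= 2L && bytes[nb] == as.raw(10L) && bytes[nb - 1L] == as.raw(10L))
      return(rawToChar(bytes[seq_len(nb - 2L)]))
  }
}

#' Read a FreeSurfer binary triangle surface
#'
#' Supports the "new" triangle format only (magic bytes `0xFF 0xFF 0xFE`):
#' a comment terminated by two newline bytes, then big-endian 32-bit vertex
#' and face counts, N x 3 float32 coordinates and M x 3 int32 0-based face
#' indices (converted to 1-based in memory).
#'
#' @param path file path.
#' @param hemisphere,kind metadata attached to the returned surface;
#'   defaults guessed from the file name (`lh.`/`rh.` prefix, suffix).
#' @return An [fs_surface].
#' @export
read_surface <- function(path, hemisphere = NULL, kind = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_magic3(con)
  if (!identical(magic, SURF_MAGIC))
    stop("not a triangle surface file (magic ", magic_str(magic),
         ", expected ", magic_str(SURF_MAGIC),
         "); legacy quad surfaces are not supported")
  read_surface_comment(con)
  nv <- read_be_int(con)
  nf <- read_be_int(con)
  if (nv < 3L || nf < 1L) stop("implausible vertex/face counts: ", nv, "/", nf)
  coords <- matrix(read_be_float(con, 3L * nv), ncol = 3L, byrow = TRUE)
  faces <- matrix(read_be_int(con, 3L * nf), ncol = 3L, byrow = TRUE) + 1L
  base <- basename(path)
  if (is.null(hemisphere))
    hemisphere <- if (grepl("^rh\\.", base)) "right" else "left"
  if (is.null(kind))
    kind <- if (grepl("pial", base)) "pial"
            else if (grepl("white", base)) "white" else "synthetic"
  fs_surface(coords, faces, hemisphere = hemisphere, kind = kind)
}

#' Write a FreeSurfer binary triangle surface
#'
#' Inverse of [read_surface()]; round trips are exact for indices and at
#' float32 precision for coordinates.
#'
#' @param surface an [fs_surface].
#' @param path output file path.
#' @export
write_surface <- function(surface, path) {
  validate_surface(surface)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SURF_MAGIC, con)
  writeBin(charToRaw("created by hgseg\n\n"), con)
  write_be_int(nrow(surface$coords), con)
  write_be_int(nrow(surface$faces), con)
  write_be_float(as.vector(t(surface$coords)), con)
  write_be_int(as.vector(t(surface$faces)) - 1L, con)
  invisible(path)
}

#' Read a FreeSurfer per-vertex scalar file (curv/thickness)
#'
#' New-format only (magic `0xFF 0xFF 0xFF`): big-endian int32 vertex count,
#' face count and values-per-vertex (must be 1), then float32 values.
#'
#' @param path file path.
#' @param expected_n expected vertex count; a mismatch with the stored
#'   count is an error. `NULL` skips the check.
#' @param kind field kind, see [fs_field()].
#' @return An [fs_field].
#' @export
read_scalar_field <- function(path, expected_n = NULL, kind = "generic") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_magic3(con)
  if (!identical(magic, CURV_MAGIC))
    stop("not a new-format scalar file (magic ", magic_str(magic),
         ", expected ", magic_str(CURV_MAGIC), ")")
  nv <- read_be_int(con)
  read_be_int(con)                       # face count, unused
  vpv <- read_be_int(con)
  if (vpv != 1L)
    stop("unsupported scalar file: ", vpv, " values per vertex (expected 1)")
  if (!is.null(expected_n) && nv != expected_n)
    stop("scalar file stores ", nv, " vertices but surface has ", expected_n)
  fs_field(read_be_float(con, nv), kind = kind)
}

#' Write a FreeSurfer per-vertex scalar file
#'
#' @param field an [fs_field] (or bare numeric vector).
#' @param path output file path.
#' @param n_faces face count to record in the header (informational).
#' @export
write_scalar_field <- function(field, path, n_faces = 0L) {
  if (!inherits(field, "fs_field")) field <- fs_field(field)
  if (field$kind == "thickness" && any(field$values < 0))
    stop("thickness fields must be non-negative")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CURV_MAGIC, con)
  write_be_int(length(field$values), con)
  write_be_int(n_faces, con)
  write_be_int(1L, con)
  write_be_float(field$values, con)
  invisible(path)
}

pack_rgb <- function(R, G, B) as.integer(R + 256L * G + 65536L * B)

#' Read a FreeSurfer annotation into a parcellation
#'
#' Parses the per-vertex packed colours (`R + 256 G + 65536 B`) and the
#' embedded version-2 colour table. Vertices whose packed colour is zero or
#' matches no table entry are returned unassigned (`-1`). Older inline
#' colour tables are rejected.
#'
#' @param path file path.
#' @return An [fs_parcellation] whose roi ids are 1-based colour-table rows.
#' @export
read_annotation <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- read_be_int(con)
  dat <- read_be_int(con, 2L * nv)
  vtx <- dat[seq(1L, 2L * nv, by = 2L)] + 1L
  packed <- dat[seq(2L, 2L * nv, by = 2L)]
  tag <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(tag) == 0L || tag != 1L)
    stop("annotation has no embedded colour table; unsupported format")
  version <- read_be_int(con)
  if (version >= 0L)
    stop("only version-2 embedded colour tables are supported ",
         "(found an old-style inline table)")
  if (version != -2L)
    stop("unsupported colour table version ", -version)
  read_be_int(con)                       # max structure id, unused
  fn_len <- read_be_int(con)
  readBin(con, "raw", n = fn_len)        # original table file name, unused
  n_entries <- read_be_int(con)
  nm <- character(n_entries); rgb <- matrix(0L, n_entries, 3)
  for (i in seq_len(n_entries)) {
    read_be_int(con)                     # structure index, unused
    len <- read_be_int(con)
    raw_nm <- readBin(con, "raw", n = len)
    nm[i] <- rawToChar(raw_nm[raw_nm != as.raw(0L)])
    rgba <- read_be_int(con, 4L)
    rgb[i, ] <- rgba[1:3]
  }
  if (anyDuplicated(nm)) stop("duplicate ROI names in colour table")
  codes <- pack_rgb(rgb[, 1], rgb[, 2], rgb[, 3])
  vertex_roi <- rep(-1L, max(vtx))
  idx <- match(packed, codes)
  idx[packed == 0L] <- NA_integer_
  vertex_roi[vtx] <- ifelse(is.na(idx), -1L, idx)
  fs_parcellation(vertex_roi,
                  data.frame(id = seq_len(n_entries), name = nm,
                             R = rgb[, 1], G = rgb[, 2], B = rgb[, 3]))
}

#' Write a parcellation as a FreeSurfer annotation
#'
#' Emits per-vertex packed colours followed by an embedded version-2 colour
#' table, readable by [read_annotation()] and by FreeSurfer tools.
#' Unassigned vertices are written with packed colour 0.
#'
#' @param parc an [fs_parcellation].
#' @param path output file path.
#' @export
write_annotation <- function(parc, path) {
  tab <- parc$roi_table
  codes <- pack_rgb(tab$R, tab$G, tab$B)
  if (any(codes == 0L))
    stop("ROI colours must have a non-zero packed code")
  if (anyDuplicated(codes)) stop("ROI colours must be distinct")
  nv <- length(parc$vertex_roi)
  packed <- rep(0L, nv)
  assigned <- parc$vertex_roi >= 0L
  packed[assigned] <- codes[match(parc$vertex_roi[assigned], tab$id)]
  con <- file(path, "wb")
  on.exit(close(con))
  write_be_int(nv, con)
  inter <- integer(2L * nv)
  inter[seq(1L, 2L * nv, by = 2L)] <- seq_len(nv) - 1L
  inter[seq(2L, 2L * nv, by = 2L)] <- packed
  write_be_int(inter, con)
  write_be_int(1L, con)                  # colour-table-present tag
  write_be_int(-2L, con)                 # table version 2
  write_be_int(nrow(tab), con)           # max structure id
  fname <- "hgseg.ctab"
  write_be_int(nchar(fname) + 1L, con)
  writeBin(c(charToRaw(fname), as.raw(0L)), con)
  write_be_int(nrow(tab), con)
  for (i in seq_len(nrow(tab))) {
    write_be_int(i - 1L, con)
    nm <- as.character(tab$name[i])
    write_be_int(nchar(nm) + 1L, con)
    writeBin(c(charToRaw(nm), as.raw(0L)), con)
    write_be_int(c(tab$R[i], tab$G[i], tab$B[i], 0L), con)
  }
  invisible(path)
}

#' Read a FreeSurfer ASCII label
#'
#' Format: a first comment line starting `#!ascii`, a line with the vertex
#' count, then one row per vertex: 0-based index, x, y, z, stat value.
#'
#' @param path file path.
#' @return An [fs_label] with 1-based vertex indices.
#' @export
read_label <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#!ascii"))
    stop("not an ASCII label file (missing '#!ascii' header)")
  count <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count)
    stop("label header announces ", count, " vertices but file has ",
         length(body), " rows")
  if (count == 0L)
    return(fs_label(integer(0), matrix(0, 0, 3),
                    name = sub("\\.label$", "", basename(path))))
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  fs_label(as.integer(m[, 1]) + 1L, coords = m[, 2:4, drop = FALSE],
           stat = m[, 5], name = sub("\\.label$", "", basename(path)))
}

#' Write a FreeSurfer ASCII label
#'
#' @param label an [fs_label]; rows are written in ascending vertex order
#'   with 0-based indices.
#' @param path output file path.
#' @export
write_label <- function(label, path) {
  n <- length(label$vertices)
  rows <- if (n > 0)
    sprintf("%d  %.9g  %.9g  %.9g %.9g",
            label$vertices - 1L, label$coords[, 1], label$coords[, 2],
            label$coords[, 3], label$stat)
  else character(0)
  writeLines(c(sprintf("#!ascii label %s, from hgseg", label$name),
               as.character(n), rows), path)
  invisible(path)
}
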