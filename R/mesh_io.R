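#' Export a mesh to PLY, OBJ, or STL
#'
#' Writes an indexed triangle mesh in one of the standard polygon formats so
#' models can be inspected or re-measured in external mesh software. The
#' format is inferred from the file extension unless given explicitly.
#' PLY is written binary little-endian by default with double-precision
#' vertex coordinates, so an export/import round trip preserves volume to
#' full precision; OBJ is ASCII; STL is binary (32-bit floats, per format).
#'
#' @param mesh An [mb_mesh()].
#' @param path Output file path.
#' @param format One of `"ply"`, `"obj"`, `"stl"`; default from extension.
#' @param ascii For PLY only: write ASCII instead of binary little-endian.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL, ascii = FALSE) {
  stopifnot(inherits(mesh, "mb_mesh"), nrow(mesh$faces) > 0)
  fmt <- tolower(format %||% tools::file_ext(path))
  switch(fmt,
    ply = write_ply(mesh, path, ascii = ascii),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    mb_abort(sprintf("unsupported mesh format '%s' (use ply, obj, or stl).", fmt),
             "unsupported_format")
  )
  invisible(path)
}

#' Read a mesh written by [export_mesh()]
#'
#' Supports ASCII and binary little-endian PLY, OBJ, and binary STL.
#' STL stores free triangles rather than an indexed mesh; on import,
#' bit-identical vertices are re-merged so a clean export round-trips to the
#' same vertex and face counts.
#'
#' @param path File path; format inferred from the extension.
#' @param format Optional explicit format.
#' @return An [mb_mesh()] (watertight flag unset; re-run [clean_mesh()] to
#'   re-verify).
#' @export
read_mesh <- function(path, format = NULL) {
  fmt <- tolower(format %||% tools::file_ext(path))
  switch(fmt,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    mb_abort(sprintf("unsupported mesh format '%s' (use ply, obj, or stl).", fmt),
             "unsupported_format")
  )
}

## PLY ---------------------------------------------------------------------

write_ply <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f0 <- mesh$faces - 1L
  header <- c(
    "ply",
    if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
    "comment produced by massbracket",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f0)),
    "property list uchar int vertex_indices",
    "end_header")
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    idx_raw <- writeBin(as.integer(t(f0)), raw(), size = 4, endian = "little")
    face_raw <- rbind(as.raw(3), matrix(idx_raw, nrow = 12))
    writeBin(as.vector(face_raw), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  ## read the header byte-wise to find the end_header offset reliably,
  ## since the payload may be binary
  raw_all <- readBin(path, raw(), n = file.size(path))
  nl <- which(raw_all == as.raw(10))
  lines <- character()
  start <- 1L
  hdr_end <- NA_integer_
  for (p in nl) {
    lines <- c(lines, rawToChar(raw_all[start:(p - 1L)]))
    start <- p + 1L
    if (identical(lines[[length(lines)]], "end_header")) { hdr_end <- p; break }
  }
  if (is.na(hdr_end)) mb_abort("malformed PLY header.", "unsupported_format")
  fmt <- sub("^format ", "", grep("^format ", lines, value = TRUE))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", lines, value = TRUE)))
  vprop <- sub("^property ", "", grep("^property (double|float) ", lines, value = TRUE))
  vtype <- unique(sub(" .*$", "", vprop))
  if (length(vtype) != 1 || length(vprop) != 3) {
    mb_abort("only x/y/z vertex properties of one type are supported.",
             "unsupported_format")
  }
  vsize <- if (vtype == "double") 8L else 4L
  if (startsWith(fmt, "ascii")) {
    txt <- strsplit(rawToChar(raw_all[(hdr_end + 1L):length(raw_all)]), "\n")[[1]]
    vv <- matrix(scan(text = txt[seq_len(nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
    ff <- matrix(scan(text = txt[nv + seq_len(nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
    if (any(ff[, 1] != 3)) mb_abort("non-triangular PLY faces.", "unsupported_format")
    return(mb_mesh(vv, ff[, 2:4] + 1L))
  }
  body <- raw_all[(hdr_end + 1L):length(raw_all)]
  vbytes <- 3L * vsize * nv
  vv <- readBin(body[seq_len(vbytes)], "numeric", n = 3L * nv, size = vsize,
                endian = "little")
  vv <- matrix(vv, ncol = 3, byrow = TRUE)
  fraw <- body[(vbytes + 1L):length(body)]
  fm <- matrix(fraw[seq_len(13L * nf)], nrow = 13L)
  if (any(as.integer(fm[1L, ]) != 3L)) {
    mb_abort("non-triangular PLY faces.", "unsupported_format")
  }
  idx <- readBin(as.vector(fm[-1L, ]), "integer", n = 3L * nf, size = 4,
                 endian = "little")
  mb_mesh(vv, matrix(idx, ncol = 3, byrow = TRUE) + 1L)
}

## OBJ ---------------------------------------------------------------------

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# produced by massbracket", con)
  v <- mesh$vertices
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  vv <- matrix(scan(text = sub("^v ", "", vlines), quiet = TRUE),
               ncol = 3, byrow = TRUE)
  fidx <- sub("/[^ ]*", "", sub("^f ", "", flines)) # drop texture/normal refs
  ff <- matrix(scan(text = fidx, quiet = TRUE), ncol = 3, byrow = TRUE)
  mb_mesh(vv, ff)
}

## STL (binary) ------------------------------------------------------------

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  tri <- cbind(nrm, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]) # m x 12
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(80)
  txt <- charToRaw("massbracket binary STL")
  hdr[seq_along(txt)] <- txt
  writeBin(hdr, con)
  writeBin(nrow(f), con, size = 4, endian = "little")
  flt <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  body <- rbind(matrix(flt, nrow = 48L), as.raw(0), as.raw(0))
  writeBin(as.vector(body), con)
  invisible(path)
}

read_stl <- function(path) {
  raw_all <- readBin(path, raw(), n = file.size(path))
  nf <- readBin(raw_all[81:84], "integer", size = 4, endian = "little")
  body <- matrix(raw_all[84 + seq_len(50L * nf)], nrow = 50L)
  flt <- readBin(as.vector(body[1:48, ]), "numeric", n = 12L * nf, size = 4,
                 endian = "little")
  tri <- matrix(flt, ncol = 12, byrow = TRUE)
  verts <- rbind(tri[, 4:6], tri[, 7:9], tri[, 10:12])
  ord <- as.vector(t(matrix(seq_len(3L * nf), ncol = 3))) # interleave v1,v2,v3
  verts <- verts[ord, , drop = FALSE]
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, key)
  uniq <- !duplicated(uid)
  mb_mesh(verts[uniq, , drop = FALSE],
          matrix(match(uid, uid[uniq]), ncol = 3, byrow = TRUE))
}

## unit conversion ---------------------------------------------------------

#' Pixel-to-meter scale from the body axis length
#'
#' All silhouettes of one model share a pixel size; the user supplies the
#' real body-axis length in meters, and the pixel count along the body axis
#' in the body images fixes the scale.
#'
#' @param body_axis_m Body axis length in meters (`> 0`).
#' @param body_axis_px Pixels along the body axis in the body images.
#' @return A `mb_unit_scale` list with `m_per_px`.
#' @examples
#' unit_scale(3, 3000)$m_per_px # 0.001
#' @export
unit_scale <- function(body_axis_m, body_axis_px) {
  stopifnot(body_axis_m > 0, body_axis_px > 0)
  structure(list(body_axis_m = body_axis_m,
                 body_axis_px = body_axis_px,
                 m_per_px = body_axis_m / body_axis_px),
            class = "mb_unit_scale")
}

#' Convert pixel measures to SI units
#'
#' @param value_px Value in `px^dim` (square pixels for areas, cubic pixels
#'   for volumes).
#' @param scale A [unit_scale()].
#' @param dim 2 for areas, 3 for volumes.
#' @return Value in `m^dim`.
#' @export
to_si <- function(value_px, scale, dim) {
  stopifnot(inherits(scale, "mb_unit_scale"))
  if (!dim %in% c(2, 3)) {
    mb_abort("`dim` must be 2 (area) or 3 (volume).", "bad_dimension")
  }
  value_px * scale$m_per_px^dim
}
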