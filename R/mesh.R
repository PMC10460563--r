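#' Triangle mesh objects
#'
#' Meshes produced by the body and fin meshers are indexed triangle meshes:
#' a numeric vertex matrix and an integer face matrix, plus a `watertight`
#' flag that only [clean_mesh()] sets. Coordinates are in image pixels until
#' converted with [to_si()].
#'
#' @param vertices Numeric `n x 3` matrix of `(x, y, z)` coordinates.
#' @param faces Integer `m x 3` matrix of 1-based vertex indices.
#' @param watertight Logical; set by [clean_mesh()], `FALSE` on construction.
#' @return An object of class `mb_mesh`.
#' @export
mb_mesh <- function(vertices, faces, watertight = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    mb_abort("face indices out of range.", "bad_mesh")
  }
  structure(list(vertices = vertices, faces = faces,
                 watertight = isTRUE(watertight)),
            class = "mb_mesh")
}

#' @export
print.mb_mesh <- function(x, ...) {
  cat(sprintf("<mb_mesh> %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$watertight) "watertight" else "not verified watertight"))
  invisible(x)
}

## undirected edge table: one row per face edge, columns (min, max)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Clean a mesh to watertightness
#'
#' Merges vertices that lie within `merge_tol_px` of each other (this is
#' what closes the tiny end-tip rings of body and fin meshes), drops
#' topologically degenerate faces (repeated vertex index) and duplicate
#' faces, orients faces so the enclosed volume is positive, and verifies
#' that every edge borders exactly two faces. Vertex merging snaps
#' coordinates onto a grid of pitch `merge_tol_px`, so merging is exact for
#' coincident vertices and transitive for near-coincident ones.
#'
#' Cleaning can fail on meshes lofted from unsmoothed, low-resolution
#' silhouettes, whose stepped outlines create pinched or non-manifold
#' geometry; this is reported as a `not_closeable` error rather than a
#' warning because volume is undefined on an open mesh.
#'
#' @param mesh An [mb_mesh()].
#' @param merge_tol_px Vertex merge distance in pixels, default `1e-4`.
#' @return A cleaned `mb_mesh` with `watertight = TRUE`.
#' @export
clean_mesh <- function(mesh, merge_tol_px = 1e-4) {
  stopifnot(inherits(mesh, "mb_mesh"), merge_tol_px > 0)
  if (nrow(mesh$faces) == 0L) mb_abort("mesh has no faces.", "bad_mesh")
  v <- mesh$vertices
  f <- mesh$faces

  ## 1. merge vertices on a merge_tol grid
  q <- round(v / merge_tol_px)
  gid <- vec_group_id(q)
  first_of <- match(unique(gid), gid)
  v2 <- v[first_of, , drop = FALSE]
  remap <- match(gid, unique(gid))
  f <- matrix(remap[f], ncol = 3)

  ## 2. drop degenerate faces (repeated index after merging)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  if (nrow(f) == 0L) mb_abort("all faces degenerate after merging.", "not_closeable")

  ## 3. drop duplicate faces (same vertex set, keep first)
  fs <- cbind(pmin(f[, 1], f[, 2], f[, 3]),
              f[, 1] + f[, 2] + f[, 3] -
                pmin(f[, 1], f[, 2], f[, 3]) - pmax(f[, 1], f[, 2], f[, 3]),
              pmax(f[, 1], f[, 2], f[, 3]))
  f <- f[!duplicated(vec_group_id(fs)), , drop = FALSE]

  ## 4. drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  v2 <- v2[used, , drop = FALSE]
  f <- matrix(match(f, used), ncol = 3)

  out <- mb_mesh(v2, f)

  ## 5. edge manifoldness: every undirected edge on exactly 2 faces
  e <- mesh_edges(out)
  ecount <- tabulate(vec_group_id(e))
  if (any(ecount != 2L)) {
    mb_abort(
      sprintf(paste0("mesh is not closeable: %d boundary and %d non-manifold ",
                     "edges remain after cleaning (typically caused by ",
                     "unsmoothed or low-resolution silhouettes)."),
              sum(ecount == 1L), sum(ecount > 2L)),
      "not_closeable")
  }
  out$watertight <- TRUE

  ## 6. orient so signed volume is positive
  if (signed_volume(out) < 0) out$faces <- out$faces[, c(1, 3, 2)]
  out
}

signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Volume by signed-tetrahedron summation (the divergence-theorem
#' algorithm): each face contributes the signed volume of the tetrahedron
#' it spans with the origin; for a closed, consistently oriented surface
#' the contributions of everything outside the solid cancel. The absolute
#' value is returned, so face winding direction does not affect the
#' magnitude. Watertightness is a hard precondition — on an open mesh the
#' sum is meaningless.
#'
#' @param mesh A cleaned, watertight [mb_mesh()].
#' @return Volume in cubic pixels.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "mb_mesh"))
  if (!isTRUE(mesh$watertight)) {
    mb_abort("mesh_volume() requires a watertight mesh; run clean_mesh() first.",
             "not_watertight")
  }
  abs(signed_volume(mesh))
}

#' Surface area of a mesh
#'
#' Sum of triangle areas (half cross-product magnitudes). Does not require
#' watertightness.
#'
#' @param mesh An [mb_mesh()].
#' @return Area in square pixels.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "mb_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Subdivide every face of a mesh
#'
#' One round of 1-to-4 midpoint subdivision. Midpoints are shared between
#' neighboring faces, so a watertight mesh stays watertight; being a
#' refinement of the same piecewise-linear surface it leaves both volume
#' and area unchanged up to round-off.
#'
#' @param mesh An [mb_mesh()].
#' @return The subdivided `mb_mesh`, `watertight` flag carried over.
#' @export
mesh_subdivide <- function(mesh) {
  stopifnot(inherits(mesh, "mb_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e <- mesh_edges(mesh)
  gid <- vec_group_id(e)
  first_of <- match(unique(gid), gid)
  mid <- (v[e[first_of, 1], , drop = FALSE] + v[e[first_of, 2], , drop = FALSE]) / 2
  mid_index <- nrow(v) + match(gid, unique(gid)) # per face-edge row
  nf <- nrow(f)
  m12 <- mid_index[seq_len(nf)]
  m23 <- mid_index[nf + seq_len(nf)]
  m31 <- mid_index[2 * nf + seq_len(nf)]
  faces <- rbind(cbind(f[, 1], m12, m31),
                 cbind(m12, f[, 2], m23),
                 cbind(m31, m23, f[, 3]),
                 cbind(m12, m23, m31))
  mb_mesh(rbind(v, mid), faces, watertight = mesh$watertight)
}

## rigid transforms --------------------------------------------------------

translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}

rotate_mesh <- function(mesh, rotation, pivot = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2, pivot)
  mesh$vertices <- sweep(v %*% t(rotation), 2, pivot, "+")
  dimnames(mesh$vertices) <- list(NULL, c("x", "y", "z"))
  mesh
}
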