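## Stitch a list of rings (each an m x 3 matrix with duplicated closing
## vertex) into a triangle strip mesh, and close both ends with a fan to
## the terminal ring centroid. Consistent quad-split winding gives outward
## normals once the overall orientation is fixed by clean_mesh().
loft_rings <- function(rings, cap = c(TRUE, TRUE)) {
  m <- nrow(rings[[1]])
  stopifnot(all(vapply(rings, nrow, numeric(1)) == m))
  nr <- length(rings)
  V <- do.call(rbind, rings)
  k <- seq_len(m - 1L)
  offs <- (seq_len(nr - 1L) - 1L) * m
  f1 <- do.call(rbind, lapply(offs, function(o) cbind(o + k, o + m + k, o + m + k + 1L)))
  f2 <- do.call(rbind, lapply(offs, function(o) cbind(o + k, o + m + k + 1L, o + k + 1L)))
  faces <- rbind(f1, f2)
  ## end caps: fan to the ring centroid (apexes merge into tip rings later).
  ## An end whose terminal ring is already collapsed flat (zero-thickness
  ## fin section) closes itself by the pinch and takes no cap.
  if (cap[1]) {
    c1 <- colMeans(rings[[1]][k, , drop = FALSE])
    i1 <- nrow(V) + 1L
    V <- rbind(V, c1)
    faces <- rbind(faces, cbind(k + 1L, k, i1)) # reversed: outward at low z
  }
  if (cap[2]) {
    c2 <- colMeans(rings[[nr]][k, , drop = FALSE])
    i2 <- nrow(V) + 1L
    V <- rbind(V, c2)
    o <- (nr - 1L) * m
    faces <- rbind(faces, cbind(o + k, o + k + 1L, i2))
  }
  mb_mesh(V, faces)
}

#' Loft the main-body mesh from an axial profile
#'
#' Draws one superelliptical section per axial station — semi-axes half the
#' transverse and dorsoventral diameters, centered on the station's section
#' centers — and stitches consecutive sections into a triangle mesh. A body
#' image with 3000 px along the axis yields 3000 sections. Tiny
#' superelliptical tip rings (radius `tip_radius_px`, default `1e-4` px)
#' are added one station beyond each end and closed with a fan, so that
#' vertex merging in [clean_mesh()] collapses each tip into a point and the
#' mesh becomes watertight; at that radius the tips are far below any
#' measurable contribution to volume or area.
#'
#' The returned mesh is uncleaned: run [clean_mesh()] before measuring.
#'
#' @param profile An [build_axial_profile()] result.
#' @param n Superelliptical exponent of the sections.
#' @param m Vertices per section ring including the duplicated closing
#'   vertex (default 181 = one per 2 degrees; 180 after merging).
#' @param tip_radius_px Radius of the terminal tip rings in pixels.
#' @return An `mb_mesh` with attribute `n_rings` (= stations used + 2 tips).
#' @export
build_body_mesh <- function(profile, n = 2, m = 181L, tip_radius_px = 1e-4) {
  stopifnot(inherits(profile, "data.frame"), tip_radius_px > 0)
  pos <- profile$dv_diameter_px > 0 & profile$tv_diameter_px > 0
  if (sum(pos) < 2) {
    mb_abort("profile needs at least 2 stations with positive diameters.",
             "empty_profile")
  }
  ## zero diameters are tolerated at the ends (they taper out), not inside
  inner <- seq(min(which(pos)), max(which(pos)))
  if (!all(pos[inner])) {
    mb_abort("non-positive diameter at an interior station; the silhouette must be one connected part.",
             "non_positive_diameter")
  }
  pr <- profile[inner, ]
  ns <- nrow(pr)
  rings <- vector("list", ns + 2L)
  rings[[1L]] <- superellipse_vertices(tip_radius_px, tip_radius_px, n, m,
                                       center = c(pr$x_center_px[1], pr$y_center_px[1]),
                                       z = pr$z_px[1] - 1)
  for (i in seq_len(ns)) {
    rings[[i + 1L]] <- superellipse_vertices(
      pr$tv_diameter_px[i] / 2, pr$dv_diameter_px[i] / 2, n, m,
      center = c(pr$x_center_px[i], pr$y_center_px[i]), z = pr$z_px[i])
  }
  rings[[ns + 2L]] <- superellipse_vertices(tip_radius_px, tip_radius_px, n, m,
                                            center = c(pr$x_center_px[ns], pr$y_center_px[ns]),
                                            z = pr$z_px[ns] + 1)
  mesh <- loft_rings(rings)
  attr(mesh, "n_rings") <- ns + 2L
  mesh
}
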