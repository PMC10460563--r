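## Shared fixtures, built in code and cached for the test run.

fx_cache <- new.env(parent = emptyenv())

fixture_dir <- function() {
  d <- file.path(tempdir(), "massbracket-fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

cached_fixture <- function(shape, long_axis_px, ...) {
  key <- paste(shape, long_axis_px, ..., sep = "_")
  if (is.null(fx_cache[[key]])) {
    fx_cache[[key]] <- render_fixture(shape, long_axis_px,
                                      dir = fixture_dir(), ...)
  }
  fx_cache[[key]]
}

## full pipeline on a sphere/spheroid fixture used as both views; cached
cached_geometry_run <- function(shape, long_axis_px, n = 2, aspect = 0.2) {
  key <- paste("run", shape, long_axis_px, n, aspect, sep = "_")
  if (is.null(fx_cache[[key]])) {
    fx_cache[[key]] <- suppressWarnings(
      validate_geometry(shape, resolutions = long_axis_px, aspect = aspect,
                        n = n, dir = fixture_dir()))
  }
  fx_cache[[key]]
}

## unit cube with consistent outward winding
cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),
             c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5),
             c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7),
             c(4, 1, 5), c(4, 5, 8))
  mb_mesh(v, f)
}

## icosphere: subdivided icosahedron re-projected to radius r
icosphere <- function(r = 1, subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- mb_mesh(v, f)
  for (i in seq_len(subdiv)) mesh <- mesh_subdivide(mesh)
  mesh$vertices <- mesh$vertices * r / sqrt(rowSums(mesh$vertices^2))
  clean_mesh(mesh, merge_tol_px = 1e-9)
}

## closed-form superellipse area, the independent oracle for ring areas
gamma_superellipse_area <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

## shoelace area of a planar ring given as (x, y) columns
shoelace_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## analytic closed outline of a circle, for tests that bypass rasterization
circle_outline <- function(r = 500, n_pts = 2000, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
  out <- tibble::tibble(u = center[1] + r * cos(th),
                        v = center[2] + r * sin(th))
  class(out) <- c("mb_outline", class(out))
  attr(out, "closed") <- TRUE
  out
}

## rectangular fin planform outline, rendered, loaded, and smoothed
rect_planform <- function(span, chord) {
  key <- sprintf("plan_%d_%d", span, chord)
  if (is.null(fx_cache[[key]])) {
    m <- matrix(1, chord + 8L, span + 8L)
    m[4 + seq_len(chord), 4 + seq_len(span)] <- 0
    p <- file.path(fixture_dir(), paste0(key, ".png"))
    EBImage::writeImage(EBImage::Image(t(m)), p)
    sil <- suppressWarnings(load_silhouette(p, view = "planar"))
    fx_cache[[key]] <- smooth_outline(extract_outline(sil), 0.1)
  }
  fx_cache[[key]]
}

## constant-diameter synthetic axial profile (a cylinder)
cylinder_profile <- function(radius = 100, stations = c(0, 1000)) {
  out <- tibble::tibble(z_px = stations,
                        dv_diameter_px = 2 * radius,
                        tv_diameter_px = 2 * radius,
                        y_center_px = 0, x_center_px = 0)
  class(out) <- c("mb_axial_profile", class(out))
  out
}
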