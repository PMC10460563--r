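#' Image resolutions of the geometric validation sweep
#'
#' The sweep draws the validation geometry with its long axis from 100 to
#' 10,000 px: steps of 100 up to 1,000 px and steps of 1,000 beyond, i.e.
#' 19 resolutions in total.
#'
#' @return Integer vector of long-axis pixel counts.
#' @export
fixture_resolutions <- function() {
  c(seq(100L, 1000L, by = 100L), seq(2000L, 10000L, by = 1000L))
}

## Rasterize an analytic region to an anti-aliased grayscale silhouette.
## inside(x, y): vectorized over x for scalar y, TRUE inside the shape.
## 4x supersampling means binarizing at 0.5 recovers the boundary to a
## fraction of a pixel, mimicking raster exports of vector drawings.
render_region <- function(inside, width, height, path, ss = 4L) {
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  xs <- rep(seq_len(width), each = ss) + rep(off, width)
  cov <- matrix(0, height, width)
  for (i in seq_len(height)) {
    acc <- numeric(length(xs))
    for (k in seq_len(ss)) {
      acc <- acc + inside(xs, i + off[k])
    }
    cov[i, ] <- colSums(matrix(acc, nrow = ss)) / ss^2
  }
  ## dark foreground on white background
  EBImage::writeImage(EBImage::Image(t(1 - cov)), path)
  invisible(path)
}

prolate_spheroid_truth <- function(a, b) {
  ## a = major semi-axis, b = minor; surface area by the standard closed form
  e <- sqrt(1 - (b / a)^2)
  list(volume = 4 / 3 * pi * a * b^2,
       area = if (e > 0) 2 * pi * b^2 * (1 + a / (b * e) * asin(e)) else 4 * pi * b^2)
}

superellipse_section_area <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

#' Render a test silhouette with known ground truth
#'
#' Programmatically draws anti-aliased silhouette images whose true volume
#' and surface area are known in closed form (or from high-resolution 1D
#' quadrature of the closed-form section area), so every stage of the
#' pipeline can be validated without any external data. A ground-truth
#' JSON is written next to the images.
#'
#' Shapes:
#' \describe{
#'   \item{`circle`}{one circle used as both body views; truth = sphere.}
#'   \item{`ellipse`}{an ellipse with `aspect` = minor/major (default 0.2,
#'     i.e. major axis five times the minor); truth = prolate spheroid.}
#'   \item{`rectangle`}{lateral `long x aspect*long` rectangle and ventral
#'     of half that height; no volume truth (corners are rounded by
#'     smoothing), used for profile tests.}
#'   \item{`superellipse_profile`}{elliptical body views; truth = quadrature
#'     of the superellipse section area at exponent `n_true` over 10^4
#'     stations.}
#'   \item{`synthetic_fish`}{elliptical body plus a rectangular caudal fin
#'     and a rectangular dorsal fin; total truth = body quadrature at
#'     `n_true` plus the NACA section-area x envelope quadrature for each
#'     fin, with body/fin overlap double-counted exactly as the pipeline
#'     does.}
#' }
#'
#' @param shape One of the shapes above.
#' @param long_axis_px Foreground extent along the long axis (>= 16).
#' @param dir Output directory.
#' @param aspect Minor/major axis ratio where applicable.
#' @param n_true Superelliptical exponent used for quadrature truths.
#' @param ss Supersampling factor for anti-aliasing.
#' @return List with `images` (named file paths) and `truth` (list of
#'   ground-truth values in px^3 / px^2, `NA` where no closed form applies).
#' @export
render_fixture <- function(shape = c("circle", "ellipse", "rectangle",
                                     "superellipse_profile", "synthetic_fish"),
                           long_axis_px, dir = tempdir(),
                           aspect = 0.2, n_true = 2, ss = 4L) {
  shape <- match.arg(shape)
  stopifnot(long_axis_px >= 16)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- long_axis_px
  margin <- 4L
  tag <- sprintf("%s_%d", shape, as.integer(L))
  img <- function(suffix) file.path(dir, sprintf("%s_%s.png", tag, suffix))

  ellipse_inside <- function(cx, cy, A, B) {
    force(cx); force(cy); force(A); force(B)
    function(x, y) ((x - cx) / A)^2 + ((y - cy) / B)^2 <= 1
  }
  rect_inside <- function(x0, x1, y0, y1) {
    function(x, y) x >= x0 & x <= x1 & (y >= y0) & (y <= y1)
  }

  out <- switch(shape,
    circle = {
      W <- L + 2L * margin
      cc <- (W + 1) / 2
      p <- img("view")
      render_region(ellipse_inside(cc, cc, L / 2, L / 2), W, W, p, ss)
      r <- L / 2
      list(images = c(lateral = p, ventral = p),
           truth = list(volume_px3 = 4 / 3 * pi * r^3,
                        area_px2 = 4 * pi * r^2))
    },
    ellipse = {
      A <- L / 2
      B <- aspect * L / 2
      W <- L + 2L * margin
      H <- ceiling(2 * B) + 2L * margin
      p <- img("view")
      render_region(ellipse_inside((W + 1) / 2, (H + 1) / 2, A, B), W, H, p, ss)
      tr <- prolate_spheroid_truth(A, B)
      list(images = c(lateral = p, ventral = p),
           truth = list(volume_px3 = tr$volume, area_px2 = tr$area))
    },
    rectangle = {
      H1 <- max(8L, round(aspect * L))
      H2 <- max(8L, round(aspect * L / 2))
      p1 <- img("lateral")
      p2 <- img("ventral")
      render_region(rect_inside(margin + 0.5, margin + 0.5 + L,
                                margin + 0.5, margin + 0.5 + H1),
                    L + 2L * margin, H1 + 2L * margin, p1, ss)
      render_region(rect_inside(margin + 0.5, margin + 0.5 + L,
                                margin + 0.5, margin + 0.5 + H2),
                    L + 2L * margin, H2 + 2L * margin, p2, ss)
      list(images = c(lateral = p1, ventral = p2),
           truth = list(volume_px3 = NA_real_, area_px2 = NA_real_,
                        dv_px = H1, tv_px = H2))
    },
    superellipse_profile = {
      A <- L / 2
      B <- aspect * L / 2
      W <- L + 2L * margin
      H <- ceiling(2 * B) + 2L * margin
      p <- img("view")
      render_region(ellipse_inside((W + 1) / 2, (H + 1) / 2, A, B), W, H, p, ss)
      zq <- seq(-A, A, length.out = 10001L)
      half <- B * sqrt(pmax(1 - (zq / A)^2, 0))
      vol <- sum(superellipse_section_area(half, half, n_true)) * (zq[2] - zq[1])
      list(images = c(lateral = p, ventral = p),
           truth = list(volume_px3 = vol, area_px2 = NA_real_,
                        n_true = n_true))
    },
    synthetic_fish = {
      A <- L / 2
      B_lat <- 0.25 * A
      B_ven <- 0.18 * A
      W <- L + 2L * margin
      H1 <- ceiling(2 * B_lat) + 2L * margin
      H2 <- ceiling(2 * B_ven) + 2L * margin
      p_lat <- img("lateral")
      p_ven <- img("ventral")
      render_region(ellipse_inside((W + 1) / 2, (H1 + 1) / 2, A, B_lat),
                    W, H1, p_lat, ss)
      render_region(ellipse_inside((W + 1) / 2, (H2 + 1) / 2, A, B_ven),
                    W, H2, p_ven, ss)
      ## rectangular fin planforms: caudal (midspan-thickest), dorsal (root)
      caudal_span <- round(0.40 * L)
      caudal_chord <- round(0.18 * L)
      dorsal_span <- round(0.25 * L)
      dorsal_chord <- round(0.15 * L)
      p_cau <- img("caudal")
      p_dor <- img("dorsal")
      render_region(rect_inside(margin + 0.5, margin + 0.5 + caudal_span,
                                margin + 0.5, margin + 0.5 + caudal_chord),
                    caudal_span + 2L * margin, caudal_chord + 2L * margin,
                    p_cau, ss)
      render_region(rect_inside(margin + 0.5, margin + 0.5 + dorsal_span,
                                margin + 0.5, margin + 0.5 + dorsal_chord),
                    dorsal_span + 2L * margin, dorsal_chord + 2L * margin,
                    p_dor, ss)
      zq <- seq(-A, A, length.out = 10001L)
      dz <- zq[2] - zq[1]
      body_vol <- sum(superellipse_section_area(
        B_ven * sqrt(pmax(1 - (zq / A)^2, 0)),
        B_lat * sqrt(pmax(1 - (zq / A)^2, 0)), n_true)) * dz
      fin_vol <- function(span, chord, t_pct, thickest_frac) {
        sec <- 2 * stats::integrate(function(x) naca_half_thickness(x, t_pct),
                                    0, 1)$value * chord^2
        envm <- stats::integrate(function(s) thickness_envelope(s, thickest_frac),
                                 0, 1)$value
        sec * envm * span
      }
      caudal_vol <- fin_vol(caudal_span, caudal_chord, 20, 0.5)
      dorsal_vol <- fin_vol(dorsal_span, dorsal_chord, 20, 0)
      list(images = c(lateral = p_lat, ventral = p_ven,
                      caudal = p_cau, dorsal = p_dor),
           truth = list(volume_px3 = body_vol + caudal_vol + dorsal_vol,
                        body_volume_px3 = body_vol,
                        caudal_volume_px3 = caudal_vol,
                        dorsal_volume_px3 = dorsal_vol,
                        area_px2 = NA_real_, n_true = n_true))
    })

  truth_path <- file.path(dir, sprintf("%s_truth.json", tag))
  jsonlite::write_json(c(list(shape = shape, long_axis_px = L), out$truth),
                       truth_path, auto_unbox = TRUE, digits = NA)
  out$truth_path <- truth_path
  out
}
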