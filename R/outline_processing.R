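## Split a closed outline into its two boundary branches, each a
## (near-)single-valued function of the axial coordinate u. The split
## points are the extreme-u vertices; the paper-frame body has no lateral
## concavities, so each branch is monotone enough for regression on u.
outline_branches <- function(u, v) {
  i_min <- which.min(u)
  i_max <- which.max(u)
  n <- length(u)
  if (i_min == i_max) {
    mb_abort("outline has no axial extent.", "degenerate_silhouette")
  }
  if (i_min < i_max) {
    b1 <- i_min:i_max
    b2 <- c(i_max:n, seq_len(i_min))
  } else {
    b1 <- i_max:i_min
    b2 <- c(i_min:n, seq_len(i_max))
  }
  list(b1, b2)
}

#' Smooth an outline with local regression
#'
#' The marching-squares trace of a binary silhouette is a half-pixel
#' staircase. Smoothing fits each boundary branch (upper and lower edge, as
#' functions of the axial coordinate `u`) with locally-weighted polynomial
#' regression — tricube weights, local degree 2, window a fraction `nn` of
#' the branch points — and replaces each point's `v` by the local fit. This
#' is what lets coordinates take non-integer values, prevents the stepped
#' look of the final model, and avoids the non-manifold mesh geometry that
#' stepped outlines produce. Locally affine stretches of the boundary are
#' reproduced exactly; pixel-scale jitter is averaged out.
#'
#' @param outline An `mb_outline` from [extract_outline()] (or any tibble
#'   with `u`, `v`).
#' @param nn Nearest-neighbor span: fraction of branch points in the local
#'   window, in `(0, 1]`. Default 0.1; 0.05 suits small fin outlines.
#' @return An `mb_outline` with the same number of points, smoothed `v`.
#' @export
smooth_outline <- function(outline, nn = 0.1) {
  stopifnot(nn > 0, nn <= 1)
  if (nrow(outline) < 10) {
    mb_abort("outline needs at least 10 points to support the local window.",
             "too_few_points")
  }
  u <- outline$u
  v <- outline$v
  for (idx in outline_branches(u, v)) {
    bu <- u[idx]
    bv <- v[idx]
    ## collapse tied u (vertical staircase runs) to their mean before
    ## fitting: local windows then always span distinct abscissae, which
    ## keeps the weighted polynomial fit well-posed on flat stretches
    uu <- sort(unique(bu))
    vv <- as.numeric(tapply(bv, match(bu, uu), mean))
    fit <- tryCatch(
      suppressWarnings(
        stats::loess(vv ~ uu, span = nn, degree = 2, family = "gaussian",
                     surface = "direct",
                     control = stats::loess.control(statistics = "none"))),
      error = function(e) {
        mb_abort(sprintf("local window too small for this outline (%s).",
                         conditionMessage(e)), "too_few_points")
      })
    v[idx] <- suppressWarnings(stats::predict(fit, data.frame(uu = bu)))
  }
  out <- outline
  out$v <- v
  out
}

## Per-integer-station extents of one outline along u: lower and upper
## boundary values, interpolated on each branch. Shared by the axial
## profile builder (body views) and the fin mesher (chord extents).
outline_extents <- function(u, v) {
  br <- outline_branches(u, v)
  z <- seq(ceiling(min(u)), floor(max(u)))
  vals <- lapply(br, function(idx) {
    stats::approx(u[idx], v[idx], xout = z, ties = mean, rule = 2)$y
  })
  lo <- pmin(vals[[1]], vals[[2]])
  hi <- pmax(vals[[1]], vals[[2]])
  tibble::tibble(station = z, lo = lo, hi = hi)
}

#' Build the per-station axial profile from the two body outlines
#'
#' Converts the lateral and ventral body outlines into one record per pixel
#' station along the body axis: the dorsoventral diameter (dorsal minus
#' ventral extent of the lateral outline), the transverse diameter (right
#' minus left extent of the ventral outline), and the section centers
#' (midpoints of those extents). A body spanning 3000 px therefore yields
#' 3000 stations, each of which later receives one superelliptical section.
#'
#' The two views are aligned at their anterior-most point and cropped to
#' the common span; they must agree in axial extent to within 1% (residual
#' one-pixel disagreements are expected from rasterization). Image row
#' coordinates increase downward; centers are converted here to the model
#' frame (y dorsal-positive) and re-expressed relative to their mean, so a
#' bilaterally symmetric tracing is centered on x = 0.
#'
#' @param lateral,ventral `mb_outline` traces of the lateral and ventral
#'   body silhouettes (smoothed or not).
#' @return A tibble of class `mb_axial_profile` with columns `z_px` (0 at
#'   the snout), `dv_diameter_px`, `tv_diameter_px`, `y_center_px`,
#'   `x_center_px`.
#' @export
build_axial_profile <- function(lateral, ventral) {
  el <- outline_extents(lateral$u, lateral$v)
  ev <- outline_extents(ventral$u, ventral$v)
  n1 <- nrow(el)
  n2 <- nrow(ev)
  if (abs(n1 - n2) > 0.01 * max(n1, n2)) {
    mb_abort(sprintf(
      "lateral and ventral views span %d vs %d axial px (> 1%% mismatch); check that both images share one pixel scale.",
      n1, n2), "view_length_mismatch")
  }
  n <- min(n1, n2)
  el <- el[seq_len(n), ]
  ev <- ev[seq_len(n), ]
  dv <- el$hi - el$lo
  tv <- ev$hi - ev$lo
  y_mid <- -(el$lo + el$hi) / 2 # negate: image v is ventral-positive
  x_mid <- (ev$lo + ev$hi) / 2
  out <- tibble::tibble(
    z_px = seq_len(n) - 1L,
    dv_diameter_px = pmax(dv, 0),
    tv_diameter_px = pmax(tv, 0),
    y_center_px = y_mid - mean(y_mid),
    x_center_px = x_mid - mean(x_mid))
  class(out) <- c("mb_axial_profile", class(out))
  attr(out, "n_stations") <- n
  out
}
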