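#' Load and binarize a silhouette image
#'
#' Reads a raster silhouette (PNG, JPEG, or TIFF; grayscale or RGB(A)),
#' converts to luminance, thresholds it, and keeps the largest connected
#' foreground component — stray specks from lossy compression are
#' discarded, since each image is expected to contain exactly one body part.
#' Silhouettes are conventionally drawn dark on a light background; set
#' `foreground = "light"` for the opposite convention.
#'
#' A warning is raised when the component's longest axis is below
#' `warn_below_px` (default 3000): volume and area errors grow quickly at
#' low resolution, and stepped outlines at a few hundred pixels can defeat
#' mesh cleaning altogether.
#'
#' @param path Image file path.
#' @param threshold Luminance threshold as a fraction of full range,
#'   default 0.5.
#' @param foreground `"dark"` (default) or `"light"`.
#' @param view One of `"lateral"`, `"ventral"`, `"planar"`; recorded on the
#'   object.
#' @param warn_below_px Resolution below which a low-resolution warning is
#'   emitted.
#' @return A `mb_silhouette`: list with `grid` (logical matrix, rows = image
#'   rows), `width_px`, `height_px`, `source_path`, `view_tag`.
#' @export
load_silhouette <- function(path, threshold = 0.5,
                            foreground = c("dark", "light"),
                            view = c("lateral", "ventral", "planar"),
                            warn_below_px = 3000) {
  foreground <- match.arg(foreground)
  view <- match.arg(view)
  if (!file.exists(path)) {
    mb_abort(sprintf("image file '%s' does not exist.", path), "unreadable_image")
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) {
                    mb_abort(sprintf("cannot decode '%s' as a raster image: %s",
                                     path, conditionMessage(e)),
                             "unreadable_image")
                  })
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nc <- dim(dat)[3]
    ## Rec. 709 luminance for RGB(A); alpha channel ignored
    if (nc >= 3) {
      dat <- 0.2126 * dat[, , 1] + 0.7152 * dat[, , 2] + 0.0722 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  lum <- t(dat) # EBImage stores [x, y]; convert to [row, col]
  mask <- if (foreground == "dark") lum < threshold else lum >= threshold
  if (!any(mask)) {
    mb_abort(sprintf("no foreground pixel in '%s' after thresholding.", path),
             "empty_silhouette")
  }
  ## keep largest connected component
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1)))
  counts <- tabulate(lab[lab > 0])
  mask <- t(lab) == which.max(counts)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  longest <- max(diff(rows), diff(cols)) + 1L
  if (longest < warn_below_px) {
    mb_warn(sprintf(
      paste0("silhouette '%s' spans only %d px along its longest axis; ",
             "at least %d px are recommended for stable sub-0.5%% accuracy."),
      basename(path), longest, warn_below_px), "low_resolution")
  }
  structure(list(grid = mask,
                 width_px = ncol(mask), height_px = nrow(mask),
                 source_path = path, view_tag = view),
            class = "mb_silhouette")
}

#' @export
print.mb_silhouette <- function(x, ...) {
  cat(sprintf("<mb_silhouette> %s view, %d x %d px, %d foreground px\n",
              x$view_tag, x$width_px, x$height_px, sum(x$grid)))
  invisible(x)
}

#' Trace the outline of a silhouette at sub-pixel precision
#'
#' Extracts the closed boundary of the foreground as the 0.5-level
#' iso-contour of the binary grid (marching squares), which places boundary
#' points half a pixel outside the outermost foreground pixel centers and
#' lets coordinates take non-integer values — the smoother then turns the
#' staircase into a smooth curve. The trace is ordered counter-clockwise in
#' the `(u, v)` image frame (`u` = column, increasing rightward; `v` = row,
#' increasing downward) and does not repeat its first point.
#'
#' @param sil A [load_silhouette()] result.
#' @return A tibble of class `mb_outline` with columns `u`, `v` and
#'   attributes `closed`, `view_tag`.
#' @export
extract_outline <- function(sil) {
  stopifnot(inherits(sil, "mb_silhouette"))
  g <- sil$grid
  rows <- which(rowSums(g) > 0)
  cols <- which(colSums(g) > 0)
  if (diff(range(rows)) < 1 || diff(range(cols)) < 1) {
    mb_abort("silhouette is under 2 px in at least one dimension.",
             "degenerate_silhouette")
  }
  padded <- rbind(0, cbind(0, g * 1, 0), 0)
  cl <- grDevices::contourLines(x = 0:(nrow(g) + 1L), y = 0:(ncol(g) + 1L),
                                z = padded, levels = 0.5)
  lens <- vapply(cl, function(l) length(l$x), numeric(1))
  loop <- cl[[which.max(lens)]] # outer boundary of the single component
  u <- loop$y
  v <- loop$x
  npt <- length(u)
  if (u[1] == u[npt] && v[1] == v[npt]) { # drop repeated closing point
    u <- u[-npt]
    v <- v[-npt]
  }
  ## enforce counter-clockwise order (positive shoelace area in (u, v))
  a2 <- sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v)
  if (a2 < 0) {
    u <- rev(u)
    v <- rev(v)
  }
  out <- tibble::tibble(u = u, v = v)
  class(out) <- c("mb_outline", class(out))
  attr(out, "closed") <- TRUE
  attr(out, "view_tag") <- sil$view_tag
  out
}
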