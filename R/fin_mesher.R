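#' Specify a fin, flipper, or cephalofoil part
#'
#' Captures the per-part modeling parameters: section thickness, span
#' position of the thickest section, and the placement transform used when
#' assembling the visual whole-body model. Defaults follow the standard
#' configuration: base thickness 10% of chord for the anal and second
#' dorsal fins and 20% for everything else; thickest section at the root
#' (span fraction 0) for pectoral/pelvic/dorsal-type fins and at midspan
#' (0.5) for a symmetric caudal fin.
#'
#' @param part_type One of `"pectoral"`, `"pelvic"`, `"caudal"`, `"dorsal"`,
#'   `"second_dorsal"`, `"anal"`, `"cephalofoil"`.
#' @param base_t_pct Base NACA section thickness in percent of chord;
#'   default depends on `part_type` (see above).
#' @param thickest_frac Span fraction of the thickest section in `[0, 1]`;
#'   default depends on `part_type`. Ignored by the cephalofoil, which is
#'   thickest at both ends.
#' @param translation Placement offset `(x, y, z)` in pixels.
#' @param roll,pitch,yaw Placement rotations in degrees about the z, x, and
#'   y axes; applied in that order (roll first) by [place_part()].
#' @param span_axis `"auto"` (default: the planform's longer foreground
#'   axis), `"u"` (image columns), or `"v"` (image rows).
#' @param cephalofoil_min_factor Midspan envelope minimum for the
#'   cephalofoil, in `(0, 1]`.
#' @return A list of class `mb_part_spec`.
#' @export
part_spec <- function(part_type = c("pectoral", "pelvic", "caudal", "dorsal",
                                    "second_dorsal", "anal", "cephalofoil"),
                      base_t_pct = NULL, thickest_frac = NULL,
                      translation = c(0, 0, 0), roll = 0, pitch = 0, yaw = 0,
                      span_axis = c("auto", "u", "v"),
                      cephalofoil_min_factor = 0.6) {
  part_type <- match.arg(part_type)
  span_axis <- match.arg(span_axis)
  base_t_pct <- base_t_pct %||%
    if (part_type %in% c("anal", "second_dorsal")) 10 else 20
  thickest_frac <- thickest_frac %||%
    if (part_type == "caudal") 0.5 else 0
  stopifnot(base_t_pct > 0, thickest_frac >= 0, thickest_frac <= 1,
            length(translation) == 3)
  structure(list(part_type = part_type, base_t_pct = base_t_pct,
                 thickest_frac = thickest_frac,
                 translation = as.numeric(translation),
                 roll = roll, pitch = pitch, yaw = yaw,
                 span_axis = span_axis,
                 cephalofoil_min_factor = cephalofoil_min_factor),
            class = "mb_part_spec")
}

## chord extents per span station, in the part's local orientation
planform_stations <- function(planar, spec) {
  u <- planar$u
  v <- planar$v
  span_axis <- spec$span_axis
  if (span_axis == "auto") {
    span_axis <- if (diff(range(u)) >= diff(range(v))) "u" else "v"
  }
  if (span_axis == "v") {
    tmp <- u
    u <- v
    v <- tmp
  }
  ext <- outline_extents(u, v)
  chord <- ext$hi - ext$lo
  keep <- chord > 0
  if (sum(keep) < 2) {
    mb_abort("planform has no positive chord; cannot build a fin.",
             "degenerate_planform")
  }
  rng <- seq(min(which(keep)), max(which(keep)))
  if (!all(keep[rng])) {
    mb_abort("planform chord vanishes at an interior span station.",
             "degenerate_planform")
  }
  ext <- ext[rng, ]
  ext$chord <- ext$hi - ext$lo
  ext$span_frac <- (ext$station - ext$station[1]) /
    (ext$station[nrow(ext)] - ext$station[1])
  ext
}

fin_mesh_impl <- function(planar, spec, env_factors, stations, n_chord) {
  x_frac <- (1 - cos(seq(0, pi, length.out = n_chord))) / 2 # leading-edge clustered
  ht <- naca_half_thickness(x_frac, spec$base_t_pct) # fraction of chord
  ns <- nrow(stations)
  m_ring <- 2L * n_chord
  section_rings <- vector("list", ns)
  for (i in seq_len(ns)) {
    c_i <- stations$chord[i]
    x <- stations$lo[i] + x_frac * c_i
    h <- c_i * ht * env_factors[i]
    ## closed ring: leading edge -> upper -> trailing edge -> lower -> back
    ring_x <- c(x, rev(x[-n_chord]))
    ring_y <- c(h, -rev(h[-n_chord]))
    section_rings[[i]] <- cbind(x = c(ring_x, ring_x[1]),
                                y = c(ring_y, ring_y[1]),
                                z = stations$station[i])
  }
  ## an end where the envelope vanishes is already pinched flat and closes
  ## itself; an open end gets a tiny tip ring + cap, like the body ends
  open_low <- env_factors[1] > 1e-12
  open_high <- env_factors[ns] > 1e-12
  rings <- section_rings
  if (open_low) {
    tip1 <- c(stations$lo[1] + stations$chord[1] / 2, 0)
    rings <- c(list(superellipse_vertices(1e-4, 1e-4, 2, m_ring, center = tip1,
                                          z = stations$station[1] - 1)),
               rings)
  }
  if (open_high) {
    tip2 <- c(stations$lo[ns] + stations$chord[ns] / 2, 0)
    rings <- c(rings,
               list(superellipse_vertices(1e-4, 1e-4, 2, m_ring, center = tip2,
                                          z = stations$station[ns] + 1)))
  }
  mesh <- loft_rings(rings, cap = c(open_low, open_high))
  ## pivot for placement: planform centroid in the local frame
  attr(mesh, "pivot") <- c(mean(c(stations$lo, stations$hi)), 0,
                           mean(range(stations$station)))
  attr(mesh, "n_rings") <- length(rings)
  attr(mesh, "part_type") <- spec$part_type
  mesh
}

#' Build a fin or flipper mesh from its planar outline
#'
#' At every pixel station along the span, the chord extent is read off the
#' planar outline and a symmetric NACA 4-digit section of that chord is
#' drawn, with thickness `base_t_pct` scaled by the square-root thickness
#' envelope at that span position (see [thickness_envelope()]). Sections
#' are stitched into a mesh and the span ends closed with tiny tip rings,
#' exactly like the main body. The open NACA trailing edge is closed per
#' section by joining the upper and lower surfaces at the trailing edge.
#'
#' The mesh lives in the part's local frame: the planform in the x–z plane
#' with the span along z and the chord along x, thickness along y.
#' Placement into the body frame is done later by [place_part()].
#'
#' @param planar An `mb_outline` of the planar fin silhouette (smoothed or
#'   not).
#' @param spec A [part_spec()].
#' @param n_chord Chordwise sample points per surface (default 60,
#'   cosine-clustered toward the leading edge).
#' @return An uncleaned `mb_mesh`; run [clean_mesh()] before measuring.
#' @export
build_fin_mesh <- function(planar, spec, n_chord = 60L) {
  stopifnot(inherits(spec, "mb_part_spec"), n_chord >= 8)
  stations <- planform_stations(planar, spec)
  env <- thickness_envelope(stations$span_frac, spec$thickest_frac)
  fin_mesh_impl(planar, spec, env, stations, n_chord)
}

#' Build a cephalofoil mesh from its planar outline
#'
#' Identical serial-NACA construction to [build_fin_mesh()], but with the
#' thickness envelope inverted: the two span ends (where a hammerhead's eye
#' sockets sit) are the thickest regions, with the envelope equal to 1 at
#' both ends and dipping to `spec$cephalofoil_min_factor` at midspan.
#'
#' @inheritParams build_fin_mesh
#' @return An uncleaned `mb_mesh`.
#' @export
build_cephalofoil_mesh <- function(planar, spec, n_chord = 60L) {
  stopifnot(inherits(spec, "mb_part_spec"), n_chord >= 8)
  stations <- planform_stations(planar, spec)
  env <- cephalofoil_envelope(stations$span_frac, spec$cephalofoil_min_factor)
  fin_mesh_impl(planar, spec, env, stations, n_chord)
}
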