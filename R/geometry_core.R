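#' Superelliptical section ring
#'
#' Generates the vertex ring of a superellipse
#' \deqn{|x/a|^n + |y/b|^n = 1}
#' at a given axial station. The exponent `n` controls how full the section
#' is: `n = 2` is an ellipse, larger values approach a rectangle, smaller
#' values a diamond. Vertices are placed at uniform steps of the angular
#' parameter (one vertex per 2 degrees at the default `m = 181`), using the
#' signed-power parametrization
#' `x = cx + a sgn(cos t)|cos t|^(2/n)`, `y = cy + b sgn(sin t)|sin t|^(2/n)`.
#' The first and the last vertex coincide; mesh cleaning later merges them,
#' so the default ring effectively has 180 distinct vertices.
#'
#' @param a,b Transverse and dorsoventral semi-axes in pixels (`> 0`).
#' @param n Superelliptical exponent (`> 0`).
#' @param m Vertex count including the duplicated closing vertex
#'   (default 181, i.e. one vertex per 2 degrees).
#' @param center Section center `(x, y)` in pixels.
#' @param z Axial station of the ring in pixels.
#' @return An `m` x 3 numeric matrix of `(x, y, z)` ring vertices with
#'   attributes `a`, `b`, `n`.
#' @examples
#' ring <- superellipse_vertices(100, 50, n = 2)
#' nrow(ring) # 181
#' @export
superellipse_vertices <- function(a, b, n, m = 181L, center = c(0, 0), z = 0) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    mb_abort("`n` must be a single positive exponent.", "invalid_exponent")
  }
  stopifnot(a > 0, b > 0, m >= 8)
  theta <- seq(0, 2 * pi, length.out = m)
  ct <- cos(theta)
  st <- sin(theta)
  x <- center[[1]] + a * sign(ct) * abs(ct)^(2 / n)
  y <- center[[2]] + b * sign(st) * abs(st)^(2 / n)
  ring <- cbind(x = x, y = y, z = rep(z, m))
  ## kill parametrization round-off so the closing vertex is exact
  ring[m, ] <- ring[1L, ]
  attr(ring, "a") <- a
  attr(ring, "b") <- b
  attr(ring, "n") <- n
  ring
}

#' Half-thickness of a symmetric NACA 4-digit foil section
#'
#' Evaluates the classical symmetric ("00xx") NACA 4-digit thickness
#' polynomial
#' \deqn{y = 5t\,(0.2969 \sqrt{x} - 0.1260 x - 0.3516 x^2 + 0.2843 x^3 -
#'       0.1015 x^4)}
#' where `x` is the chordwise position as a fraction of the chord and `t`
#' the section thickness as a fraction of the chord (so `t_pct = 20` gives
#' a section about 20% of chord thick at its thickest point, near
#' `x = 0.3`). The printed `-0.1015` trailing-edge coefficient is kept, so
#' the section is slightly open at `x = 1`; the fin mesher closes the
#' trailing edge geometrically.
#'
#' @param x_frac Chordwise position(s) in `[0, 1]`.
#' @param t_pct Thickness in percent of chord (`> 0`).
#' @return Half-thickness as a fraction of the chord, same length as
#'   `x_frac`; zero at the leading edge.
#' @examples
#' naca_half_thickness(0.3, 20) # ~0.1: full thickness ~20% of chord
#' @export
naca_half_thickness <- function(x_frac, t_pct) {
  if (any(!is.finite(x_frac)) || any(x_frac < 0) || any(x_frac > 1)) {
    mb_abort("`x_frac` must lie within the chord, i.e. in [0, 1].", "out_of_chord")
  }
  stopifnot(is.numeric(t_pct), t_pct > 0)
  x <- x_frac
  5 * (t_pct / 100) *
    (0.2969 * sqrt(x) - 0.1260 * x - 0.3516 * x^2 + 0.2843 * x^3 - 0.1015 * x^4)
}

#' Span-wise thickness envelope for fins and flippers
#'
#' Raw fin thickness is proportional to the local chord, which would put the
#' thickest part of the fin wherever the chord happens to be longest. To
#' force the thickest section to a chosen span position (the root of a
#' pectoral flipper, the middle of a symmetric caudal fin), the raw
#' thickness is rescaled by an envelope: the span axis from the thickest
#' point to each fin end is given a normalized coordinate `u` running from 1
#' (thickest point) to 0 (end), and the envelope factor is `sqrt(u)`. At the
#' midpoint between the thickest point and a tip the factor is therefore
#' `sqrt(0.5)`.
#'
#' @param span_fracs Span positions in `[0, 1]` (0 and 1 are the fin ends).
#'   Values outside are clamped with a warning.
#' @param thickest_frac Span fraction of the thickest section, in `[0, 1]`
#'   (0 for pectoral/pelvic/dorsal-type fins, 0.5 for a symmetric caudal
#'   fin). Clamped with a warning if outside.
#' @return Scale factors in `[0, 1]`, same length as `span_fracs`.
#' @examples
#' thickness_envelope(c(0, 0.5, 1), thickest_frac = 0)
#' @export
thickness_envelope <- function(span_fracs, thickest_frac) {
  if (any(span_fracs < 0 | span_fracs > 1) ||
      thickest_frac < 0 || thickest_frac > 1) {
    mb_warn("span positions clamped to [0, 1].", "clamped_span")
  }
  s <- pmin(pmax(span_fracs, 0), 1)
  tf <- min(max(thickest_frac, 0), 1)
  u <- numeric(length(s))
  lower <- s <= tf
  if (tf > 0) u[lower] <- s[lower] / tf else u[lower] <- 1
  if (tf < 1) u[!lower] <- (1 - s[!lower]) / (1 - tf) else u[!lower] <- 1
  sqrt(pmin(pmax(u, 0), 1))
}

#' End-thickened envelope for the hammerhead cephalofoil
#'
#' The cephalofoil (the "hammer" of hammerhead sharks) is thickest at its
#' two lateral ends, where the eye sockets sit, rather than tapering toward
#' the tips like a fin. This envelope is 1 at both span ends and dips to
#' `min_factor` at midspan, following the same square-root profile as
#' [thickness_envelope()] measured from midspan outward.
#'
#' @param span_fracs Span positions in `[0, 1]`; clamped with a warning.
#' @param min_factor Envelope value at midspan, in `(0, 1]`; default 0.6.
#'   The magnitude of the end thickening is not constrained by anatomy here
#'   and is deliberately exposed as a parameter.
#' @return Scale factors in `[min_factor, 1]`.
#' @export
cephalofoil_envelope <- function(span_fracs, min_factor = 0.6) {
  stopifnot(min_factor > 0, min_factor <= 1)
  if (any(span_fracs < 0 | span_fracs > 1)) {
    mb_warn("span positions clamped to [0, 1].", "clamped_span")
  }
  s <- pmin(pmax(span_fracs, 0), 1)
  u <- abs(2 * s - 1)
  min_factor + (1 - min_factor) * sqrt(u)
}
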