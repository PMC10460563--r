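---
title: "Bracketing body volume from orthogonal silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bracketing body volume from orthogonal silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massbracket)
```

## The problem and the model

Skeletonized, liquid-preserved, and fossil marine vertebrates carry no body
mass record, and limb-based regression estimators do not transfer to animals
that never support their weight on limbs. What such specimens often do
preserve — or allow a careful reconstruction of — is the body *silhouette*.
`massbracket` turns a pair of orthogonal silhouettes (lateral and ventral
views of the fin-less main body, plus one planar view per fin) into a pair of
3D models whose volumes bracket the true body volume, and converts volume to
mass at a configurable mean body density.

The key assumption is about cross-sectional shape. A transverse section of a
vertebrate body is well approximated by a superellipse,

$$\left|\frac{x}{a}\right|^{n} + \left|\frac{y}{b}\right|^{n} = 1,$$

where $a$ and $b$ are the transverse and dorsoventral semi-axes measured from
the two silhouettes, and the exponent $n$ controls the fullness of the
section: $n = 2$ is an ellipse, larger values approach a rectangle, smaller
values a diamond. Two models built from the *same* silhouettes differ only in
$n$; because section area is strictly increasing in $n$ at fixed semi-axes,
choosing a pair of exponents that straddle the animal's true sectional shape
brackets the true volume between the two model volumes. Empirically useful
brackets are 2.0–2.4 for marine tetrapods (2.0–2.3 for cetaceans
specifically), 1.8–2.0 for sharks, 1.8–2.1 for typical bony fish, 2.2–2.4
for fish with flattened ventral sides, and 1.6–1.7 for strongly compressed
forms; `exponent_preset()` exposes these. The choice is the user's — the
package makes no attempt to infer a clade from an image.

Working coordinates: $x$ is bilateral (right positive), $y$ dorsoventral
(dorsal positive), $z$ the body axis (snout at the origin, posterior
positive). All modeling happens in image pixels; the user-supplied body-axis
length in meters fixes the scale at the very end.

## Pipeline stages and the choices inside them

**Binarization and outline tracing.** Images decode through EBImage;
luminance is thresholded at 0.5 of full range with dark foreground by
default (both configurable), and only the largest connected component is
kept, which silently discards JPEG speckle. The boundary is extracted as the
0.5-level iso-contour of the binary grid (marching squares via
`grDevices::contourLines`), giving an ordered, closed, sub-pixel trace
rather than a pixel-edge walk. Anti-aliased edges therefore binarize to a
boundary within about half a pixel of the underlying curve.

**Smoothing.** The staircase trace is smoothed by locally-weighted
polynomial regression: the outline is split at its extreme axial points into
two branches, each treated as a function of the axial coordinate, and each
branch is fitted with `stats::loess` using tricube weights, local degree 2,
and a span equal to the nearest-neighbor fraction `nn` (default 0.1 for the
body; 0.05 suits small fin outlines). Degree 2 was chosen over degree 1
because it removes the leading curvature bias on convex outlines while still
reproducing locally affine stretches exactly; both satisfy the contract that
matters (affine data unchanged, noise variance reduced). Tied abscissae —
vertical staircase runs — are collapsed to their mean before fitting so the
local windows always span distinct abscissae; without this the local fit is
singular on flat stretches. Smoothing may be disabled, but stepped outlines
are the main cause of non-manifold geometry at the cleaning stage, and low
resolutions make this worse; the loader warns below 3000 px along the long
axis for exactly this reason.

**Axial profile.** For every integer pixel station along the body axis the
lateral outline gives the dorsoventral extent and the ventral outline the
transverse extent; diameters are the extent differences and section centers
their midpoints, converted to the dorsal-positive frame. The two views are
aligned at their anterior-most points and must agree in axial span to 1%
(residual one-pixel disagreements are rasterization noise; larger ones mean
unequal pixel scales). Centers are re-expressed relative to their mean — a
pure translation, invisible to volume and area — so that a symmetric tracing
yields a model symmetric about $x = 0$.

**Body meshing.** One superellipse ring per station (181 vertices, one per
2°, the first and last coincident), rings stitched by quad-split triangles
with consistent winding. The duplicated ring vertex is merged away during
cleaning, leaving 180 distinct vertices per section. Each end receives a
tiny superelliptical tip ring of radius $10^{-4}$ px one station beyond the
terminal section, closed by a centroid fan; after vertex merging this
collapses to a point and seals the mesh. At that radius the tips are
numerically invisible in both volume and area.

**Fins.** At every pixel station along the span the planar outline yields
the local chord, and a symmetric NACA 4-digit section of that chord is
drawn from the classical thickness polynomial
$y = 5t\,(0.2969\sqrt{x} - 0.1260x - 0.3516x^2 + 0.2843x^3 - 0.1015x^4)$,
with $t$ the thickness as a fraction of chord (`base_t_pct`, default 20% of
chord, 10% for the anal and second dorsal fins). The printed $-0.1015$
coefficient leaves the trailing edge slightly open; it is kept verbatim and
the mesher closes each section geometrically by joining the upper and lower
surfaces at the trailing edge, rather than substituting the closed-edge
$-0.1036$ variant. Chordwise sampling uses 60 points per surface,
cosine-clustered toward the leading edge where curvature concentrates — a
sampling choice, not part of the model.

Raw thickness proportional to chord would put the thickest part of the fin
wherever the chord is longest, so thickness is rescaled by a span-wise
envelope: the span from the thickest station (`thickest_frac`, 0 at the
root for pectoral/pelvic/dorsal-type fins, 0.5 for a symmetric caudal fin)
to each end is renormalized to run from 1 to 0 and the envelope is the
square root of that coordinate — $\sqrt{0.5} \approx 0.707$ midway between
thickest point and tip. A span end where the envelope vanishes is pinched
flat and closes itself; an open end (a fin root) is closed with a tip ring
and fan like the body. The cephalofoil of hammerhead sharks uses the same
serial-NACA construction with the envelope inverted: 1 at both span ends
(the eye-socket regions), dipping to a configurable minimum at midspan. How
strong that end-thickening is has no published value; the default minimum
factor of 0.6 is an explicit, exposed guess, not an inference.

**Cleaning and measurement.** Cleaning snaps vertices onto a grid of pitch
`merge_tol_px` ($10^{-4}$ px) and merges coincident ones, drops
topologically degenerate and duplicate faces, verifies that every edge
borders exactly two faces, and orients the surface so the enclosed volume
is positive. Zero-area faces with three distinct vertices are deliberately
*kept*: they carry topology, removing them would open holes, and they
contribute nothing to any measurement. Failure to close is an error, not a
warning, because volume is undefined on an open surface; in practice it
signals unsmoothed or very low-resolution input. Volume is the absolute
signed-tetrahedron sum over faces (divergence theorem); area is the plain
triangle-area sum. Exact integer grouping (chained `match()` keys) rather
than string hashing keeps cleaning a million-face body mesh to a couple of
seconds in pure R.

**Mass.** Part volumes are summed — overlap between fins and body is counted
twice, by design; a Boolean union is out of scope until stable tooling
exists in R — and converted at two densities: seawater (1.027 g/cm³, the
neutral-buoyancy default for animals with lungs or air bladders) and an
adjustable second density defaulting to 1.000 g/cm³. Fins carry no
exponent, so each fin is meshed once and shared between the low- and
high-exponent totals. Part placement (roll about $z$, then pitch about $x$,
then yaw about $y$, about the part's planform centroid, then translation)
exists for assembling a visual whole-animal mesh only; measurement always
happens on unplaced parts.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_low`, `n_high` | 2.0, 2.4 | – | tetrapod bracket; presets per clade |
| `m_vertices` | 181 | vertices/section | one per 2°; 180 after merging |
| `nn_body`, `nn_fin` | 0.1 | fraction of branch points | smoothing span |
| `tip_radius_px` | 1e-4 | px | end tips collapse under merging |
| `merge_tol_px` | 1e-4 | px | vertex merge grid pitch |
| `base_t_pct` | 20 (10 anal/2nd dorsal) | % of chord | NACA section thickness |
| `thickest_frac` | 0 (0.5 caudal) | span fraction | envelope peak |
| `rho_seawater`, `rho_user` | 1.027, 1.000 | g/cm³ | mass conversion |
| `threshold` | 0.5 | luminance fraction | binarization |

Every default applied in a run is echoed in the report metadata.

## What the synthetic fixtures do and do not show

All test inputs are rendered in code: anti-aliased circles, 5:1 ellipses,
rectangles, and a synthetic fish (elliptical body, rectangular fin
planforms) drawn with 4× supersampling, which mimics how vector drawings
exported to raster behave at edges. Their ground truths are closed forms
(sphere, prolate spheroid) or $10^4$-station quadrature of the closed-form
section area, computed independently of the mesh path. On these, the
$n = 2$ pipeline recovers volume and area to better than 0.1% at 3000 px
and better than 0.5% from 800 px up, errors shrink with resolution, and a
spheroid's true volume falls strictly inside the $[V(1.9), V(2.1)]$
bracket.

What passing these tests does *not* show: real animals have concave
flanks, curved vertebral axes, fins that violate the no-camber assumption,
and hand-traced outlines with errors that dominate the method's own ~0.1%
geometric error. The fixtures validate the geometry engine and the
bracketing mechanics, not the biological accuracy of any particular
reconstruction — that rests on the quality of the silhouettes and the
chosen exponent bracket.

## Numerical choices and degenerate inputs

Station extents are interpolated per branch with `approx(ties = mean)`, so
vertical runs in a trace average cleanly. Zero diameters are tolerated only
at profile ends (tapered out); an interior zero is an error, since the
workflow guarantees one connected part per image. A silhouette under 2 px
in either dimension cannot be traced; an outline under 10 points cannot be
smoothed. Envelope inputs outside $[0, 1]$ are clamped with a warning.
Mesh export defaults to binary little-endian PLY with double-precision
coordinates so an export/import round trip preserves volume to $10^{-6}$
relative or better; ASCII PLY, OBJ, and binary STL are also supported, and
the STL importer re-merges bit-identical vertices to restore indexing.

Test problem sizes were chosen to exercise every regime while keeping the
suite quick: module tests run at 120–1000 px, the validation protocol at
its recommended 3000 px, and the resolution-sweep machinery enumerates the
full 100–10,000 px schedule while the automated checks sample it at 400,
800, 1000, and 3000 px.

## Known limitations

Straight body axes only; no lateral body concavities or dorso-ventral fin
concavities; no cambered or swept foils; no Boolean union of parts (overlap
is double-counted); no automatic background removal or photograph
segmentation; one part per image. The smoothing span is a real tradeoff:
larger `nn` suppresses staircase noise better but rounds genuine corners
(a rectangle's corners visibly shorten at `nn = 0.1`), which is why the fin
default is worth lowering for small, angular planforms.
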