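#' Body density configuration
#'
#' Marine vertebrates that regulate buoyancy with lungs or an air bladder
#' experience neutral buoyancy over part of daily life, so the mean body
#' density near the sea surface is taken as that of seawater,
#' 1.027 g/cm^3; the corresponding fresh-water value is about 1 g/cm^3 and
#' is user-adjustable. Masses are reported at both densities.
#'
#' @param rho_seawater Seawater density in g/cm^3 (default 1.027).
#' @param rho_user Adjustable second density in g/cm^3 (default 1.000).
#' @return A list of class `mb_density_config`.
#' @export
density_config <- function(rho_seawater = 1.027, rho_user = 1.000) {
  stopifnot(rho_seawater > 0, rho_user > 0)
  structure(list(rho_seawater = rho_seawater, rho_user = rho_user),
            class = "mb_density_config")
}

#' Place a part mesh in the body frame
#'
#' Applies the part's rigid placement: rotation about the z axis (roll),
#' then about x (pitch), then about y (yaw) — roll first is the canonical
#' order — followed by the translation. Rotations pivot about the part's
#' planform centroid (carried on fin meshes as the `pivot` attribute; the
#' vertex centroid is used as a fallback). Rigid motion leaves volume and
#' area untouched, and placement is for assembling the visual whole-body
#' model only: measurement always happens on the unplaced parts.
#'
#' @param mesh An `mb_mesh`.
#' @param spec A [part_spec()] holding `roll`, `pitch`, `yaw` (degrees) and
#'   `translation` (pixels).
#' @return The transformed `mb_mesh`.
#' @export
place_part <- function(mesh, spec) {
  stopifnot(inherits(mesh, "mb_mesh"), inherits(spec, "mb_part_spec"))
  d2r <- pi / 180
  cr <- cos(spec$roll * d2r);  sr <- sin(spec$roll * d2r)
  cp <- cos(spec$pitch * d2r); sp <- sin(spec$pitch * d2r)
  cy <- cos(spec$yaw * d2r);   sy <- sin(spec$yaw * d2r)
  Rz <- matrix(c(cr, sr, 0, -sr, cr, 0, 0, 0, 1), 3)  # roll
  Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3)  # pitch
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)  # yaw
  pivot <- attr(mesh, "pivot") %||% colMeans(mesh$vertices)
  out <- rotate_mesh(mesh, Ry %*% Rx %*% Rz, pivot = pivot)
  out <- translate_mesh(out, spec$translation)
  attr(out, "pivot") <- pivot + spec$translation
  attr(out, "part_type") <- attr(mesh, "part_type")
  out
}

#' Summarize bracketed volumes, areas, and masses into a model report
#'
#' Measures the low- and high-exponent body meshes and every part mesh,
#' converts pixel measures to SI units, sums them into bracketing totals,
#' and converts total volume to mass at each configured density
#' (`mass [kg] = volume [m^3] x density [g/cm^3] x 1000`). Fins carry no
#' superelliptical exponent, so each part is measured once and shared
#' between the two body models. Where parts overlap the body, the overlap
#' is counted twice — the bracketing totals are sums of part volumes, not a
#' Boolean union — which inflates totals slightly but predictably.
#'
#' @param body_low,body_high Cleaned body meshes at the low and high
#'   exponents.
#' @param parts Named list of cleaned part meshes (possibly empty).
#' @param scale A [unit_scale()].
#' @param densities A [density_config()].
#' @param meta Optional named list merged into the report metadata.
#' @return An object of class `mb_report`; see [tidy.mb_report()] and
#'   [glance.mb_report()].
#' @export
summarize_model <- function(body_low, body_high, parts = list(),
                            scale, densities = density_config(),
                            meta = list()) {
  stopifnot(inherits(scale, "mb_unit_scale"),
            inherits(densities, "mb_density_config"))
  meshes <- c(list(body = body_low), parts)
  for (nm in names(meshes)) {
    if (!isTRUE(meshes[[nm]]$watertight)) {
      mb_abort(sprintf("mesh '%s' is not watertight; clean it before summarizing.",
                       nm), "not_watertight")
    }
  }
  if (!isTRUE(body_high$watertight)) {
    mb_abort("high-exponent body mesh is not watertight.", "not_watertight")
  }
  if (length(parts) && is.null(names(parts))) {
    names(parts) <- paste0("part_", seq_along(parts))
  }
  n_low <- meta$n_low %||% NA_real_
  n_high <- meta$n_high %||% NA_real_
  part_v <- vapply(parts, function(p) to_si(mesh_volume(p), scale, 3), numeric(1))
  part_a <- vapply(parts, function(p) to_si(mesh_area(p), scale, 2), numeric(1))
  body_v <- c(low = to_si(mesh_volume(body_low), scale, 3),
              high = to_si(mesh_volume(body_high), scale, 3))
  body_a <- c(low = to_si(mesh_area(body_low), scale, 2),
              high = to_si(mesh_area(body_high), scale, 2))
  sections <- dplyr::bind_rows(
    tibble::tibble(component = "body", model = c("low", "high"),
                   exponent = c(n_low, n_high),
                   volume_m3 = as.numeric(body_v), area_m2 = as.numeric(body_a)),
    if (length(parts)) {
      tibble::tibble(component = rep(names(parts), each = 2),
                     model = rep(c("low", "high"), length(parts)),
                     exponent = rep(c(n_low, n_high), length(parts)),
                     volume_m3 = rep(as.numeric(part_v), each = 2),
                     area_m2 = rep(as.numeric(part_a), each = 2))
    })
  totals <- sections |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(volume_m3 = sum(.data$volume_m3),
                     area_m2 = sum(.data$area_m2), .groups = "drop") |>
    dplyr::arrange(match(.data$model, c("low", "high")))
  rho <- c(seawater = densities$rho_seawater, user = densities$rho_user)
  masses <- tibble::tibble(
    density_label = rep(names(rho), each = 2),
    density_g_cm3 = rep(as.numeric(rho), each = 2),
    model = rep(c("low", "high"), 2),
    mass_kg = rep(as.numeric(rho), each = 2) * 1000 *
      totals$volume_m3[match(rep(c("low", "high"), 2), totals$model)])
  structure(list(sections = sections, totals = totals, masses = masses,
                 meta = utils::modifyList(list(
                   m_per_px = scale$m_per_px,
                   body_axis_m = scale$body_axis_m,
                   body_axis_px = scale$body_axis_px,
                   rho_seawater = densities$rho_seawater,
                   rho_user = densities$rho_user,
                   rotation_pivot = "planform centroid",
                   version = as.character(utils::packageVersion("massbracket"))),
                   meta)),
            class = "mb_report")
}

#' @export
print.mb_report <- function(x, ...) {
  lo <- x$totals[x$totals$model == "low", ]
  hi <- x$totals[x$totals$model == "high", ]
  cat(sprintf("<mb_report> exponents [%s, %s]\n",
              format(x$meta$n_low), format(x$meta$n_high)))
  cat(sprintf("  volume: %.6g - %.6g m^3\n", lo$volume_m3, hi$volume_m3))
  cat(sprintf("  area:   %.6g - %.6g m^2\n", lo$area_m2, hi$area_m2))
  for (lab in unique(x$masses$density_label)) {
    mm <- x$masses[x$masses$density_label == lab, ]
    cat(sprintf("  mass @ %.3f g/cm^3 (%s): %.6g - %.6g kg\n",
                mm$density_g_cm3[1], lab,
                mm$mass_kg[mm$model == "low"], mm$mass_kg[mm$model == "high"]))
  }
  invisible(x)
}

#' Tidy a model report
#'
#' One row per component x model (low/high exponent), with volumes and
#' areas in SI units.
#'
#' @param x An `mb_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mb_report <- function(x, ...) x$sections

#' One-row summary of a model report
#'
#' @param x An `mb_report`.
#' @param ... Unused.
#' @return A one-row tibble with bracketing totals and seawater-density
#'   masses.
#' @export
glance.mb_report <- function(x, ...) {
  lo <- x$totals[x$totals$model == "low", ]
  hi <- x$totals[x$totals$model == "high", ]
  msw <- x$masses[x$masses$density_label == "seawater", ]
  tibble::tibble(
    n_low = x$meta$n_low %||% NA_real_,
    n_high = x$meta$n_high %||% NA_real_,
    volume_low_m3 = lo$volume_m3, volume_high_m3 = hi$volume_m3,
    area_low_m2 = lo$area_m2, area_high_m2 = hi$area_m2,
    mass_low_kg = msw$mass_kg[msw$model == "low"],
    mass_high_kg = msw$mass_kg[msw$model == "high"])
}

#' Write a model report to JSON and CSV
#'
#' The JSON carries the full report including metadata; the CSV is flat,
#' one row per component x model x density.
#'
#' @param report An `mb_report`.
#' @param dir Output directory (created if missing).
#' @param stem File name stem, default `"report"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir, stem = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, paste0(stem, ".json"))
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  payload <- list(sections = report$sections, totals = report$totals,
                  masses = report$masses, meta = report$meta)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  flat <- dplyr::cross_join(report$sections,
                            unique(report$masses[, c("density_label",
                                                     "density_g_cm3")]))
  utils::write.csv(flat, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
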