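test_that("fixture ground truths follow the closed forms", {
  fx <- cached_fixture("circle", 200)
  expect_equal(fx$truth$volume_px3, 4 / 3 * pi * 100^3)
  expect_equal(fx$truth$area_px2, 4 * pi * 100^2)
  fe <- cached_fixture("ellipse", 300)
  a <- 150
  b <- 30
  e <- sqrt(1 - (b / a)^2)
  expect_equal(fe$truth$volume_px3, 4 / 3 * pi * a * b^2)
  expect_equal(fe$truth$area_px2, 2 * pi * b^2 * (1 + a / (b * e) * asin(e)))
  expect_true(file.exists(fe$truth_path))
})

test_that("the validation sweep covers 19 resolutions from 100 to 10000", {
  res <- fixture_resolutions()
  expect_length(res, 19L)
  expect_equal(range(res), c(100L, 10000L))
  expect_true(all(diff(res[res <= 1000]) == 100))
  expect_true(all(diff(res[res >= 1000]) == 1000))
})

test_that("superellipse-profile ground truth agrees with an independent quadrature", {
  fx <- cached_fixture("superellipse_profile", 300, n_true = 2.5)
  ## independent check: integrate() on the closed-form section area
  A <- 150
  B <- 30
  g <- 4 * gamma(1 + 1 / 2.5)^2 / gamma(1 + 2 / 2.5)
  v <- stats::integrate(function(z) g * (B * sqrt(pmax(1 - (z / A)^2, 0)))^2,
                        -A, A, rel.tol = 1e-10)$value
  expect_equal(fx$truth$volume_px3, v, tolerance = 1e-5)
})

test_that("the pipeline reproduces a small sphere within the error bound", {
  run <- cached_geometry_run("circle", 400)
  expect_lt(abs(run$vol_err_pct), 0.5)
  expect_lt(abs(run$area_err_pct), 0.5)
})

test_that("the pipeline brackets the synthetic fish oracle", {
  fx <- cached_fixture("synthetic_fish", 400)
  cfg <- run_config(fx$images[["lateral"]], fx$images[["ventral"]],
                    body_axis_m = 0.4,
                    parts = list(caudal = list(path = fx$images[["caudal"]]),
                                 dorsal = list(path = fx$images[["dorsal"]])),
                    n_low = 2, n_high = 2)
  rep <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  expect_equal(sort(unique(tidy(rep)$component)),
               c("body", "caudal", "dorsal"))
  tot_px <- rep$totals$volume_m3[1] / (0.4 / rep$meta$body_axis_px)^3
  expect_lt(abs(tot_px - fx$truth$volume_px3) / fx$truth$volume_px3, 0.02)
})

test_that("single optional part runs list exactly that part", {
  fx <- cached_fixture("synthetic_fish", 400)
  cfg <- run_config(fx$images[["lateral"]], fx$images[["ventral"]],
                    body_axis_m = 0.4,
                    parts = list(caudal = list(path = fx$images[["caudal"]])),
                    n_low = 1.8, n_high = 2.1)
  rep <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  expect_equal(setdiff(unique(tidy(rep)$component), "body"), "caudal")
  g <- glance(rep)
  expect_lt(g$volume_low_m3, g$volume_high_m3)
})

test_that("invalid exponent ordering is rejected at configuration", {
  fx <- cached_fixture("circle", 200)
  expect_error(run_config(fx$images[["lateral"]], fx$images[["ventral"]],
                          body_axis_m = 1, n_low = 2.4, n_high = 2.0),
               class = "massbracket_error_bad_config")
})

test_that("clade presets give the documented exponent brackets", {
  expect_equal(unname(exponent_preset("tetrapod")), c(2.0, 2.4))
  expect_equal(unname(exponent_preset("shark")), c(1.8, 2.0))
  expect_equal(unname(exponent_preset("fish")), c(1.8, 2.1))
  expect_equal(unname(exponent_preset("v_shaped_fish")), c(1.6, 1.7))
})

test_that("two identical runs produce byte-identical reports", {
  fx <- cached_fixture("circle", 200)
  cfg <- run_config(fx$images[["lateral"]], fx$images[["ventral"]],
                    body_axis_m = 1, n_low = 2, n_high = 2.2)
  r1 <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  r2 <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  j <- function(r) jsonlite::toJSON(list(r$sections, r$totals, r$masses),
                                    digits = NA)
  expect_identical(j(r1), j(r2))
})

test_that("pipeline writes meshes and reports when an output dir is set", {
  fx <- cached_fixture("circle", 200)
  out <- file.path(tempdir(), "mb-out")
  unlink(out, recursive = TRUE)
  cfg <- run_config(fx$images[["lateral"]], fx$images[["ventral"]],
                    body_axis_m = 1, n_low = 2, n_high = 2.2,
                    output_dir = out, export_formats = "ply")
  rep <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  expect_true(file.exists(file.path(out, "body_low.ply")))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "report.csv")))
  back <- read_mesh(file.path(out, "body_low.ply"))
  expect_equal(nrow(back$faces),
               nrow(clean_mesh(read_mesh(file.path(out, "body_low.ply")))$faces))
  ## defaults echoed in metadata
  expect_equal(rep$meta$nn_body, 0.1)
  expect_equal(rep$meta$tip_radius_px, 1e-4)
})

test_that("YAML configuration round-trips through read_run_config", {
  fx <- cached_fixture("synthetic_fish", 400)
  yml <- file.path(tempdir(), "cfg.yaml")
  yaml::write_yaml(list(
    body_lateral = fx$images[["lateral"]],
    body_ventral = fx$images[["ventral"]],
    body_axis_m = 0.4,
    n_low = 1.8, n_high = 2.1,
    parts = list(caudal = list(path = fx$images[["caudal"]],
                               part_type = "caudal", base_t_pct = 15))), yml)
  cfg <- read_run_config(yml, n_high = 2.0)
  expect_equal(cfg$n_high, 2.0) # override wins
  expect_equal(cfg$parts$caudal$spec$base_t_pct, 15)
  expect_s3_class(cfg, "mb_run_config")
})

test_that("autoplot methods return ggplot objects", {
  fx <- cached_fixture("circle", 200)
  tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
  pr <- build_axial_profile(tr, tr)
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(autoplot(pr), "ggplot")
  cube <- clean_mesh(cube_mesh())
  rep <- summarize_model(cube, cube, list(), unit_scale(1, 1),
                         meta = list(n_low = 2, n_high = 2))
  expect_s3_class(autoplot(rep), "ggplot")
})
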