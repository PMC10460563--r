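test_that("smoothing reproduces straight boundary stretches exactly", {
  ## long thin rhombus: each branch is affine away from the kinks
  n_half <- 60
  u <- c(seq(0, 100, length.out = n_half), seq(100, 0, length.out = n_half))
  v <- c(seq(0, 10, length.out = n_half), seq(-10, 0, length.out = n_half))
  tr <- tibble::tibble(u = u, v = v)
  sm <- smooth_outline(tr, nn = 0.1)
  ## points well inside an affine stretch are reproduced to round-off
  mid <- 20:40
  expect_lt(max(abs(sm$v[mid] - tr$v[mid])), 1e-6)
  expect_equal(nrow(sm), nrow(tr))
})

test_that("smoothing shrinks the radial error of a jittered circle", {
  set.seed(42)
  tr <- circle_outline(r = 500, n_pts = 1200)
  jit <- tr
  jit$v <- jit$v + runif(nrow(jit), -1, 1)
  rms <- function(t) {
    sqrt(mean((sqrt(t$u^2 + t$v^2) - 500)^2))
  }
  sm <- smooth_outline(jit, nn = 0.1)
  expect_lt(rms(sm), rms(jit))
})

test_that("small fin outlines accept the tighter smoothing span", {
  fx <- cached_fixture("synthetic_fish", 400)
  sil <- load_silhouette(fx$images[["caudal"]], view = "planar",
                         warn_below_px = 0)
  tr <- extract_outline(sil)
  sm <- smooth_outline(tr, nn = 0.05)
  expect_equal(nrow(sm), nrow(tr))
  expect_false(identical(sm$v, tr$v))
})

test_that("too few points for the local window is an error", {
  tr <- tibble::tibble(u = c(0, 1, 2, 1), v = c(0, 1, 0, -1))
  expect_error(smooth_outline(tr, nn = 0.1),
               class = "massbracket_error_too_few_points")
})

test_that("a circle used as both views gives equal semi-axes per station", {
  fx <- cached_fixture("circle", 400)
  tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
  sm <- smooth_outline(tr)
  pr <- build_axial_profile(sm, sm)
  interior <- pr[pr$z_px > 10 & pr$z_px < max(pr$z_px) - 10, ]
  expect_lt(max(abs(interior$dv_diameter_px - interior$tv_diameter_px)), 0.5)
})

test_that("station count equals the foreground extent along the body axis", {
  fx <- cached_fixture("circle", 400)
  tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
  pr <- build_axial_profile(tr, tr)
  expect_equal(nrow(pr), 400L)
  expect_equal(attr(pr, "n_stations"), 400L)
  expect_equal(pr$z_px, 0:399)
})

test_that("rectangle views give constant interior diameters", {
  fx <- cached_fixture("rectangle", 200, aspect = 0.5) # lateral 100, ventral 50
  lat <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
  ven <- extract_outline(suppressWarnings(load_silhouette(fx$images[["ventral"]])))
  pr <- build_axial_profile(lat, ven)
  interior <- pr[pr$z_px %in% 5:194, ]
  expect_true(all(abs(interior$dv_diameter_px - fx$truth$dv_px) < 1e-9))
  expect_true(all(abs(interior$tv_diameter_px - fx$truth$tv_px) < 1e-9))
})

test_that("diameters are invariant under translation of the silhouette", {
  tr <- circle_outline(r = 80, n_pts = 500, center = c(100, 100))
  tr2 <- circle_outline(r = 80, n_pts = 500, center = c(137, 212))
  p1 <- build_axial_profile(tr, tr)
  p2 <- build_axial_profile(tr2, tr2)
  expect_equal(p1$dv_diameter_px, p2$dv_diameter_px, tolerance = 1e-9)
  expect_equal(p1$tv_diameter_px, p2$tv_diameter_px, tolerance = 1e-9)
})

test_that("mirror-symmetric ventral views center x at zero", {
  fx <- cached_fixture("ellipse", 300)
  tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["ventral"]])))
  pr <- build_axial_profile(smooth_outline(tr), smooth_outline(tr))
  expect_lt(max(abs(pr$x_center_px)), 0.5)
})

test_that("views of clearly different axial extent are rejected", {
  a <- circle_outline(r = 100, n_pts = 400)
  b <- circle_outline(r = 80, n_pts = 400)
  expect_error(build_axial_profile(a, b),
               class = "massbracket_error_view_length_mismatch")
})

test_that("unsmoothed diameters track smoothed ones for smooth shapes", {
  fx <- cached_fixture("circle", 400)
  tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
  pr_raw <- build_axial_profile(tr, tr)
  sm <- smooth_outline(tr)
  pr_sm <- build_axial_profile(sm, sm)
  ## compare over the central half of the sphere, where the boundary slope
  ## stays below ~0.6; at the steep end caps a half-pixel staircase step
  ## exceeds a pixel of diameter by itself
  interior <- pr_raw$z_px > 100 & pr_raw$z_px < 300
  d <- abs(pr_raw$dv_diameter_px[interior] - pr_sm$dv_diameter_px[interior])
  ## each branch of the raw trace is quantized to half a pixel, so the two
  ## can stack to ~1 px of diameter at isolated stations
  expect_lt(stats::quantile(d, 0.9), 1)
  expect_lt(max(d), 1.5)
})
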