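test_that("cube volume and area are exact", {
  cube <- clean_mesh(cube_mesh())
  expect_true(cube$watertight)
  expect_equal(mesh_volume(cube), 1.0)
  expect_equal(mesh_area(cube), 6.0)
})

test_that("icosphere volume and area match the closed forms within 0.1%", {
  sph <- icosphere(r = 3, subdiv = 5) # ~20k faces
  expect_gt(nrow(sph$faces), 15000)
  expect_lt(abs(mesh_volume(sph) - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 1e-3)
  expect_lt(abs(mesh_area(sph) - 4 * pi * 9) / (4 * pi * 9), 1e-3)
})

test_that("winding reversal does not change the measured magnitude", {
  cube <- clean_mesh(cube_mesh())
  flipped <- mb_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  flipped <- clean_mesh(flipped)
  expect_equal(mesh_volume(flipped), mesh_volume(cube))
})

test_that("duplicated vertices merge and cleaning is idempotent", {
  cube <- cube_mesh()
  dup <- mb_mesh(rbind(cube$vertices, cube$vertices),
                 rbind(cube$faces, cube$faces + 8L))
  cleaned <- clean_mesh(dup)
  expect_equal(nrow(cleaned$vertices), 8L)
  expect_equal(nrow(cleaned$faces), 12L)
  expect_true(cleaned$watertight)
  again <- clean_mesh(cleaned)
  expect_equal(nrow(again$vertices), nrow(cleaned$vertices))
  expect_equal(nrow(again$faces), nrow(cleaned$faces))
  expect_equal(mesh_volume(again), 1.0)
})

test_that("volume requires watertightness; open meshes fail cleaning", {
  cube <- cube_mesh()
  expect_error(mesh_volume(cube), class = "massbracket_error_not_watertight")
  open_mesh <- mb_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(clean_mesh(open_mesh), class = "massbracket_error_not_closeable")
})

test_that("degenerate triangles have zero area", {
  degen <- mb_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   rbind(c(1, 2, 3)))
  expect_equal(mesh_area(degen), 0)
})

test_that("volume and area are rigid-motion invariant", {
  sph <- icosphere(r = 2, subdiv = 3)
  v0 <- mesh_volume(sph)
  a0 <- mesh_area(sph)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- massbracket:::rotate_mesh(massbracket:::translate_mesh(sph, c(5, -3, 11)),
                                     rot, pivot = c(1, 2, 3))
  expect_lt(abs(mesh_volume(moved) - v0) / v0, 1e-9)
  expect_lt(abs(mesh_area(moved) - a0) / a0, 1e-9)
})

test_that("face subdivision changes neither volume nor area", {
  sph <- icosphere(r = 1.5, subdiv = 3)
  sub <- mesh_subdivide(sph)
  expect_equal(nrow(sub$faces), 4L * nrow(sph$faces))
  expect_lt(abs(mesh_volume(sub) - mesh_volume(sph)) / mesh_volume(sph), 1e-9)
  expect_lt(abs(mesh_area(sub) - mesh_area(sph)) / mesh_area(sph), 1e-9)
})

test_that("export/import round-trips preserve counts and volume", {
  sph <- icosphere(r = 1, subdiv = 2)
  for (fmt in c("ply", "obj", "stl")) {
    p <- file.path(fixture_dir(), paste0("roundtrip.", fmt))
    export_mesh(sph, p)
    back <- clean_mesh(read_mesh(p), merge_tol_px = 1e-9)
    expect_equal(nrow(back$vertices), nrow(sph$vertices))
    expect_equal(nrow(back$faces), nrow(sph$faces))
    expect_lt(abs(mesh_volume(back) - mesh_volume(sph)) / mesh_volume(sph),
              1e-6)
  }
  ## ASCII PLY round-trips too
  p <- file.path(fixture_dir(), "ascii.ply")
  export_mesh(sph, p, ascii = TRUE)
  back <- clean_mesh(read_mesh(p), merge_tol_px = 1e-9)
  expect_lt(abs(mesh_volume(back) - mesh_volume(sph)) / mesh_volume(sph), 1e-6)
})

test_that("re-imported faces keep outward orientation", {
  cube <- clean_mesh(cube_mesh())
  p <- file.path(fixture_dir(), "wind.obj")
  export_mesh(cube, p)
  back <- read_mesh(p)
  expect_gt(massbracket:::signed_volume(back), 0)
})

test_that("unknown mesh formats are rejected", {
  cube <- clean_mesh(cube_mesh())
  expect_error(export_mesh(cube, file.path(fixture_dir(), "cube.xyz")),
               class = "massbracket_error_unsupported_format")
  expect_error(read_mesh(file.path(fixture_dir(), "cube.xyz")),
               class = "massbracket_error_unsupported_format")
})

test_that("pixel-to-SI conversion follows the scale and dimension", {
  sc <- unit_scale(3.0, 3000)
  expect_equal(sc$m_per_px, 1e-3)
  expect_equal(to_si(1, sc, 3), 1e-9)
  expect_equal(to_si(1e6, sc, 2), 1)
  expect_error(to_si(1, sc, 4), class = "massbracket_error_bad_dimension")
})
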