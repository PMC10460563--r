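test_that("an image with no foreground is rejected", {
  p <- file.path(fixture_dir(), "blank.png")
  EBImage::writeImage(EBImage::Image(matrix(1, 32, 32)), p)
  expect_error(load_silhouette(p), class = "massbracket_error_empty_silhouette")
})

test_that("undecodable files and missing files raise unreadable_image", {
  p <- file.path(fixture_dir(), "not_an_image.png")
  writeLines("this is not a PNG", p)
  expect_error(load_silhouette(p), class = "massbracket_error_unreadable_image")
  expect_error(load_silhouette(file.path(fixture_dir(), "nope.png")),
               class = "massbracket_error_unreadable_image")
})

test_that("a high-resolution circle binarizes to the right pixel count", {
  fx <- cached_fixture("circle", 3000)
  sil <- load_silhouette(fx$images[["lateral"]])
  ## oracle: exact pixel-center rasterization of the same disk
  r <- 1500
  W <- 3008L
  cc <- (W + 1) / 2
  d2 <- outer((seq_len(W) - cc)^2, (seq_len(W) - cc)^2, "+")
  oracle <- sum(d2 <= r^2)
  expect_lt(abs(sum(sil$grid) - oracle) / oracle, 0.002)
  expect_equal(sil$view_tag, "lateral")
})

test_that("low-resolution silhouettes load with a resolution warning", {
  fx <- cached_fixture("circle", 800)
  expect_warning(load_silhouette(fx$images[["lateral"]]),
                 class = "massbracket_warning_low_resolution")
  sil <- suppressWarnings(load_silhouette(fx$images[["lateral"]]))
  expect_s3_class(sil, "mb_silhouette")
  expect_gt(sum(sil$grid), 0)
})

test_that("binarization is idempotent on an already-binary image", {
  fx <- cached_fixture("circle", 200)
  sil1 <- suppressWarnings(load_silhouette(fx$images[["lateral"]]))
  p2 <- file.path(fixture_dir(), "rebinarized.png")
  EBImage::writeImage(EBImage::Image(t(1 - sil1$grid)), p2)
  sil2 <- suppressWarnings(load_silhouette(p2))
  expect_identical(sil1$grid, sil2$grid)
})

test_that("speckles are dropped: only the largest component is kept", {
  m <- matrix(1, 64, 64)
  m[20:40, 20:40] <- 0 # main blob (dark foreground)
  m[5, 5] <- 0         # speck
  p <- file.path(fixture_dir(), "speck.png")
  EBImage::writeImage(EBImage::Image(t(m)), p)
  sil <- suppressWarnings(load_silhouette(p))
  expect_equal(sum(sil$grid), 21L * 21L)
})

test_that("outline of a filled square has the square's bounding box", {
  m <- matrix(1, 24, 24)
  m[8:17, 6:15] <- 0 # 10 x 10 square
  p <- file.path(fixture_dir(), "square.png")
  EBImage::writeImage(EBImage::Image(t(m)), p)
  tr <- extract_outline(suppressWarnings(load_silhouette(p)))
  expect_equal(diff(range(tr$u)), 10)
  expect_equal(diff(range(tr$v)), 10)
})

test_that("rectangle outline length approaches 2(W + H)", {
  ## corner cuts are a constant ~1.2 px, so use a perimeter that dwarfs them
  m <- matrix(1, 40, 80)
  m[9:28, 11:70] <- 0 # 20 x 60 rectangle
  p <- file.path(fixture_dir(), "rect_perim.png")
  EBImage::writeImage(EBImage::Image(t(m)), p)
  tr <- extract_outline(suppressWarnings(load_silhouette(p)))
  seg <- sqrt(diff(c(tr$u, tr$u[1]))^2 + diff(c(tr$v, tr$v[1]))^2)
  expect_lt(abs(sum(seg) - 160) / 160, 0.02)
})

test_that("circle outline points sit on the analytic circle within a pixel", {
  fx <- cached_fixture("circle", 1000)
  tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
  d <- sqrt((tr$u - mean(range(tr$u)))^2 + (tr$v - mean(range(tr$v)))^2)
  expect_true(all(abs(d - 500) <= 1))
})

test_that("sub-degenerate silhouettes cannot be traced", {
  m <- matrix(1, 16, 16)
  m[8, 8] <- 0 # single pixel
  p <- file.path(fixture_dir(), "pixel.png")
  EBImage::writeImage(EBImage::Image(t(m)), p)
  sil <- suppressWarnings(load_silhouette(p))
  expect_error(extract_outline(sil),
               class = "massbracket_error_degenerate_silhouette")
})

test_that("doubling resolution roughly halves the boundary error", {
  err_for <- function(L) {
    fx <- cached_fixture("circle", L)
    tr <- extract_outline(suppressWarnings(load_silhouette(fx$images[["lateral"]])))
    d <- sqrt((tr$u - mean(range(tr$u)))^2 + (tr$v - mean(range(tr$v)))^2)
    mean(abs(d - L / 2)) / (L / 2) # relative radial error
  }
  e200 <- err_for(200)
  e400 <- err_for(400)
  expect_lt(e400, e200 * 0.7) # ~0.5 expected; allow discretization noise
})
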