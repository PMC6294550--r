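test_that("TIFF round-trip preserves pixel data, channel order and size", {
  set.seed(1)
  img <- mc_image(list(giantin = matrix(runif(32 * 32) * 100, 32, 32),
                       marker = matrix(runif(32 * 32) * 10, 32, 32)),
                  pixel_size_nm = 47.5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- read_image(path)
  expect_identical(names(back$channels), c("giantin", "marker"))
  expect_equal(back$pixel_size_nm, 47.5)
  # float32 storage: relative error below 1e-6
  expect_equal(back$channels$giantin, img$channels$giantin,
               tolerance = 1e-6)
  expect_equal(back$channels$marker, img$channels$marker,
               tolerance = 1e-6)
  # single channel -> one-entry channel map
  one <- mc_image(list(only = matrix(1:100 / 7, 10, 10)), 50)
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_image(one, p2)
  expect_length(read_image(p2)$channels, 1)
  # channel_names override must match page count
  expect_error(read_image(p2, channel_names = c("a", "b")), "pages")
})

test_that("our TIFFs agree with an independent reader and vice versa", {
  # cross-validation against Python tifffile (pre-installed): our writer's
  # files parse identically there, and a tifffile-written multipage float32
  # file parses identically here
  img <- mc_image(list(a = matrix(seq(0, 1, length.out = 144), 12, 12),
                       b = matrix(rev(seq(0, 5, length.out = 144)), 12,
                                  12)),
                  pixel_size_nm = 50)
  ours <- withr::local_tempfile(fileext = ".tif")
  theirs <- withr::local_tempfile(fileext = ".tif")
  csv_out <- withr::local_tempfile(fileext = ".csv")
  write_image(img, ours)
  py <- sprintf("
import tifffile, numpy as np
a = tifffile.imread(%s)
np.savetxt(%s, a.reshape(a.shape[0]*a.shape[1], -1), delimiter=',')
tifffile.imwrite(%s, (np.arange(200, dtype=np.float32)
                      .reshape(2, 10, 10) / 7))
", deparse(ours), deparse(csv_out), deparse(theirs))
  status <- system2("python", c("-c", shQuote(py)))
  expect_identical(status, 0L)
  flat <- as.matrix(utils::read.csv(csv_out, header = FALSE))
  expect_equal(unname(flat[1:12, ]), img$channels$a, tolerance = 1e-6)
  expect_equal(unname(flat[13:24, ]), img$channels$b, tolerance = 1e-6)
  back <- read_image(theirs, pixel_size_nm = 50)
  expect_length(back$channels, 2)
  expect_equal(back$channels[[2]][1, 1], 100 / 7, tolerance = 1e-6)
  # a plain TIFF without embedded metadata needs an explicit pixel size
  expect_error(read_image(theirs), "pixel_size_nm")
})

test_that("max_intensity_projection takes the per-pixel maximum", {
  set.seed(2)
  mk <- function() mc_image(list(a = matrix(runif(64), 8, 8),
                                 b = matrix(runif(64), 8, 8)), 50)
  slices <- list(mk(), mk(), mk())
  mip <- max_intensity_projection(slices)
  # elementwise oracle
  for (ch in c("a", "b")) {
    arr <- simplify2array(lapply(slices, function(s) s$channels[[ch]]))
    expect_equal(mip$channels[[ch]], apply(arr, c(1, 2), max))
  }
  expect_equal(max_intensity_projection(slices[1])$channels,
               slices[[1]]$channels)
  zero <- mc_image(list(a = matrix(0, 8, 8), b = matrix(0, 8, 8)), 50)
  expect_equal(max_intensity_projection(list(slices[[1]], zero))$channels,
               slices[[1]]$channels)
  expect_error(max_intensity_projection(list()), "empty")
})

test_that("border-median background subtraction removes a pedestal", {
  flat <- mc_image(list(a = matrix(7, 20, 20)), 50)
  expect_true(all(subtract_background(flat)$channels$a == 0))
  # ring on a pedestal b: pedestal removed, ring reduced by exactly b
  sc <- ring_scene(radius_px = 5, center = c(16, 16), size = 33,
                   width_px = 2)
  ped <- 3
  img <- mc_image(list(giantin = sc$image$channels$giantin + ped), 50)
  out <- subtract_background(img)$channels$giantin
  expect_equal(out, sc$image$channels$giantin, tolerance = 1e-12)
  # already-zero background: unchanged
  out2 <- subtract_background(sc$image)$channels$giantin
  expect_equal(out2, sc$image$channels$giantin)
  expect_error(subtract_background(flat, "rolling_ball", radius_px = 0),
               "radius")
})

test_that("rolling-ball background flattens a gradient under a punctum", {
  base <- outer(seq(0, 4, length.out = 40), seq(0, 4, length.out = 40),
                `+`)
  m <- base
  m[20, 20] <- m[20, 20] + 50
  out <- subtract_background(mc_image(list(a = m), 50),
                             method = "rolling_ball",
                             radius_px = 6)$channels$a
  expect_gt(out[20, 20], 45)           # punctum survives
  expect_lt(max(out[-20, -20][5:30, 5:30]), 1.0)  # gradient removed
})

test_that("crop_square extracts and re-embeds faithfully", {
  set.seed(3)
  img <- mc_image(list(a = matrix(runif(40 * 40), 40, 40)), 50)
  cr <- crop_square(img, center = c(20, 15), side_px = 11)
  org <- attr(cr, "origin")
  expect_equal(cr$channels$a,
               img$channels$a[org["y"] + 1:11, org["x"] + 1:11])
  # full-size centered crop is the identity
  full <- crop_square(img, center = c(19.5, 19.5), side_px = 40)
  expect_equal(full$channels$a, img$channels$a)
  expect_error(crop_square(img, center = c(2, 2), side_px = 11), "bounds")
  expect_equal(dim(crop_square(img, c(2, 2), 11, pad = TRUE)), c(11, 11))
  # crop around a planted ring center keeps the centroid at the crop center
  sc <- ring_scene(radius_px = 10, center = c(70, 58), size = 128,
                   width_px = 2)
  cr2 <- crop_square(sc$image, center = c(70, 58), side_px = 41)
  expect_lt(max(abs(center_of_mass(cr2$channels$giantin) - c(20, 20))),
            0.5)
})

test_that("center_of_mass matches the definition and a brute-force oracle", {
  m <- matrix(0, 30, 30)
  m[21, 11] <- 5                      # x = 10, y = 20
  expect_equal(unname(center_of_mass(m)), c(10, 20))
  m2 <- matrix(0, 15, 15)
  m2[1, 1] <- 2; m2[1, 11] <- 2       # (0,0) and (10,0)
  expect_equal(unname(center_of_mass(m2)), c(5, 0))
  sc <- ring_scene(radius_px = 30, center = c(64, 64), width_px = 3)
  got <- center_of_mass(sc$image$channels$giantin)
  expect_equal(unname(got),
               brute_centroid(sc$image$channels$giantin),
               tolerance = 1e-9)
  expect_error(center_of_mass(matrix(0, 5, 5)), "not positive")
})

test_that("center_of_mass is translation-equivariant", {
  sc <- disk_scene(radius_px = 8, center = c(20, 22), size = 64)
  m <- sc$image$channels$marker
  c0 <- center_of_mass(m)
  for (sh in list(c(5, 0), c(0, 9), c(13, 17))) {
    m2 <- matrix(0, 64, 64)
    m2[(1 + sh[2]):64, (1 + sh[1]):64] <-
      m[1:(64 - sh[2]), 1:(64 - sh[1])]
    expect_equal(unname(center_of_mass(m2)), unname(c0 + sh),
                 tolerance = 1e-9)
  }
})

test_that("line_profile reproduces rows, finds puncta, and normalizes", {
  set.seed(4)
  img <- mc_image(list(a = matrix(runif(20 * 20), 20, 20)), 50)
  p <- line_profile(img, start = c(0, 7), end = c(19, 7), width_px = 1)
  expect_equal(p$a, img$channels$a[8, ])          # row y = 7
  expect_equal(p$position_nm, p$position_px * 50)
  # double punctum along its axis: maxima at the planted positions
  sc <- render_scene(scene_spec(
    96, 50, structure_spec("s", "double_punctum", c(48, 48), 1e4,
                           separation_px = 24),
    psf_sigma_nm = 100))
  pp <- line_profile(sc$image, c(20, 48), c(76, 48))
  ord <- order(pp$s, decreasing = TRUE)
  peaks <- sort(pp$position_px[ord[1:2]]) + 20    # back to x coords
  expect_lt(max(abs(peaks - c(36, 60))), 0.5)
  pn <- line_profile(sc$image, c(20, 48), c(76, 48), normalize = TRUE)
  expect_equal(max(pn$s), 1.0)
  expect_error(line_profile(img, c(5, 5), c(5, 5)), "differ")
  expect_error(line_profile(img, c(-50, -50), c(-40, -50)), "outside")
})

test_that("roi_total_intensity recovers totals and subtracts background", {
  flat <- matrix(4, 41, 41)
  expect_equal(roi_total_intensity(flat, c(20, 20), 6), 0)
  sc <- render_scene(scene_spec(
    64, 50, structure_spec("p", "punctum", c(31.5, 30.5), 8000),
    psf_sigma_nm = 70))
  got <- roi_total_intensity(sc$image$channels$p, c(31.5, 30.5), 8)
  expect_equal(got, 8000, tolerance = 0.01)
  # single-pixel ROI: that pixel minus local background
  m <- matrix(1, 21, 21); m[11, 11] <- 10
  expect_equal(roi_total_intensity(m, c(10, 10), 0, bg_annulus = c(2, 5)),
               9)
  # linearity in image intensity (zero background)
  expect_equal(roi_total_intensity(sc$image$channels$p * 3.5,
                                   c(31.5, 30.5), 8),
               3.5 * got, tolerance = 1e-9)
  expect_error(roi_total_intensity(m, c(10, 10), 2,
                                   bg_annulus = c(50, 60)),
               "annulus")
})
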