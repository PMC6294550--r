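test_that("gyradius matches analytic identities and a brute-force sum", {
  # thin circle: all mass at distance r -> gyradius = r
  sc <- ring_scene(radius_px = 50, width_px = 1)
  expect_lt(abs(gyradius(sc$image$channels$giantin) - 50), 0.2)
  # uniform disk radius R -> R/sqrt(2) in the continuum limit
  dk <- disk_scene(radius_px = 40)
  m <- dk$image$channels$marker
  expect_equal(gyradius(m), 40 / sqrt(2), tolerance = 0.005)
  # brute-force oracle: explicit double loop over pixels
  ctr <- unname(center_of_mass(m))
  acc <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      acc <- acc + m[i, j] * ((j - 1 - ctr[1])^2 + (i - 1 - ctr[2])^2)
  expect_equal(gyradius(m, ctr), sqrt(acc / sum(m)), tolerance = 1e-12)
  # all mass at the center -> 0
  one <- matrix(0, 11, 11); one[6, 6] <- 3
  expect_equal(gyradius(one, c(5, 5)), 0)
  expect_error(gyradius(matrix(0, 5, 5)), "not positive")
})

test_that("normalize_ministack rescales the reference gyradius to 100 px", {
  sc <- ring_scene(radius_px = 50, width_px = 2, size = 160,
                   center = c(80, 78))
  nms <- normalize_ministack(mini_stack(sc$image, "giantin"))
  expect_equal(dim(nms$image), c(701L, 701L))
  expect_lt(abs(nms$ref_gyradius - 100), 0.5)
  expect_equal(nms$scale_factor, 2, tolerance = 0.01)
  # per-channel intensity normalization: unit pixel sum
  expect_equal(sum(nms$image$channels$giantin), 1, tolerance = 1e-9)
  # input already at gyradius 100: scale factor 1, values preserved
  sc2 <- canvas_ring(radius_px = 100, width_px = 3)
  ms2 <- mini_stack(sc2$image, "giantin")
  n2 <- normalize_ministack(ms2, normalize_intensity = FALSE)
  expect_equal(n2$scale_factor, 1, tolerance = 0.002)
  expect_equal(n2$image$channels$giantin, sc2$image$channels$giantin,
               tolerance = 0.02)
})

test_that("align_ministack moves the reference centroid to (350, 350)", {
  off <- canvas_ring(radius_px = 80, center = c(340, 355))
  al <- align_ministack(off)
  got <- center_of_mass(al$image$channels$giantin)
  expect_lt(max(abs(got - c(350, 350))), 0.25)
  expect_equal(unname(al$shift), c(10, -5), tolerance = 0.05)
  # already centered: near-zero shift, image essentially unchanged
  ctr <- canvas_ring(radius_px = 80, center = c(350, 350))
  al2 <- align_ministack(ctr)
  expect_lt(max(abs(al2$shift)), 1e-6)
  expect_equal(al2$image$channels$giantin, ctr$image$channels$giantin,
               tolerance = 1e-9)
  # rigid common shift: a second channel's offset from the reference is
  # preserved through alignment
  two <- canvas_ring(radius_px = 80, center = c(340, 355),
                     extra_structures = list(
                       structure_spec("marker", "disk", c(360, 355), 1e4,
                                      radius_px = 30)))
  al3 <- align_ministack(two)
  d_ref <- center_of_mass(al3$image$channels$giantin)
  d_mk <- center_of_mass(al3$image$channels$marker)
  expect_equal(unname(d_mk - d_ref), c(20, 0), tolerance = 0.05)
})

test_that("average_ministacks is the per-pixel mean with n bookkeeping", {
  a <- align_ministack(canvas_ring(radius_px = 90, center = c(348, 352)))
  avg1 <- average_ministacks(list(a, a, a))
  expect_equal(avg1$image$channels$giantin, a$image$channels$giantin)
  expect_equal(avg1$n, 3)
  expect_length(avg1$stack_ids, 3)
  b <- canvas_ring(radius_px = 90, channel = "other")
  expect_error(average_ministacks(list(a, b)), "channel set")
})

test_that("averaging noisy planted rings recovers the radial peak", {
  set.seed(17)
  aligned <- lapply(1:30, function(i)
    align_ministack(canvas_ring(radius_px = 100, width_px = 3,
                                center = c(350, 350) +
                                  stats::runif(2, -3, 3),
                                total = 2e4, poisson = TRUE,
                                seed = 800L + i)))
  avg <- average_ministacks(aligned)
  pr <- radial_mean_profile(avg)
  expect_lt(abs(pr$radius_px[which.max(pr$giantin)] - 100), 1)
})

test_that("radial_mean_profile matches a brute-force annulus oracle", {
  sc <- disk_scene(radius_px = 30, center = c(64, 64), size = 128)
  img <- sc$image
  pr <- radial_mean_profile(img, center = c(64, 64), r_max = 60)
  oracle <- brute_annulus_means(img$channels$marker, c(64, 64), 60)
  expect_equal(pr$marker, oracle, tolerance = 1e-12)
  # uniform disk: flat well inside (to the renderer's ~1% radial ripple),
  # zero well outside
  expect_true(all(abs(pr$marker[1:25] / pr$marker[1] - 1) < 0.02))
  expect_true(all(pr$marker[35:60] == 0))
  # thin ring: profile max at the planted radius
  rg <- ring_scene(radius_px = 45, width_px = 1)
  prr <- radial_mean_profile(rg$image, center = c(64, 64), r_max = 60)
  expect_lt(abs(prr$radius_px[which.max(prr$giantin)] - 45), 1)
  prn <- radial_mean_profile(rg$image, center = c(64, 64), r_max = 60,
                             normalize = TRUE)
  expect_equal(max(prn$giantin), 1.0)
  # cumulative mode: running disk means; nonincreasing for a disk up to
  # the renderer's radial ripple, and far below the plateau at the edge
  prc <- radial_mean_profile(img, center = c(64, 64), r_max = 60,
                             cumulative = TRUE)
  expect_true(all(diff(prc$marker) < 0.02 * prc$marker[1]))
  expect_lt(prc$marker[60], 0.5 * prc$marker[1])
  expect_error(radial_mean_profile(img, center = c(500, 500)), "outside")
})

test_that("extract_marker_radius finds the outer half-max crossing", {
  mk_profile <- function(vals) {
    out <- data.frame(radius_px = seq_along(vals))
    out$ch <- vals
    class(out) <- c("radial_profile", "data.frame")
    out
  }
  # triangular profile peaked at 100: half-max 5 met exactly at r = 105
  tri <- mk_profile(pmax(0, 10 - abs(seq_len(200) - 100)))
  mr <- extract_marker_radius(tri, "ch")
  expect_equal(mr$radius_px, 105.0)
  expect_equal(mr$peak_radius_px, 100)
  # Gaussian profile: half-max at r0 + sigma * sqrt(2 log 2)
  r0 <- 80; sg <- 12
  gau <- mk_profile(exp(-(seq_len(200) - r0)^2 / (2 * sg^2)))
  expect_equal(extract_marker_radius(gau, "ch")$radius_px,
               r0 + sg * sqrt(2 * log(2)), tolerance = 0.05)
  # reference channel against itself -> normalized radius 1
  mr2 <- extract_marker_radius(tri, "ch", reference_radius_px = 105.0)
  expect_equal(mr2$radius_normalized, 1.0)
  # never falls below half-max -> error
  flat <- mk_profile(c(1, 2, rep(2, 50)))
  expect_error(extract_marker_radius(flat, "ch"), "outer slope")
})

test_that("ring diameter comes from outer half-max crossings", {
  # hand-computed oracle from the constructed profile:
  # peaks of 10 at positions 5 and 15, half-max 5 met at 4 and 16
  vals <- rep(0, 21)
  vals[5] <- 5; vals[6] <- 10; vals[7] <- 5
  vals[15] <- 5; vals[16] <- 10; vals[17] <- 5
  expect_equal(diameter_from_profile(0:20, vals, center_pos = 10), 12)
  # fewer than two flanking peaks -> NA
  expect_true(is.na(diameter_from_profile(0:20, c(rep(0, 10), 5,
                                                  rep(0, 10)), 10)))
  # noiseless annulus of planted diameter, psf 0: +/- 1 px at any angle
  sc <- ring_scene(radius_px = 40, width_px = 2, size = 128)
  for (ang in c(0, 30, 77, 90)) {
    dm <- measure_ring_diameter(sc$image, "giantin", center = c(64, 64),
                                angle_deg = ang)
    expect_lt(abs(dm$diameter_px - (2 * 40 + 2)), 1)
  }
  dm_all <- measure_ring_diameter(sc$image, "giantin", center = c(64, 64))
  expect_equal(dm_all$diameter_nm, dm_all$diameter_px * 50)
})

test_that("summarize_radii aggregates per channel and joins LQs", {
  mk <- function(ch, v) structure(list(channel = ch, radius_px = v * 100,
                                       radius_normalized = v,
                                       peak_radius_px = 90,
                                       peak_value = 1, half_max = 0.5),
                                  class = "marker_radius")
  single <- summarize_radii(list(mk("a", 0.7)))
  expect_equal(single$mean_radius_normalized, 0.7)
  expect_true(is.na(single$sem))
  two <- summarize_radii(list(mk("a", 0.4), mk("a", 0.6)),
                         lq_table = data.frame(channel = "a", lq = 0.53))
  expect_equal(two$mean_radius_normalized, 0.5)
  expect_equal(two$sem, 0.1, tolerance = 1e-9)
  expect_equal(two$n, 2)
  expect_equal(two$lq, 0.53)
  expect_warning(summarize_radii(list(mk("b", 0.5)),
                                 lq_table = data.frame(channel = "a",
                                                       lq = 0)),
                 "missing")
})
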