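# scene builders shared across the suite --------------------------------

# noiseless thin ring on a small canvas
ring_scene <- function(radius_px = 50, center = c(64, 64), size = 128,
                       width_px = 1, psf_sigma_nm = 0, total = 1e4,
                       channel = "giantin", pixel_size_nm = 50, ...) {
  render_scene(scene_spec(
    size, pixel_size_nm,
    structure_spec(channel, "ring", center, total, radius_px = radius_px,
                   ring_width_px = width_px),
    psf_sigma_nm = psf_sigma_nm, ...))
}

disk_scene <- function(radius_px = 40, center = c(64, 64), size = 128,
                       psf_sigma_nm = 0, total = 1e4, channel = "marker",
                       pixel_size_nm = 50, ...) {
  render_scene(scene_spec(
    size, pixel_size_nm,
    structure_spec(channel, "disk", center, total, radius_px = radius_px),
    psf_sigma_nm = psf_sigma_nm, ...))
}

# a ring already on the 701x701 normalized canvas, wrapped as norm_stack
canvas_ring <- function(radius_px = 100, center = c(350, 350),
                        width_px = 3, total = 1e4, seed = NULL,
                        poisson = FALSE, channel = "giantin",
                        extra_structures = list()) {
  sts <- c(list(structure_spec(channel, "ring", center, total,
                               radius_px = radius_px,
                               ring_width_px = width_px)),
           extra_structures)
  sc <- render_scene(scene_spec(701, 50, sts, psf_sigma_nm = 0,
                                poisson_noise = poisson, seed = seed))
  norm_stack(sc$image, channel)
}

# brute-force centroid oracle, independent of center_of_mass()
brute_centroid <- function(m) {
  s <- 0; sx <- 0; sy <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      s <- s + m[i, j]
      sx <- sx + m[i, j] * (j - 1)
      sy <- sy + m[i, j] * (i - 1)
    }
  c(sx / s, sy / s)
}

# brute-force annular mean oracle for radial profiles
brute_annulus_means <- function(m, center, r_max) {
  out <- numeric(r_max)
  cnt <- numeric(r_max)
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      d <- sqrt((j - 1 - center[1])^2 + (i - 1 - center[2])^2)
      r <- floor(d + 0.5)
      if (r >= 1 && r <= r_max) {
        out[r] <- out[r] + m[i, j]
        cnt[r] <- cnt[r] + 1
      }
    }
  ifelse(cnt > 0, out / cnt, NA_real_)
}
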