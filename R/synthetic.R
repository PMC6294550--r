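#' Structure specification for the synthetic scene generator
#'
#' Describes one fluorescent structure of a synthetic mini-stack. Supported
#' kinds mirror the appearances of Golgi markers in the two canonical
#' orientations: en face views of rim markers are `ring`s (and concentric
#' `inner_ring`s), interior markers are `disk`s; side views are
#' `double_punctum` (rim) and `bar` (interior); `punctum` models a
#' diffraction-limited spot such as a nuclear pore standard.
#'
#' @param channel_name channel the structure is rendered into.
#' @param kind one of `"ring"`, `"disk"`, `"inner_ring"`,
#'   `"double_punctum"`, `"bar"`, `"punctum"`.
#' @param center_px numeric `(x, y)` center, 0-based pixel coordinates.
#' @param total_intensity expected photon count summed over the structure
#'   (> 0).
#' @param radius_px radius in px (ring/disk/inner_ring).
#' @param ring_width_px radial width of the annulus top-hat (rings).
#' @param separation_px center-to-center separation (double_punctum).
#' @param length_px,width_px bar dimensions.
#' @param angle_deg orientation of double_punctum/bar axes, degrees.
#' @return a `structure_spec` list.
#' @export
structure_spec <- function(channel_name, kind, center_px, total_intensity,
                           radius_px = NULL, ring_width_px = NULL,
                           separation_px = NULL, length_px = NULL,
                           width_px = NULL, angle_deg = 0) {
  kinds <- c("ring", "disk", "inner_ring", "double_punctum", "bar",
             "punctum")
  if (!kind %in% kinds)
    stop("unknown structure kind '", kind, "'; must be one of: ",
         paste(kinds, collapse = ", "))
  if (!is.numeric(total_intensity) || total_intensity <= 0)
    stop("total_intensity must be > 0")
  if (kind %in% c("ring", "inner_ring")) {
    if (is.null(radius_px) || radius_px < 0) stop(kind, " needs radius_px >= 0")
    if (is.null(ring_width_px)) ring_width_px <- 1
    if (ring_width_px <= 0) stop("ring_width_px must be > 0")
  }
  if (kind == "disk" && (is.null(radius_px) || radius_px <= 0))
    stop("disk needs radius_px > 0")
  if (kind == "double_punctum" &&
      (is.null(separation_px) || separation_px <= 0))
    stop("double_punctum needs separation_px > 0")
  if (kind == "bar") {
    if (is.null(length_px) || length_px <= 0) stop("bar needs length_px > 0")
    if (is.null(width_px)) width_px <- 2
  }
  structure(list(channel_name = channel_name, kind = kind,
                 center_px = as.numeric(center_px),
                 total_intensity = as.numeric(total_intensity),
                 radius_px = radius_px, ring_width_px = ring_width_px,
                 separation_px = separation_px, length_px = length_px,
                 width_px = width_px, angle_deg = angle_deg),
            class = "structure_spec")
}

#' Scene specification for the synthetic generator
#'
#' @param image_size_px square canvas side, px (>= 32).
#' @param pixel_size_nm pixel size, nm.
#' @param structures list of [structure_spec] objects.
#' @param psf_sigma_nm standard deviation of the isotropic Gaussian PSF, nm
#'   (0 disables blurring). Default 70 nm, i.e. about 165 nm FWHM — the
#'   scale of a well-corrected Airyscan-class system.
#' @param poisson_noise apply Poisson shot noise to the expected counts?
#' @param read_noise_sd additive Gaussian read noise sd, counts.
#' @param background_level constant background, counts per pixel (added
#'   before shot noise).
#' @param seed integer RNG seed; required whenever any noise is enabled.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size_px, pixel_size_nm, structures,
                       psf_sigma_nm = 70, poisson_noise = FALSE,
                       read_noise_sd = 0, background_level = 0,
                       seed = NULL) {
  if (image_size_px < 32) stop("image_size_px must be >= 32")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (psf_sigma_nm < 0 || read_noise_sd < 0 || background_level < 0)
    stop("psf_sigma_nm, read_noise_sd and background_level must be >= 0")
  if (inherits(structures, "structure_spec")) structures <- list(structures)
  stopifnot(all(vapply(structures, inherits, logical(1), "structure_spec")))
  if ((poisson_noise || read_noise_sd > 0) && is.null(seed))
    stop("a seed is required when noise is enabled (reproducibility)")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_nm = pixel_size_nm, structures = structures,
                 psf_sigma_nm = psf_sigma_nm, poisson_noise = poisson_noise,
                 read_noise_sd = read_noise_sd,
                 background_level = background_level, seed = seed),
            class = "scene_spec")
}

# radial extent of a structure, used for the fits-on-canvas check
structure_extent <- function(st) {
  switch(st$kind,
         ring = , inner_ring = st$radius_px + st$ring_width_px / 2,
         disk = st$radius_px,
         double_punctum = st$separation_px / 2 + 1,
         bar = sqrt(st$length_px^2 + st$width_px^2) / 2 + 1,
         punctum = 1)
}

# Render the ideal (pre-PSF) image of one structure with unit total
# intensity. All structures are laid down as bilinearly splatted sample
# points: the bilinear splat preserves each sample's position exactly in
# the centroid sense, and area structures are sampled on grids that are
# exactly symmetric about the planted center (polar grids for rings and
# disks, a centered rectangular grid for bars), so symmetric structures
# keep sub-0.01 px centroids by construction.
render_ideal <- function(st, size) {
  cx <- st$center_px[1]; cy <- st$center_px[2]
  acc <- numeric(size * size)
  splat <- function(x, y, w) {
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    px <- c(x0, x0 + 1, x0, x0 + 1)
    py <- c(y0, y0, y0 + 1, y0 + 1)
    wt <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
            w * (1 - fx) * fy, w * fx * fy)
    ok <- px >= 0 & px <= size - 1 & py >= 0 & py <= size - 1
    idx <- px[ok] * size + py[ok] + 1          # column-major (row = y + 1)
    ag <- rowsum(wt[ok], idx)
    at <- as.integer(rownames(ag))
    acc[at] <<- acc[at] + ag[, 1]
  }
  polar_samples <- function(r_lo, r_hi) {
    n_r <- max(3L, ceiling(4 * (r_hi - r_lo)))
    dr <- (r_hi - r_lo) / n_r
    rs <- r_lo + (seq_len(n_r) - 0.5) * dr
    for (r in rs) {
      k <- max(16L, ceiling(6 * pi * r))
      th <- (seq_len(k) - 0.5) * 2 * pi / k
      splat(cx + r * cos(th), cy + r * sin(th), rep(r / k, k))
    }
  }
  switch(st$kind,
    punctum = splat(cx, cy, 1),
    double_punctum = {
      a <- st$angle_deg * pi / 180
      h <- st$separation_px / 2
      splat(cx + h * cos(a), cy + h * sin(a), 0.5)
      splat(cx - h * cos(a), cy - h * sin(a), 0.5)
    },
    ring = , inner_ring = polar_samples(
      max(0, st$radius_px - st$ring_width_px / 2),
      st$radius_px + st$ring_width_px / 2),
    disk = polar_samples(0, st$radius_px),
    bar = {
      a <- st$angle_deg * pi / 180
      n_u <- max(2L, ceiling(4 * st$length_px))
      n_v <- max(2L, ceiling(4 * st$width_px))
      us <- ((seq_len(n_u) - 0.5) / n_u - 0.5) * st$length_px
      vs <- ((seq_len(n_v) - 0.5) / n_v - 0.5) * st$width_px
      u <- rep(us, times = n_v); v <- rep(vs, each = n_u)
      splat(cx + u * cos(a) - v * sin(a), cy + u * sin(a) + v * cos(a),
            rep(1 / (n_u * n_v), n_u * n_v))
    })
  s <- sum(acc)
  if (s <= 0) stop("structure '", st$kind, "' rendered no coverage")
  matrix(acc / s, size, size)
}

# sum-preserving separable Gaussian blur (zero padding); kernel truncated at
# 4 sigma and normalized to sum 1
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  n <- nrow(m)
  stopifnot(ncol(m) == n)
  cm <- matrix(0, n, n)
  for (o in -r:r) {
    i <- max(1, 1 - o):min(n, n - o)
    cm[cbind(i, i + o)] <- k[o + r + 1]
  }
  cm %*% m %*% t(cm)
}

#' Render a synthetic multi-channel mini-stack scene
#'
#' Produces the noiseless expected image of every structure (ideal geometry
#' convolved with the Gaussian PSF, scaled to its `total_intensity`), sums
#' structures per channel, adds the constant background, then applies
#' Poisson shot noise and Gaussian read noise if enabled. Negative pixels
#' after read noise are clamped at zero.
#'
#' @param spec a [scene_spec].
#' @return list with `image` (an [mc_image]), `truth` (data.frame with one
#'   row per structure: channel, kind, true center, radius in px and nm,
#'   total intensity, seed) and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  size <- spec$image_size_px
  sigma_px <- spec$psf_sigma_nm / spec$pixel_size_nm
  for (st in spec$structures) {
    ext <- structure_extent(st) + 3 * sigma_px
    if (st$center_px[1] - ext < 0 || st$center_px[1] + ext > size - 1 ||
        st$center_px[2] - ext < 0 || st$center_px[2] + ext > size - 1)
      stop("structure '", st$kind, "' in channel '", st$channel_name,
           "' does not fit within the canvas")
  }
  ch_names <- unique(vapply(spec$structures, `[[`, character(1),
                            "channel_name"))
  channels <- stats::setNames(
    replicate(length(ch_names), matrix(0, size, size), simplify = FALSE),
    ch_names)
  for (st in spec$structures) {
    ideal <- render_ideal(st, size) * st$total_intensity
    channels[[st$channel_name]] <- channels[[st$channel_name]] + ideal
  }
  if (sigma_px > 0)
    channels <- lapply(channels, gaussian_blur, sigma_px = sigma_px)
  channels <- lapply(channels, function(m) m + spec$background_level)
  if (spec$poisson_noise || spec$read_noise_sd > 0) {
    set.seed(spec$seed)
    channels <- lapply(channels, function(m) {
      v <- as.vector(m)
      if (spec$poisson_noise) v <- stats::rpois(length(v), v)
      if (spec$read_noise_sd > 0)
        v <- v + stats::rnorm(length(v), 0, spec$read_noise_sd)
      matrix(pmax(v, 0), nrow(m), ncol(m))
    })
  }
  truth <- do.call(rbind, lapply(seq_along(spec$structures), function(i) {
    st <- spec$structures[[i]]
    r_px <- if (!is.null(st$radius_px)) st$radius_px else NA_real_
    data.frame(structure_id = i, channel = st$channel_name, kind = st$kind,
               center_x = st$center_px[1], center_y = st$center_px[2],
               radius_px = r_px, radius_nm = r_px * spec$pixel_size_nm,
               diameter_nm = 2 * r_px * spec$pixel_size_nm,
               total_intensity = st$total_intensity,
               seed = if (is.null(spec$seed)) NA_integer_ else spec$seed)
  }))
  img <- mc_image(channels, spec$pixel_size_nm,
                  provenance = sprintf("render_scene(size=%d, seed=%s)",
                                       size, spec$seed %||% "none"))
  list(image = img, truth = truth, spec = spec)
}

# deterministic per-image seed derived from a master seed (kept < 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

#' Default configuration for [make_dataset]
#'
#' The stated world the generator emulates: Airyscan-class imaging at
#' 50 nm/px with a 70 nm PSF sigma, a Giantin-like reference ring whose
#' radius is drawn Normal(475 nm, 50 nm) — i.e. ring diameters around the
#' 950 nm scale typical of the largest Golgi rim marker — plus one interior
#' marker channel, Poisson shot noise and a small read noise.
#'
#' @param view `"enface"` (rings/disks) or `"side"` (three puncta along a
#'   cis-to-trans axis, for LQ validation).
#' @return a named list of generator parameters; any element can be
#'   overridden by name in the `config` argument of [make_dataset].
#' @export
dataset_config <- function(view = c("enface", "side")) {
  view <- match.arg(view)
  list(
    view = view,
    image_size_px = 128L,
    pixel_size_nm = 50,
    psf_sigma_nm = 70,
    poisson_noise = TRUE,
    read_noise_sd = 2,
    background_level = 5,
    center_jitter_px = 4,
    reference = list(channel = "giantin", radius_mean_nm = 475,
                     radius_sd_nm = 50, ring_width_nm = 120,
                     total_intensity = 5e4),
    markers = list(list(channel = "marker", kind = "disk",
                        radius_ratio = 0.6, ring_width_nm = 120,
                        total_intensity = 3e4)),
    # side-view geometry: axis length and marker's fractional axial position
    side = list(axis_length_nm = 800, marker_fraction = 0.53,
                punctum_intensity = 2e4,
                channels = c(cis = "gm130", marker = "marker",
                             trans = "galt"))
  )
}

#' Generate a reproducible synthetic mini-stack dataset
#'
#' Draws `n_stacks` scenes with randomized centers and reference radii
#' (Normal in nm, truncated at 5 px equivalents), derives a per-image seed
#' deterministically from the master seed, and returns the rendered images
#' with a ground-truth manifest. With `dir` set, images are written as
#' multi-channel TIFFs and the manifest as `manifest.csv`.
#'
#' @param config list as produced by [dataset_config()]; partial lists are
#'   merged over the defaults.
#' @param n_stacks number of mini-stacks (>= 1).
#' @param seed master seed (required).
#' @param dir optional output directory for TIFFs + manifest.
#' @return list with `stacks` (list of [render_scene] results), `truth`
#'   (combined manifest data.frame) and `config`.
#' @export
make_dataset <- function(config = dataset_config(), n_stacks, seed,
                         dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("a master seed is required for a reproducible dataset")
  if (n_stacks < 1) stop("n_stacks must be >= 1")
  base <- dataset_config(view = config$view %||% "enface")
  user_has_markers <- "markers" %in% names(config)
  user_markers <- config$markers
  config <- utils::modifyList(base, config)
  # modifyList cannot merge the unnamed markers list; replace it wholesale
  # whenever the caller supplied one (including an empty list)
  if (user_has_markers) config$markers <- user_markers
  px <- config$pixel_size_nm
  set.seed(derive_seed(seed, 0L))
  cjit <- config$center_jitter_px
  c0 <- (config$image_size_px - 1) / 2
  centers <- cbind(stats::runif(n_stacks, c0 - cjit, c0 + cjit),
                   stats::runif(n_stacks, c0 - cjit, c0 + cjit))
  ref_radii_nm <- pmax(stats::rnorm(n_stacks, config$reference$radius_mean_nm,
                                    config$reference$radius_sd_nm), 5 * px)
  axis_angles <- stats::runif(n_stacks, 0, 2 * pi)
  stacks <- vector("list", n_stacks)
  for (i in seq_len(n_stacks)) {
    ctr <- centers[i, ]
    structures <- if (config$view == "enface") {
      ref <- config$reference
      r_ref <- ref_radii_nm[i] / px
      sts <- list(structure_spec(ref$channel, "ring", ctr,
                                 ref$total_intensity, radius_px = r_ref,
                                 ring_width_px = ref$ring_width_nm / px))
      for (mk in config$markers) {
        sts[[length(sts) + 1L]] <- switch(mk$kind,
          disk = structure_spec(mk$channel, "disk", ctr, mk$total_intensity,
                                radius_px = mk$radius_ratio * r_ref),
          ring = , inner_ring = structure_spec(
            mk$channel, mk$kind, ctr, mk$total_intensity,
            radius_px = mk$radius_ratio * r_ref,
            ring_width_px = mk$ring_width_nm / px),
          stop("unsupported en-face marker kind: ", mk$kind))
      }
      sts
    } else {
      sv <- config$side
      L <- sv$axis_length_nm / px
      a <- axis_angles[i]
      u <- c(cos(a), sin(a))
      p_cis <- ctr - u * L / 2
      list(structure_spec(sv$channels[["cis"]], "punctum", p_cis,
                          sv$punctum_intensity),
           structure_spec(sv$channels[["marker"]], "punctum",
                          p_cis + u * L * sv$marker_fraction,
                          sv$punctum_intensity),
           structure_spec(sv$channels[["trans"]], "punctum", p_cis + u * L,
                          sv$punctum_intensity))
    }
    sp <- scene_spec(config$image_size_px, px, structures,
                     psf_sigma_nm = config$psf_sigma_nm,
                     poisson_noise = config$poisson_noise,
                     read_noise_sd = config$read_noise_sd,
                     background_level = config$background_level,
                     seed = derive_seed(seed, i))
    stacks[[i]] <- render_scene(sp)
  }
  truth <- do.call(rbind, lapply(seq_len(n_stacks), function(i) {
    tr <- stacks[[i]]$truth
    tr$stack_id <- sprintf("stack%04d", i)
    tr
  }))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_stacks))
      write_image(stacks[[i]]$image,
                  file.path(dir, sprintf("stack%04d.tif", i)))
    utils::write.csv(truth, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(stacks = stacks, truth = truth, config = config,
       seed = seed)
}
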