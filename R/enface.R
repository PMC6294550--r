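#' Golgi mini-stack container
#'
#' A square, background-subtracted multi-channel crop of one Golgi
#' mini-stack with a designated reference (rim marker, Giantin-like)
#' channel.
#'
#' @param image an [mc_image]; must be square and the reference channel must
#'   carry signal.
#' @param reference_channel name of the rim-marker channel used for size
#'   normalization and alignment.
#' @param stack_id identifier string.
#' @return a `mini_stack` object.
#' @export
mini_stack <- function(image, reference_channel, stack_id = "stack") {
  stopifnot(is_mc_image(image))
  d <- dim(image)
  if (d[1] != d[2]) stop("mini-stack image must be square")
  if (!reference_channel %in% names(image$channels))
    stop("reference channel '", reference_channel, "' not present")
  if (sum(image$channels[[reference_channel]]) <= 0)
    stop("reference channel has zero total intensity")
  structure(list(image = image, reference_channel = reference_channel,
                 stack_id = stack_id),
            class = "mini_stack")
}

#' Construct a normalized mini-stack directly from a 701 x 701 image
#'
#' Mostly useful for testing the alignment step in isolation: wraps an
#' image that is already on the standard canvas (e.g. a synthetic ring
#' rendered at a known off-center position) as a `norm_stack` without
#' rescaling it.
#'
#' @param image a 701 x 701 [mc_image].
#' @param reference_channel reference channel name.
#' @param stack_id identifier.
#' @param scale_factor scale factor to record (default 1).
#' @return a `norm_stack`.
#' @export
norm_stack <- function(image, reference_channel, stack_id = "stack",
                       scale_factor = 1) {
  stopifnot(is_mc_image(image))
  if (!all(dim(image) == NORM_CANVAS))
    stop("normalized mini-stacks must be ", NORM_CANVAS, " x ",
         NORM_CANVAS, " px")
  if (!reference_channel %in% names(image$channels))
    stop("reference channel '", reference_channel, "' not present")
  structure(list(image = image, reference_channel = reference_channel,
                 stack_id = stack_id, scale_factor = scale_factor,
                 ref_gyradius = gyradius(get_channel(image,
                                                     reference_channel)),
                 shift = c(x = 0, y = 0)),
            class = "norm_stack")
}

# canvas constants of the size-normalized frame: reference gyradius is
# rescaled to 100 px and images live on a 701 x 701 canvas whose center,
# (350, 350), is the alignment target
NORM_GYRADIUS <- 100
NORM_CANVAS <- 701L
NORM_CENTER <- c(x = 350, y = 350)

#' Gyradius (radius of gyration) of a channel
#'
#' The intensity-weighted root-mean-square distance of all pixels from a
#' given center: `sqrt(sum(I_i * r_i^2) / sum(I_i))`, where `r_i` is the
#' Euclidean distance from pixel `i`'s center to `center`. For an ideal thin
#' ring this equals the ring radius, which is what makes it a robust size
#' measure for rim-marker rings; for a uniform disk of radius R it is
#' R/sqrt(2).
#'
#' @param channel numeric matrix, or an [mc_image] with `which` naming the
#'   channel.
#' @param center numeric `(x, y)`; defaults to the channel's own center of
#'   fluorescence mass.
#' @param which channel name when `channel` is an [mc_image].
#' @return gyradius in px (scalar).
#' @export
gyradius <- function(channel, center = NULL, which = NULL) {
  m <- if (is_mc_image(channel))
    get_channel(channel, which %||% names(channel$channels)[1])
  else channel
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0)
    stop("cannot compute gyradius: total intensity is not positive")
  if (is.null(center)) center <- center_of_mass(m)
  r2 <- (coord_x(m) - center[1])^2 + (coord_y(m) - center[2])^2
  sqrt(sum(m * r2) / tot)
}

#' Size-normalize a mini-stack to the standard frame
#'
#' Rescales all channels isotropically so the reference channel's gyradius
#' becomes 100 px, embeds the result in a 701 x 701 canvas, and normalizes
#' each channel's intensity to unit pixel sum so that subsequent averaging
#' weights every mini-stack equally. Scaling is performed about the
#' reference channel's center of fluorescence mass, which is mapped to the
#' canvas center plus its original offset from the image center (alignment
#' to (350, 350) is the separate [align_ministack] step).
#'
#' @param ms a [mini_stack].
#' @param normalize_intensity scale each channel to unit pixel sum
#'   (default `TRUE`).
#' @return a `norm_stack`: list with `image` (701 x 701 [mc_image]),
#'   `reference_channel`, `stack_id`, `scale_factor`, `ref_gyradius`
#'   (post-scaling) and `shift` (so far applied; zero here).
#' @export
normalize_ministack <- function(ms, normalize_intensity = TRUE) {
  stopifnot(inherits(ms, "mini_stack"))
  ref <- get_channel(ms$image, ms$reference_channel)
  ctr <- center_of_mass(ref)
  g <- gyradius(ref, ctr)
  if (g <= 0) stop("reference gyradius is zero")
  s <- NORM_GYRADIUS / g
  in_size <- nrow(ref)
  if (s * in_size > 4 * NORM_CANVAS)
    stop("structure would be scaled far beyond the 701 px canvas; ",
         "check the reference channel")
  # inverse map: output pixel (X, Y) samples the input at
  # ctr + (X - ctr') / s, where ctr' is the centroid's landing position --
  # the image center offset is preserved so alignment remains a distinct,
  # observable step
  ctr_out <- NORM_CENTER + (ctr - (in_size - 1) / 2)
  n <- NORM_CANVAS
  X <- matrix(rep(0:(n - 1), each = n), n, n)   # x = column index
  Y <- matrix(rep(0:(n - 1), times = n), n, n)  # y = row index
  map_x <- ctr[1] + (X - ctr_out[1]) / s
  map_y <- ctr[2] + (Y - ctr_out[2]) / s
  out <- lapply(ms$image$channels, function(m) {
    w <- warp_channel(m, n, n, map_x, map_y)
    if (normalize_intensity) {
      tot <- sum(w)
      if (tot > 0) w <- w / tot
    }
    w
  })
  img <- mc_image(out, ms$image$pixel_size_nm / s,
                  c(ms$image$provenance,
                    sprintf("normalize_ministack(scale=%.4f)", s)))
  out_g <- gyradius(get_channel(img, ms$reference_channel))
  structure(list(image = img, reference_channel = ms$reference_channel,
                 stack_id = ms$stack_id, scale_factor = s,
                 ref_gyradius = out_g, shift = c(x = 0, y = 0)),
            class = "norm_stack")
}

#' Align a normalized mini-stack to the canvas center
#'
#' Applies one rigid sub-pixel translation — computed from the reference
#' channel's center of fluorescence mass — identically to all channels, so
#' that the reference centroid lands on (350, 350). Inter-channel offsets
#' are preserved; aligning each channel to its own centroid would fabricate
#' concentricity and is deliberately not done.
#'
#' @param nms a `norm_stack` from [normalize_ministack()].
#' @return the aligned `norm_stack` with `shift` recording the translation.
#' @export
align_ministack <- function(nms) {
  stopifnot(inherits(nms, "norm_stack"))
  ref <- get_channel(nms$image, nms$reference_channel)
  ctr <- center_of_mass(ref)
  shift <- NORM_CENTER - ctr
  n <- nrow(ref)
  X <- matrix(rep(0:(n - 1), each = n), n, n)
  Y <- matrix(rep(0:(n - 1), times = n), n, n)
  map_x <- X - shift[1]
  map_y <- Y - shift[2]
  before <- vapply(nms$image$channels, sum, numeric(1))
  out <- lapply(nms$image$channels, warp_channel, out_nrow = n,
                out_ncol = n, map_x = map_x, map_y = map_y)
  after <- vapply(out, sum, numeric(1))
  lost <- before > 0 & after < 0.98 * before
  if (any(lost))
    stop("alignment shifted >2% of the signal off-canvas (channels: ",
         paste(names(out)[lost], collapse = ", "), ")")
  nms$image <- mc_image(out, nms$image$pixel_size_nm,
                        c(nms$image$provenance,
                          sprintf("align_ministack(shift=(%.2f,%.2f))",
                                  shift[1], shift[2])))
  nms$shift <- nms$shift + shift
  nms
}

#' Average aligned mini-stacks (en face averaging)
#'
#' The per-pixel, per-channel arithmetic mean across aligned mini-stacks —
#' the "z-projection" of the stack of aligned images that turns dozens of
#' noisy individual mini-stacks into one clean average whose radial
#' structure can be profiled.
#'
#' @param aligned list of aligned `norm_stack` objects with identical
#'   channel sets.
#' @return an `enface_average`: list with `image` (701 x 701 [mc_image]),
#'   `n`, `stack_ids` and `reference_channel`.
#' @export
average_ministacks <- function(aligned) {
  if (inherits(aligned, "norm_stack")) aligned <- list(aligned)
  if (length(aligned) == 0L) stop("need at least one aligned mini-stack")
  stopifnot(all(vapply(aligned, inherits, logical(1), "norm_stack")))
  ch <- names(aligned[[1]]$image$channels)
  for (a in aligned)
    if (!identical(names(a$image$channels), ch))
      stop("all mini-stacks must share the same channel set")
  acc <- lapply(aligned[[1]]$image$channels, function(m) m * 0)
  for (a in aligned)
    for (cn in ch)
      acc[[cn]] <- acc[[cn]] + a$image$channels[[cn]]
  n <- length(aligned)
  acc <- lapply(acc, `/`, n)
  img <- mc_image(acc, aligned[[1]]$image$pixel_size_nm,
                  sprintf("average_ministacks(n=%d)", n))
  structure(list(image = img, n = n,
                 stack_ids = vapply(aligned, `[[`, character(1),
                                    "stack_id"),
                 reference_channel = aligned[[1]]$reference_channel),
            class = "enface_average")
}

#' Radial mean intensity profile
#'
#' For each integer radius r = 1..r_max, the mean intensity of all pixels
#' whose distance to the center falls in the unit-width annulus
#' `[r - 0.5, r + 0.5)`. Computed per channel about one common center
#' (normally the reference channel's center of fluorescence mass of an
#' en-face average).
#'
#' @param image an [mc_image] or `enface_average`.
#' @param center numeric `(x, y)`; defaults to (350, 350) for a 701-px
#'   canvas, otherwise to the first channel's centroid.
#' @param r_max largest radius, px (default 350).
#' @param normalize scale each channel's profile to maximum 1?
#' @param cumulative if `TRUE`, report the mean over the full disk of
#'   radius r instead of the annulus at r (an alternative reading of
#'   "mean intensity within a circle"; the annular mode is primary because
#'   it produces the peaked rim profiles the method relies on).
#' @return a data.frame (class `radial_profile`) with `radius_px` and one
#'   column per channel; the center used is stored as attribute `"center"`.
#' @export
radial_mean_profile <- function(image, center = NULL, r_max = 350L,
                                normalize = FALSE, cumulative = FALSE) {
  img <- if (inherits(image, "enface_average")) image$image else image
  stopifnot(is_mc_image(img))
  d <- dim(img)
  if (is.null(center)) {
    center <- if (all(d == NORM_CANVAS)) NORM_CENTER
    else center_of_mass(img$channels[[1]])
  }
  if (center[1] < 0 || center[1] > d[2] - 1 ||
      center[2] < 0 || center[2] > d[1] - 1)
    stop("center lies outside the image")
  m1 <- img$channels[[1]]
  dist <- sqrt((coord_x(m1) - center[1])^2 + (coord_y(m1) - center[2])^2)
  bin <- as.integer(floor(dist + 0.5))          # annulus [r-0.5, r+0.5)
  keep <- bin >= 1L & bin <= r_max
  counts <- tabulate(bin[keep], nbins = r_max)
  out <- data.frame(radius_px = seq_len(r_max))
  for (ch in names(img$channels)) {
    sums <- rep(0, r_max)
    agg <- tapply(img$channels[[ch]][keep], bin[keep], sum)
    sums[as.integer(names(agg))] <- agg
    prof <- ifelse(counts > 0, sums / counts, NA_real_)
    if (cumulative) {
      csum <- cumsum(sums); ccnt <- cumsum(counts)
      prof <- ifelse(ccnt > 0, csum / ccnt, NA_real_)
    }
    if (normalize && max(prof, na.rm = TRUE) > 0)
      prof <- prof / max(prof, na.rm = TRUE)
    out[[ch]] <- prof
  }
  class(out) <- c("radial_profile", "data.frame")
  attr(out, "center") <- center
  attr(out, "normalized") <- normalize
  out
}

# first half-maximum crossing outward of the peak of a sampled profile;
# positions: sample positions, values: intensities. Linear interpolation
# between bracketing samples; an exact-half plateau resolves to its
# outermost sample. direction +1 scans right of the peak, -1 left.
half_max_outer <- function(positions, values, peak_idx, direction = 1L) {
  half <- values[peak_idx] / 2
  idx <- if (direction > 0) (peak_idx + 1L):length(values)
         else (peak_idx - 1L):1L
  if (peak_idx + direction < 1L || peak_idx + direction > length(values))
    return(NA_real_)
  prev <- peak_idx
  for (i in idx) {
    if (values[i] < half) {
      return(positions[prev] + (positions[i] - positions[prev]) *
               (values[prev] - half) / (values[prev] - values[i]))
    }
    if (values[i] == half) {
      j <- i
      while (j + direction >= 1L && j + direction <= length(values) &&
             values[j + direction] == half)
        j <- j + direction
      return(positions[j])
    }
    prev <- i
  }
  NA_real_
}

#' Extract a marker's radius from a radial profile
#'
#' The marker radius is the half-maximum position on the outer slope of the
#' radial mean intensity profile: the first radius beyond the profile's
#' global peak at which intensity crosses half the peak value, linearly
#' interpolated between the bracketing integer radii. The normalized radius
#' divides by the reference (Giantin) radius extracted from the same
#' averaged image set.
#'
#' @param profile a `radial_profile` from [radial_mean_profile()].
#' @param channel channel whose radius to extract.
#' @param reference_radius_px the reference channel's radius from the same
#'   profile (px), used for normalization; `NULL` skips normalization.
#' @return a `marker_radius` list: `channel`, `radius_px`,
#'   `radius_normalized`, `peak_radius_px`, `peak_value`, `half_max`.
#' @export
extract_marker_radius <- function(profile, channel,
                                  reference_radius_px = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!channel %in% names(profile)) stop("channel '", channel,
                                         "' not in profile")
  v <- profile[[channel]]
  r <- profile$radius_px
  ok <- !is.na(v)
  v <- v[ok]; r <- r[ok]
  peak <- which.max(v)
  if (peak == length(v))
    stop("profile peak lies at the outermost radius; outer slope not ",
         "resolved")
  radius <- half_max_outer(r, v, peak, +1L)
  if (is.na(radius))
    stop("outer slope not resolved: profile never falls below half-max")
  structure(list(channel = channel, radius_px = radius,
                 radius_normalized = if (!is.null(reference_radius_px))
                   radius / reference_radius_px else NA_real_,
                 peak_radius_px = r[peak], peak_value = v[peak],
                 half_max = v[peak] / 2),
            class = "marker_radius")
}

#' Ring diameter from a line profile across the center
#'
#' Draws a line through the ring center at a given angle, takes its
#' intensity profile, finds the two maxima flanking the center, and for
#' each locates the half-maximum crossing on its outer slope (the slope
#' facing away from the center), linearly interpolated. The diameter is the
#' distance between the two crossings. The multi-angle mode averages over a
#' set of evenly spaced angles, removing the operator dependence of a
#' hand-drawn line.
#'
#' @param image [mc_image] containing the ring.
#' @param channel channel to measure.
#' @param center numeric `(x, y)` ring center; defaults to the channel's
#'   center of fluorescence mass.
#' @param angle_deg single angle, or a vector of angles to average over;
#'   default 36 evenly spaced angles over 180 degrees.
#' @param width_px perpendicular averaging width of the line profile.
#' @return list with `diameter_px`, `diameter_nm`, `angles_deg` and the
#'   per-angle diameters `per_angle_px`.
#' @export
measure_ring_diameter <- function(image, channel = NULL, center = NULL,
                                  angle_deg = seq(0, 175, by = 5),
                                  width_px = 1) {
  stopifnot(is_mc_image(image))
  channel <- channel %||% names(image$channels)[1]
  m <- get_channel(image, channel)
  center <- center %||% center_of_mass(m)
  d <- dim(image)
  half_len <- min(center[1], d[2] - 1 - center[1],
                  center[2], d[1] - 1 - center[2])
  if (half_len < 2) stop("center too close to the border for a diameter")
  per_angle <- vapply(angle_deg, function(a) {
    th <- a * pi / 180
    u <- c(cos(th), sin(th))
    p <- line_profile(image, center - u * half_len, center + u * half_len,
                      width_px = width_px)
    diameter_from_profile(p$position_px, p[[channel]], center_pos = half_len)
  }, numeric(1))
  ok <- is.finite(per_angle)
  if (!any(ok)) stop("no angle yielded two resolvable flanking peaks")
  diameter_px <- mean(per_angle[ok])
  list(diameter_px = diameter_px,
       diameter_nm = diameter_px * image$pixel_size_nm,
       angles_deg = angle_deg, per_angle_px = per_angle)
}

#' Ring diameter from a sampled 1D profile
#'
#' Core of [measure_ring_diameter()], exposed for constructed profiles:
#' identifies the maxima on either side of `center_pos`, then for each peak
#' the half-maximum crossing on its outer slope, and returns the distance
#' between the crossings. Returns `NA` when fewer than two flanking peaks
#' exist or a half-max is never crossed outward.
#'
#' @param positions monotone sample positions.
#' @param values intensities at `positions`.
#' @param center_pos position of the ring center along the profile.
#' @return diameter in the units of `positions`, or `NA`.
#' @export
diameter_from_profile <- function(positions, values, center_pos) {
  n <- length(values)
  ci <- which.min(abs(positions - center_pos))
  left <- seq_len(ci - 1L)
  right <- if (ci < n) (ci + 1L):n else integer(0)
  if (length(left) < 2L || length(right) < 2L) return(NA_real_)
  lp <- left[which.max(values[left])]
  rp <- right[which.max(values[right])]
  if (values[lp] <= 0 || values[rp] <= 0) return(NA_real_)
  lx <- half_max_outer(positions, values, lp, -1L)   # away from center
  rx <- half_max_outer(positions, values, rp, +1L)
  if (is.na(lx) || is.na(rx)) return(NA_real_)
  rx - lx
}

#' Summarize normalized radii across mini-stack sets
#'
#' Aggregates `marker_radius` records per channel to mean, SEM and n, and
#' joins an LQ table when supplied — the plot-ready summary of normalized
#' radius versus axial position.
#'
#' @param records list of `marker_radius` objects (possibly from several
#'   averaged sets).
#' @param lq_table optional data.frame with columns `channel` and `lq`.
#' @return data.frame with `channel`, `mean_radius_normalized`, `sem`, `n`
#'   and, when joined, `lq`; channels missing from `lq_table` get `NA` and
#'   a warning, not an error.
#' @export
summarize_radii <- function(records, lq_table = NULL) {
  if (inherits(records, "marker_radius")) records <- list(records)
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, logical(1), "marker_radius")))
  df <- data.frame(
    channel = vapply(records, `[[`, character(1), "channel"),
    radius_normalized = vapply(records, `[[`, numeric(1),
                               "radius_normalized"))
  agg <- do.call(rbind, lapply(split(df, df$channel), function(g) {
    n <- nrow(g)
    data.frame(channel = g$channel[1],
               mean_radius_normalized = mean(g$radius_normalized),
               sem = if (n >= 2) stats::sd(g$radius_normalized) / sqrt(n)
                     else NA_real_,
               n = n)
  }))
  rownames(agg) <- NULL
  if (!is.null(lq_table)) {
    miss <- setdiff(agg$channel, lq_table$channel)
    if (length(miss))
      warning("channels missing from LQ table: ",
              paste(miss, collapse = ", "))
    agg$lq <- lq_table$lq[match(agg$channel, lq_table$channel)]
  }
  agg
}
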