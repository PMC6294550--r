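#' Maximal intensity projection of an image stack
#'
#' Collapses a list of congruent multi-channel slices into one image by
#' taking, per channel and per pixel, the maximum across slices — the MIP
#' preprocessing conventionally applied to confocal z-stacks before 2D
#' analysis.
#'
#' @param slices list of [mc_image] objects with identical channel sets,
#'   dimensions and pixel size.
#' @return an [mc_image].
#' @export
max_intensity_projection <- function(slices) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("empty stack: need at least one slice")
  if (is_mc_image(slices)) slices <- list(slices)
  stopifnot(all(vapply(slices, is_mc_image, logical(1))))
  ref <- slices[[1]]
  for (s in slices[-1]) {
    if (!identical(names(s$channels), names(ref$channels)) ||
        !identical(dim(s), dim(ref)))
      stop("slices must have congruent channels and dimensions")
  }
  out <- ref$channels
  for (s in slices[-1])
    for (ch in names(out))
      out[[ch]] <- pmax(out[[ch]], s$channels[[ch]])
  mc_image(out, ref$pixel_size_nm,
           c(ref$provenance, sprintf("max_intensity_projection(n=%d)",
                                     length(slices))))
}

#' Background subtraction
#'
#' Removes an additive background estimate from every channel, clamping
#' negative results at zero. `border_median` (the default) estimates a
#' constant background as the median of a border frame of the image;
#' `rolling_ball` estimates a smoothly varying background as a grey-scale
#' morphological opening with a disk structuring element (a flat-ball
#' approximation of the classical rolling-ball filter).
#'
#' @param img an [mc_image].
#' @param method `"border_median"` or `"rolling_ball"`.
#' @param border_px border frame width in px for `border_median`.
#' @param radius_px ball radius in px for `rolling_ball` (> 0).
#' @return background-subtracted [mc_image]; the method used is logged in
#'   `provenance`.
#' @export
subtract_background <- function(img, method = c("border_median",
                                                "rolling_ball"),
                                border_px = 3L, radius_px = 25) {
  stopifnot(is_mc_image(img))
  method <- match.arg(method)
  out <- img$channels
  for (ch in names(out)) {
    m <- out[[ch]]
    if (method == "border_median") {
      b <- min(border_px, floor(min(dim(m)) / 2))
      border <- c(m[seq_len(b), ], m[nrow(m) - seq_len(b) + 1, ],
                  m[, seq_len(b)], m[, ncol(m) - seq_len(b) + 1])
      bg <- stats::median(border)
    } else {
      if (radius_px <= 0) stop("rolling-ball radius must be > 0")
      bg <- rolling_ball_background(m, radius_px)
    }
    out[[ch]] <- pmax(m - bg, 0)
  }
  mc_image(out, img$pixel_size_nm,
           c(img$provenance,
             sprintf("subtract_background(method=%s, %s)", method,
                     if (method == "border_median")
                       sprintf("border_px=%d", as.integer(border_px))
                     else sprintf("radius_px=%g", radius_px))))
}

# grey-scale opening (erosion then dilation) with a disk of given radius;
# separable only for squares, so the disk is applied directly — adequate for
# the small crops this package handles.
rolling_ball_background <- function(m, radius_px) {
  r <- ceiling(radius_px)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius_px^2, ]
  nr <- nrow(m); nc <- ncol(m)
  shift_pad <- function(mm, dx, dy, pad) {
    out <- matrix(pad, nr, nc)
    src_r <- seq_len(nr) + dy; src_c <- seq_len(nc) + dx
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- mm[src_r[ok_r], src_c[ok_c]]
    out
  }
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off)))
    ero <- pmin(ero, shift_pad(m, off$dx[k], off$dy[k], Inf))
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off)))
    dil <- pmax(dil, shift_pad(ero, off$dx[k], off$dy[k], -Inf))
  dil
}

#' Square crop about a point
#'
#' @param img an [mc_image].
#' @param center numeric `(x, y)` in 0-based pixel coordinates; the crop is
#'   the `side_px` x `side_px` block of whole pixels whose center is nearest
#'   to `center`.
#' @param side_px side of the square crop, px.
#' @param pad if `TRUE`, out-of-bounds regions are zero-filled instead of
#'   raising an error.
#' @return cropped [mc_image]; the crop's `(x, y)` origin in the source image
#'   is recorded in `provenance` and returned as attribute `"origin"`.
#' @export
crop_square <- function(img, center, side_px, pad = FALSE) {
  stopifnot(is_mc_image(img), length(center) == 2, side_px >= 1)
  side_px <- as.integer(side_px)
  d <- dim(img)
  x0 <- as.integer(round(center[1])) - side_px %/% 2L
  y0 <- as.integer(round(center[2])) - side_px %/% 2L
  xs <- x0 + seq_len(side_px) - 1L
  ys <- y0 + seq_len(side_px) - 1L
  in_x <- xs >= 0 & xs <= d[2] - 1
  in_y <- ys >= 0 & ys <= d[1] - 1
  if (!pad && (!all(in_x) || !all(in_y)))
    stop("crop extends outside image bounds; use pad = TRUE to zero-fill")
  out <- lapply(img$channels, function(m) {
    cm <- matrix(0, side_px, side_px)
    cm[which(in_y), which(in_x)] <- m[ys[in_y] + 1, xs[in_x] + 1]
    cm
  })
  res <- mc_image(out, img$pixel_size_nm,
                  c(img$provenance,
                    sprintf("crop_square(origin=(%d,%d), side=%d)",
                            x0, y0, side_px)))
  attr(res, "origin") <- c(x = x0, y = y0)
  res
}

#' Center of fluorescence mass of a channel
#'
#' The intensity-weighted mean pixel position: `(sum(I*x)/sum(I),
#' sum(I*y)/sum(I))` with pixel centers at 0-based integer coordinates.
#'
#' @param channel numeric matrix or an [mc_image] (then `which` selects the
#'   channel).
#' @param which channel name when `channel` is an [mc_image].
#' @return numeric `(x, y)`.
#' @export
center_of_mass <- function(channel, which = NULL) {
  m <- if (is_mc_image(channel))
    get_channel(channel, which %||% names(channel$channels)[1])
  else channel
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0)
    stop("cannot compute center of mass: total intensity is not positive")
  cx <- sum(m * coord_x(m)) / tot
  cy <- sum(m * coord_y(m)) / tot
  c(x = cx, y = cy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thick-line intensity profile
#'
#' Samples the image along the segment `start -> end` at 1-px spacing; at
#' each sample position the intensity is averaged over `width_px` bilinearly
#' interpolated samples spread across the perpendicular extent — the "thick
#' line" profile used to read out side-view mini-stacks.
#'
#' @param img an [mc_image].
#' @param start,end numeric `(x, y)` endpoints, 0-based pixel coordinates.
#' @param width_px perpendicular averaging width in px (>= 1).
#' @param normalize if `TRUE`, each channel is scaled to maximum 1.
#' @return a data.frame with `position_px`, `position_nm` and one intensity
#'   column per channel; class `profile_series`.
#' @export
line_profile <- function(img, start, end, width_px = 1, normalize = FALSE) {
  stopifnot(is_mc_image(img), length(start) == 2, length(end) == 2,
            width_px >= 1)
  v <- c(end[1] - start[1], end[2] - start[2])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("start and end must differ")
  u <- v / len                       # along-track unit vector
  p <- c(-u[2], u[1])                # perpendicular unit vector
  t_pos <- seq(0, len, by = 1)
  # perpendicular sample offsets spanning width_px, centered on the line
  n_perp <- max(1L, as.integer(round(width_px)))
  w_off <- if (n_perp == 1L) 0 else seq(-(width_px - 1) / 2,
                                        (width_px - 1) / 2,
                                        length.out = n_perp)
  xs <- outer(start[1] + t_pos * u[1], w_off * p[1], `+`)
  ys <- outer(start[2] + t_pos * u[2], w_off * p[2], `+`)
  d <- dim(img)
  inside <- xs >= 0 & xs <= d[2] - 1 & ys >= 0 & ys <= d[1] - 1
  if (!any(inside)) stop("profile segment lies entirely outside the image")
  out <- data.frame(position_px = t_pos,
                    position_nm = t_pos * img$pixel_size_nm)
  for (ch in names(img$channels)) {
    vals <- matrix(sample_bilinear(img$channels[[ch]], as.vector(xs),
                                   as.vector(ys)),
                   nrow = length(t_pos))
    prof <- rowMeans(vals)
    if (normalize && max(prof) > 0) prof <- prof / max(prof)
    out[[ch]] <- prof
  }
  class(out) <- c("profile_series", "data.frame")
  attr(out, "width_px") <- width_px
  attr(out, "normalized") <- normalize
  out
}

#' Background-corrected total intensity of a circular ROI
#'
#' Sums pixel intensities inside a circular region of interest and subtracts
#' a local background estimated as the median per-pixel intensity of a
#' surrounding annulus times the ROI pixel area — the standard readout for
#' diffraction-limited puncta such as nuclear pores.
#'
#' @param channel numeric matrix (one channel).
#' @param roi_center numeric `(x, y)`, 0-based pixel coordinates.
#' @param roi_radius_px ROI radius, px; pixels whose centers fall within the
#'   radius are included (radius 0 selects the single nearest pixel).
#' @param bg_annulus numeric `(inner, outer)` radii of the background
#'   annulus, px; `NULL` disables background correction.
#' @param clamp if `TRUE` (default), negative corrected totals return 0.
#' @return background-corrected total intensity (scalar).
#' @export
roi_total_intensity <- function(channel, roi_center, roi_radius_px,
                                bg_annulus = roi_radius_px * c(1.5, 2.5),
                                clamp = TRUE) {
  m <- if (is_mc_image(channel)) channel$channels[[1]] else channel
  stopifnot(is.matrix(m), length(roi_center) == 2, roi_radius_px >= 0)
  d2 <- (coord_x(m) - roi_center[1])^2 + (coord_y(m) - roi_center[2])^2
  if (roi_radius_px == 0) {
    sel <- d2 == min(d2)
  } else {
    sel <- d2 <= roi_radius_px^2
  }
  if (!any(sel)) stop("ROI contains no pixels")
  total <- sum(m[sel])
  area <- sum(sel)
  if (!is.null(bg_annulus)) {
    ann <- d2 > bg_annulus[1]^2 & d2 <= bg_annulus[2]^2
    if (!any(ann)) stop("background annulus contains no pixels")
    total <- total - stats::median(m[ann]) * area
  }
  if (clamp) max(total, 0) else total
}
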