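#' Multi-channel 2D fluorescence image
#'
#' The basic container used throughout the package: an ordered, named list of
#' equally sized numeric matrices (one per channel) plus the physical pixel
#' size in nanometres and a processing log.
#'
#' Coordinate convention (used everywhere in this package): pixel indices are
#' 0-based with pixel centers at integer coordinates; `x` runs along matrix
#' columns and `y` along matrix rows, so the pixel stored at `m[i, j]` has
#' center `(x, y) = (j - 1, i - 1)`.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions. Intensities must be finite; negative values are rejected
#'   (background subtraction clamps at zero before images enter the
#'   pipeline).
#' @param pixel_size_nm physical size of one pixel edge, in nm (> 0).
#' @param provenance character vector of processing-log entries.
#' @return An object of class `mc_image`.
#' @examples
#' img <- mc_image(list(giantin = matrix(1, 8, 8)), pixel_size_nm = 50)
#' dim(img$channels$giantin)
#' @export
mc_image <- function(channels, pixel_size_nm, provenance = character()) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of matrices")
  if (is.null(names(channels)) || anyNA(names(channels)) ||
      any(names(channels) == ""))
    stop("every channel must be named")
  if (anyDuplicated(names(channels)))
    stop("channel names must be unique")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1))))
    stop("every channel must be a numeric matrix")
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channels must share identical dimensions")
  bad <- vapply(channels, function(m) any(!is.finite(m)) || any(m < 0),
                logical(1))
  if (any(bad))
    stop("channel intensities must be finite and >= 0 (channels: ",
         paste(names(channels)[bad], collapse = ", "), ")")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(
    list(channels = lapply(channels, unname),
         pixel_size_nm = as.numeric(pixel_size_nm),
         provenance = as.character(provenance)),
    class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %d x %d px, %.3g nm/px, %d channel(s): %s\n",
              d[1], d[2], x$pixel_size_nm,
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mc_image <- function(x) dim(x$channels[[1]])

channel_names <- function(img) names(img$channels)

get_channel <- function(img, channel) {
  if (!channel %in% names(img$channels))
    stop("channel '", channel, "' not present (have: ",
         paste(names(img$channels), collapse = ", "), ")")
  img$channels[[channel]]
}

log_step <- function(img, msg) {
  img$provenance <- c(img$provenance, msg)
  img
}

#' @rdname mc_image
#' @param x object to test.
#' @export
is_mc_image <- function(x) inherits(x, "mc_image")

# 0-based x (column) coordinates of every pixel of a matrix, as a matrix
coord_x <- function(m) {
  matrix(rep(seq_len(ncol(m)) - 1, each = nrow(m)), nrow(m), ncol(m))
}

# 0-based y (row) coordinates
coord_y <- function(m) {
  matrix(rep(seq_len(nrow(m)) - 1, times = ncol(m)), nrow(m), ncol(m))
}

# Bilinear sample of matrix `m` at 0-based coordinates (x, y); points outside
# the support evaluate to 0. Vectorized over x/y.
sample_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  val <- function(xi, yi) {
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    out <- numeric(length(xi))
    out[ok] <- m[cbind(yi[ok] + 1, xi[ok] + 1)]
    out
  }
  v <- val(x0, y0)     * (1 - fx) * (1 - fy) +
       val(x0 + 1, y0) * fx       * (1 - fy) +
       val(x0, y0 + 1) * (1 - fx) * fy +
       val(x0 + 1, y0 + 1) * fx  * fy
  v
}

# Apply an inverse coordinate map to every pixel of `m`: output pixel (x, y)
# takes the bilinearly interpolated value of `m` at (map_x, map_y).
warp_channel <- function(m, out_nrow, out_ncol, map_x, map_y) {
  matrix(sample_bilinear(m, map_x, map_y), out_nrow, out_ncol)
}
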