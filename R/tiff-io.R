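#' Multi-channel TIFF input and output
#'
#' `write_image()` stores an [mc_image] as an uncompressed, little-endian,
#' 32-bit floating point, multi-page baseline TIFF (one grayscale page per
#' channel, channel order preserved). Channel names and the pixel size are
#' embedded as a JSON `ImageDescription` tag so `read_image()` round-trips
#' the object losslessly (up to float32 precision of the pixel data).
#'
#' The reader also accepts uncompressed single- or multi-strip grayscale
#' TIFFs with 8/16-bit unsigned integer or 32/64-bit float samples, which
#' covers typical exports of raw microscopy crops. Compressed or tiled TIFFs
#' are rejected with an informative error.
#'
#' @param img an [mc_image].
#' @param path file path of the TIFF to write/read.
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   an [mc_image].
#' @export
write_image <- function(img, path) {
  stopifnot(is_mc_image(img))
  chans <- img$channels
  n_pages <- length(chans)
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])
  desc <- jsonlite::toJSON(
    list(channels = names(chans), pixel_size_nm = img$pixel_size_nm),
    auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  bytes_per_page <- 4L * h * w
  data_offsets <- 8L + bytes_per_page * (seq_len(n_pages) - 1L)
  desc_offset <- 8L + bytes_per_page * n_pages
  ifd_size <- function(n_tags) 2L + 12L * n_tags + 4L
  # page 1 carries the description tag (11 tags); later pages have 10
  n_tags <- c(11L, rep(10L, max(0L, n_pages - 1L)))
  ifd_offsets <- desc_offset + length(desc_raw) +
    cumsum(c(0L, utils::head(vapply(n_tags, ifd_size, integer(1)), -1L)))

  con <- file(path, "wb")
  on.exit(close(con))
  wr_short <- function(x) writeBin(as.integer(x), con, size = 2,
                                   endian = "little")
  wr_long <- function(x) writeBin(as.integer(x), con, size = 4,
                                  endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wr_short(42L)
  wr_long(ifd_offsets[1])
  # pixel data, row-major float32
  for (m in chans)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  tag <- function(id, type, count, value) {
    wr_short(id); wr_short(type); wr_long(count)
    if (type == 3L && count == 1L) { wr_short(value); wr_short(0L) }
    else wr_long(value)
  }
  for (p in seq_len(n_pages)) {
    wr_short(n_tags[p])
    tag(256L, 4L, 1L, w)                    # ImageWidth
    tag(257L, 4L, 1L, h)                    # ImageLength
    tag(258L, 3L, 1L, 32L)                  # BitsPerSample
    tag(259L, 3L, 1L, 1L)                   # Compression: none
    tag(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    if (p == 1L)
      tag(270L, 2L, length(desc_raw), desc_offset)  # ImageDescription
    tag(273L, 4L, 1L, data_offsets[p])      # StripOffsets
    tag(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    tag(278L, 4L, 1L, h)                    # RowsPerStrip
    tag(279L, 4L, 1L, bytes_per_page)       # StripByteCounts
    tag(339L, 3L, 1L, 3L)                   # SampleFormat: IEEE float
    wr_long(if (p < n_pages) ifd_offsets[p + 1] else 0L)
  }
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size_nm pixel size override/fallback in nm; required when the
#'   file carries no embedded pixel size.
#' @param channel_names optional character vector naming the pages, used when
#'   the file carries no embedded channel names.
#' @export
read_image <- function(path, pixel_size_nm = NULL, channel_names = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM")
    "big" else stop("not a TIFF file (bad byte-order mark): ", path)
  rd_int <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2)
  }
  if (rd_int(2, 2) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  desc <- NULL
  ifd_off <- rd_int(4, 4)
  while (ifd_off != 0) {
    n_tags <- rd_int(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      toff <- ifd_off + 2 + 12 * (i - 1)
      id <- rd_int(toff, 2); type <- rd_int(toff + 2, 2)
      count <- rd_int(toff + 4, 4)
      type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      inline <- count * type_size <= 4
      voff <- if (inline) toff + 8 else rd_int(toff + 8, 4)
      value <- if (type %in% c(3L, 4L)) {
        rd_int(voff, type_size, count)
      } else if (type == 2L) {
        rawToChar(raw[(voff + 1):(voff + count - 1)])
      } else NULL
      tags[[as.character(id)]] <- value
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- need(256); h <- need(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    if (need(259, 1L)[1] != 1L)
      stop("compressed TIFF not supported; re-save uncompressed: ", path)
    if (!is.null(tags[["322"]]))
      stop("tiled TIFF not supported: ", path)
    bits <- need(258, 1L)[1]
    fmt <- need(339, 1L)[1]
    spp <- need(277, 1L)[1]
    if (spp != 1L)
      stop("only one sample per pixel (grayscale pages) supported")
    offs <- need(273); counts <- need(279)
    if (is.null(offs) || is.null(counts)) stop("TIFF page missing strips")
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + counts[s])])
    px <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "double", n = w * h, size = 4, endian = endian)
    } else if (fmt == 3L && bits == 64L) {
      readBin(buf, "double", n = w * h, size = 8, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = w * h, size = 1,
                         signed = FALSE, endian = endian))
    } else if (bits == 16L) {
      as.numeric(readBin(buf, "integer", n = w * h, size = 2,
                         signed = FALSE, endian = endian))
    } else stop("unsupported sample format (bits=", bits, ", fmt=", fmt, ")")
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w,
                                          byrow = TRUE)
    if (is.null(desc) && !is.null(tags[["270"]])) desc <- tags[["270"]]
    ifd_off <- rd_int(ifd_off + 2 + 12 * n_tags, 4)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  if (length(unique(lapply(pages, dim))) != 1L)
    stop("TIFF pages have mismatched dimensions; channels must be congruent")

  meta <- if (!is.null(desc))
    tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  nms <- channel_names
  if (is.null(nms) && !is.null(meta$channels)) nms <- meta$channels
  if (is.null(nms)) nms <- paste0("ch", seq_along(pages))
  if (length(nms) != length(pages))
    stop("channel_names length (", length(nms), ") != number of pages (",
         length(pages), ")")
  psz <- pixel_size_nm
  if (is.null(psz) && !is.null(meta$pixel_size_nm)) psz <- meta$pixel_size_nm
  if (is.null(psz))
    stop("pixel size not found in TIFF metadata; pass pixel_size_nm= ",
         "explicitly (nm per pixel)")
  names(pages) <- nms
  mc_image(pages, pixel_size_nm = psz,
           provenance = paste0("read_image(", path, ")"))
}
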