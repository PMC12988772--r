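#' Pixel images with physical pixel size and lazy backends
#'
#' A `pixel_image` couples a 2-D (or 2-D + channels) pixel array with the
#' physical pixel size in micrometres. Pixels are stored row-major with the
#' origin at the top-left; the centre of pixel (r, c) sits at
#' ((c + 0.5) * s, (r + 0.5) * s) micrometres for pixel size s. Intensities
#' are kept on their native scale (0-255 for 8-bit data); TIFF readers and
#' writers rescale at the boundary.
#'
#' Images can be backed by an in-memory array or lazily by a reader
#' function: creating or loading a lazy image reads no pixel payload, the
#' array materializes (and is cached) on first access. A separate
#' region reader, when available, serves rectangular windows without
#' materializing the full array, which the tile-streamed quantifier relies
#' on.
#'
#' @param pixels numeric array, `h x w` or `h x w x channels`.
#' @param pixel_size micrometres per pixel, > 0.
#' @param channel_names optional character vector, one per channel.
#' @param name image name.
#' @param origin micrometre position of the image's top-left corner in the
#'   sample frame; (0, 0) for the primary image, non-zero after unshifted
#'   crops.
#' @return A `pixel_image` object.
#' @export
pixel_image <- function(pixels, pixel_size, channel_names = NULL,
                        name = "image", origin = c(0, 0)) {
  pixels <- img_canonical_array(pixels)
  new_pixel_image(
    shape = dim(pixels), pixel_size = pixel_size,
    channel_names = channel_names, name = name,
    reader = local({ px <- pixels; function() px }), origin = origin
  )
}

#' @rdname pixel_image
#' @param shape integer vector `c(h, w)` or `c(h, w, channels)`.
#' @param reader function() returning the full pixel array, or NULL if only
#'   region access is possible.
#' @param region_reader optional function(r0, c0, h, w) returning the window
#'   with top-left pixel (r0, c0) (1-based) — used for tile streaming.
#' @param checksum optional list(path=, sha256=) verified at first payload
#'   access.
#' @export
lazy_pixel_image <- function(shape, pixel_size, reader = NULL,
                             region_reader = NULL, channel_names = NULL,
                             name = "image", checksum = NULL,
                             origin = c(0, 0)) {
  new_pixel_image(shape = shape, pixel_size = pixel_size,
                  channel_names = channel_names, name = name,
                  reader = reader, region_reader = region_reader,
                  checksum = checksum, origin = origin)
}

new_pixel_image <- function(shape, pixel_size, channel_names, name,
                            reader = NULL, region_reader = NULL,
                            checksum = NULL, origin = c(0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 1L))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single value > 0", call. = FALSE)
  }
  n_ch <- if (length(shape) == 3L) shape[3L] else 1L
  if (is.null(channel_names)) {
    channel_names <- if (n_ch == 1L) "intensity" else paste0("ch", seq_len(n_ch))
  }
  if (length(channel_names) != n_ch) {
    stop("length(channel_names) must equal the channel count", call. = FALSE)
  }
  backend <- new.env(parent = emptyenv())
  backend$cache <- NULL
  backend$n_reads <- 0L
  backend$reader <- reader
  backend$region_reader <- region_reader
  backend$checksum <- checksum
  backend$verified <- is.null(checksum)
  structure(list(name = name, pixel_size = as.numeric(pixel_size),
                 shape = shape, channel_names = as.character(channel_names),
                 origin = as.numeric(origin), backend = backend),
            class = "pixel_image")
}

img_canonical_array <- function(pixels) {
  pixels <- if (is.matrix(pixels)) pixels else as.array(pixels)
  storage.mode(pixels) <- "double"
  stopifnot(length(dim(pixels)) %in% c(2L, 3L))
  pixels
}

#' @export
print.pixel_image <- function(x, ...) {
  st <- if (is.null(x$backend$cache)) "lazy" else "in memory"
  cat(sprintf("<pixel_image '%s' %s px, %.3g um/px, %d channel(s), %s>\n",
              x$name, paste(x$shape[1:2], collapse = "x"), x$pixel_size,
              img_n_channels(x), st))
  invisible(x)
}

#' @rdname pixel_image
#' @param x a `pixel_image`.
#' @export
img_shape <- function(x) x$shape

#' @rdname pixel_image
#' @export
img_n_channels <- function(x) if (length(x$shape) == 3L) x$shape[3L] else 1L

#' Number of payload reads performed on an image backend
#'
#' Counts full-array materializations and region reads; zero for a freshly
#' opened lazy image. Used to assert the laziness contract.
#' @param x a `pixel_image`.
#' @export
img_read_count <- function(x) x$backend$n_reads

img_verify_checksum <- function(x) {
  be <- x$backend
  if (be$verified) return(invisible(TRUE))
  got <- digest::digest(be$checksum$path, algo = "sha256", file = TRUE)
  if (!identical(got, be$checksum$sha256)) {
    stop(sprintf("corruption error: static file '%s' digest mismatch",
                 be$checksum$path), call. = FALSE)
  }
  be$verified <- TRUE
  invisible(TRUE)
}

#' Materialize the full pixel array of an image
#'
#' Triggers the payload read on a lazy image (verifying the recorded
#' checksum, if any) and caches the result.
#' @param x a `pixel_image`.
#' @return Numeric array `h x w` or `h x w x channels`.
#' @export
img_pixels <- function(x) {
  be <- x$backend
  if (!is.null(be$cache)) return(be$cache)
  img_verify_checksum(x)
  if (is.null(be$reader)) {
    stop("image backend does not support full materialization", call. = FALSE)
  }
  be$n_reads <- be$n_reads + 1L
  px <- img_canonical_array(be$reader())
  stopifnot(identical(dim(px)[1:2], x$shape[1:2]))
  be$cache <- px
  px
}

#' Read a rectangular pixel window from an image
#'
#' Serves the window from the region backend when one exists (reading only
#' the tiles that intersect it), otherwise from the materialized array.
#' @param x a `pixel_image`.
#' @param r0,c0 1-based top-left pixel of the window.
#' @param h,w window height and width in pixels.
#' @export
img_read_region <- function(x, r0, c0, h, w) {
  be <- x$backend
  stopifnot(r0 >= 1L, c0 >= 1L, r0 + h - 1L <= x$shape[1L],
            c0 + w - 1L <= x$shape[2L])
  if (!is.null(be$cache)) {
    return(index_region(be$cache, r0, c0, h, w))
  }
  if (!is.null(be$region_reader)) {
    img_verify_checksum(x)
    be$n_reads <- be$n_reads + 1L
    return(img_canonical_array(be$region_reader(r0, c0, h, w)))
  }
  index_region(img_pixels(x), r0, c0, h, w)
}

index_region <- function(px, r0, c0, h, w) {
  if (length(dim(px)) == 3L) {
    px[r0:(r0 + h - 1L), c0:(c0 + w - 1L), , drop = FALSE]
  } else {
    px[r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE]
  }
}

#' Extract one channel of an image as a matrix
#' @param x a `pixel_image`.
#' @param channel channel index or name.
#' @export
img_channel <- function(x, channel = 1L) {
  ch <- resolve_channel(x, channel)
  px <- img_pixels(x)
  if (length(dim(px)) == 3L) px[, , ch] else px
}

resolve_channel <- function(x, channel) {
  if (is.character(channel)) {
    ch <- match(channel, x$channel_names)
    if (is.na(ch)) stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
    ch
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > img_n_channels(x)) {
      stop(sprintf("unknown channel %d", ch), call. = FALSE)
    }
    ch
  }
}

# Extent of the image in the sample's micrometre frame.
img_extent <- function(x) {
  o <- x$origin %||% c(0, 0)
  c(xmin = o[1L], ymin = o[2L],
    xmax = o[1L] + x$shape[2L] * x$pixel_size,
    ymax = o[2L] + x$shape[1L] * x$pixel_size)
}

# Crop an image to pixel rows r0..r1, cols c0..c1 (1-based, clamped by
# caller); the cropped image's origin records its position in the frame.
img_crop_pixels <- function(x, r0, r1, c0, c1) {
  px <- index_region(img_pixels(x), r0, c0, r1 - r0 + 1L, c1 - c0 + 1L)
  o <- x$origin %||% c(0, 0)
  pixel_image(px, x$pixel_size, channel_names = x$channel_names,
              name = x$name,
              origin = c(o[1L] + (c0 - 1L) * x$pixel_size,
                         o[2L] + (r0 - 1L) * x$pixel_size))
}
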