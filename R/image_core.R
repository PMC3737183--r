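#' Construct a micrograph object
#'
#' A micrograph is a 2D grid of 8-bit intensities (integers in 0..255)
#' stored as an integer matrix (rows = image rows, top row first), plus
#' free-text provenance.
#'
#' @param pixels numeric or integer matrix; values must lie in 0..255.
#' @param source free-text provenance (file path or `"synthetic"`).
#' @param scale_note optional free text, e.g. magnification (`"200x"`).
#' @return An object of class `micrograph` with fields `pixels`, `source`,
#'   `scale_note`.
#' @export
micrograph <- function(pixels, source = "in-memory", scale_note = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("zero-sized image")
  px <- pixels
  if (!is.integer(px)) {
    storage.mode(px) <- "double"
    px <- round(px)
    storage.mode(px) <- "integer"
  }
  if (anyNA(px)) stop("pixel values must not be NA")
  if (min(px) < 0L || max(px) > 255L)
    stop("pixel values must lie in [0, 255]")
  structure(
    list(pixels = px, source = source, scale_note = scale_note),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph> %d x %d px (height x width), range [%d, %d], source: %s\n",
    nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels), x$source))
  if (!is.null(x$scale_note)) cat("  scale:", x$scale_note, "\n")
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

img_height <- function(img) nrow(img$pixels)
img_width <- function(img) ncol(img$pixels)

as_micrograph <- function(x) {
  if (inherits(x, "micrograph")) return(x)
  if (is.matrix(x)) return(micrograph(x))
  stop("cannot interpret object as a micrograph")
}

# Convert an [0,1]-scaled array as returned by png/jpeg/tiff readers into an
# 8-bit grayscale integer matrix. 3rd-dimension channels are collapsed by
# ITU-R 601 luminance; an alpha channel, if present, is ignored.
array_to_gray8 <- function(a) {
  if (length(dim(a)) == 2L) {
    g <- a
  } else {
    nch <- dim(a)[3]
    if (nch >= 3L) {
      g <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      g <- a[, , 1]
    }
  }
  m <- round(g * 255)
  m[m < 0] <- 0
  m[m > 255] <- 255
  storage.mode(m) <- "integer"
  m
}

#' Load a micrograph from a raster file
#'
#' Reads TIFF, PNG or JPEG. RGB input is converted to grayscale with the
#' ITU-R 601 luminance formula `0.299 R + 0.587 G + 0.114 B` (rounded to the
#' nearest integer); 16-bit input is rescaled linearly (per-image min-max)
#' to the 8-bit range.
#'
#' @param path path to a TIFF/PNG/JPEG file.
#' @param scale_note optional free-text magnification note.
#' @return A [micrograph].
#' @export
load_micrograph <- function(path, scale_note = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop("unreadable image: ", path))
    # as.is=TRUE returns integer sample values at native bit depth
    if (length(dim(raw)) == 3L) {
      mx <- max(raw)
      a <- raw / max(mx, 1)
      if (mx > 255) {          # 16-bit channels: min-max rescale first
        rng <- range(raw)
        a <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
             else raw * 0
      }
      m <- array_to_gray8(a)
    } else {
      if (max(raw) > 255) {
        rng <- range(raw)
        sc <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
              else raw * 0
        m <- round(sc * 255)
      } else {
        m <- raw
      }
      storage.mode(m) <- "integer"
    }
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable image: ", path))
    m <- array_to_gray8(raw)
  } else if (ext %in% c("jpg", "jpeg")) {
    raw <- tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop("unreadable image: ", path))
    m <- array_to_gray8(raw)
  } else {
    stop("unsupported image format: ", path)
  }
  if (is.null(dim(m)) || nrow(m) < 1L || ncol(m) < 1L)
    stop("zero-sized image: ", path)
  micrograph(m, source = path, scale_note = scale_note)
}

#' Save a micrograph to a raster file
#'
#' Writes 8-bit grayscale TIFF or PNG (chosen by file extension). The
#' write/read round trip on these lossless formats is bit-identical.
#'
#' @param img a [micrograph].
#' @param path output path ending in .tif/.tiff or .png.
#' @return `path`, invisibly.
#' @export
save_micrograph <- function(img, path) {
  img <- as_micrograph(img)
  a <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(a, path)
  } else {
    stop("unsupported output format: ", path)
  }
  invisible(path)
}

#' Invert image intensities
#'
#' Replaces every pixel value v by 255 - v. Trichome bases are the darkest
#' structures in a transmitted-light wing micrograph, so detection by maxima
#' finding always runs on the inverted image.
#'
#' @param img a [micrograph].
#' @return The inverted [micrograph].
#' @export
invert <- function(img) {
  img <- as_micrograph(img)
  out <- img
  out$pixels <- 255L - img$pixels
  out
}

#' Resize a micrograph by bilinear interpolation
#'
#' Aspect ratio is not preserved automatically: the caller passes the exact
#' target, matching the fixed 512 x 380 working resolution used by the
#' segmentation pipeline. Output values are rounded and clamped to 0..255.
#'
#' @param img a [micrograph].
#' @param out_width,out_height target size in pixels (both >= 1).
#' @return The resized [micrograph].
#' @export
resize <- function(img, out_width, out_height) {
  img <- as_micrograph(img)
  if (out_width < 1 || out_height < 1)
    stop("target dimensions must be positive")
  src <- img$pixels
  nr <- nrow(src); nc <- ncol(src)
  out_height <- as.integer(out_height); out_width <- as.integer(out_width)
  # sample positions at output pixel centers mapped into source coordinates
  ry <- (seq_len(out_height) - 0.5) * (nr / out_height) - 0.5
  cx <- (seq_len(out_width) - 0.5) * (nc / out_width) - 0.5
  ry <- pmin(pmax(ry, 0), nr - 1)
  cx <- pmin(pmax(cx, 0), nc - 1)
  r0 <- floor(ry); c0 <- floor(cx)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- ry - r0; fc <- cx - c0
  # gather the four corners via outer indexing (1-based)
  i00 <- src[cbind(rep(r0 + 1, out_width), rep(c0 + 1, each = out_height))]
  i10 <- src[cbind(rep(r1 + 1, out_width), rep(c0 + 1, each = out_height))]
  i01 <- src[cbind(rep(r0 + 1, out_width), rep(c1 + 1, each = out_height))]
  i11 <- src[cbind(rep(r1 + 1, out_width), rep(c1 + 1, each = out_height))]
  wfr <- rep(fr, out_width); wfc <- rep(fc, each = out_height)
  vals <- (1 - wfr) * (1 - wfc) * i00 + wfr * (1 - wfc) * i10 +
    (1 - wfr) * wfc * i01 + wfr * wfc * i11
  m <- matrix(vals, nrow = out_height, ncol = out_width)
  m <- round(m)
  m[m < 0] <- 0; m[m > 255] <- 255
  storage.mode(m) <- "integer"
  out <- img
  out$pixels <- m
  out
}

# Nearest-neighbour upscaling of a working-resolution mask or label map to
# source resolution, using the same center-aligned mapping as resize().
upscale_nn <- function(m, out_height, out_width) {
  nr <- nrow(m); nc <- ncol(m)
  ry <- (seq_len(out_height) - 0.5) * (nr / out_height) - 0.5
  cx <- (seq_len(out_width) - 0.5) * (nc / out_width) - 0.5
  ri <- pmin(pmax(round(ry), 0), nr - 1) + 1
  ci <- pmin(pmax(round(cx), 0), nc - 1) + 1
  m[ri, ci, drop = FALSE]
}
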