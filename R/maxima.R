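#' Find intensity maxima with noise tolerance
#'
#' The core trichome detector. A candidate is a plateau: a maximal
#' 8-connected set of equal-valued pixels none of which has an 8-neighbour
#' of strictly greater value. A candidate of value v is accepted iff every
#' 8-connected path from it to any strictly higher pixel descends to
#' `v - noise_tolerance` or below somewhere along the way (the prominence
#' criterion). Each accepted plateau emits one point: its pixel centroid
#' rounded to the nearest pixel (exact ties toward the smaller row, then the
#' smaller column). Among equal-valued candidates mutually reachable above
#' the tolerance floor only the one with the smallest centroid is kept. A
#' plateau that touches the image border and has no strictly higher pixel
#' anywhere in the image (e.g. a constant image) is suppressed: a flat field
#' contains no identifiable spot.
#'
#' Trichome bases are dark, so trichome detection runs with
#' `invert_first = TRUE` (the default).
#'
#' @param img a [micrograph].
#' @param noise_tolerance prominence threshold on the 8-bit scale (>= 0);
#'   the empirical operating point for wing trichomes is 10.
#' @param invert_first detect dark spots (invert before finding maxima)?
#' @return An object of class `trichome_points`: a list with `points` (a
#'   data.frame of 0-based `row`, `col`, sorted by row then col),
#'   `noise_tolerance`, and `source_dims` `(height, width)`.
#' @export
find_maxima <- function(img, noise_tolerance = 10, invert_first = TRUE) {
  img <- as_micrograph(img)
  if (noise_tolerance < 0) stop("noise_tolerance must be >= 0")
  w <- if (invert_first) 255L - img$pixels else img$pixels
  pts <- cpp_find_maxima(w, as.numeric(noise_tolerance))
  structure(
    list(
      points = data.frame(row = pts[, 1], col = pts[, 2]),
      noise_tolerance = noise_tolerance,
      source_dims = c(height = nrow(w), width = ncol(w))
    ),
    class = "trichome_points"
  )
}

#' @export
print.trichome_points <- function(x, ...) {
  cat(sprintf("<trichome_points> %d points, noise tolerance %g, image %d x %d\n",
              nrow(x$points), x$noise_tolerance,
              x$source_dims[1], x$source_dims[2]))
  invisible(x)
}

#' Count detected trichomes inside a region of interest
#'
#' Detection always runs on the full image (inverted), then points are
#' filtered by the ROI; cropping before detection would change tolerance
#' comparisons near the crop border.
#'
#' @param img a [micrograph].
#' @param roi a [square_roi()] or [polygon_roi()].
#' @param noise_tolerance prominence threshold (default 10).
#' @return Integer count of detected points inside the ROI (polygon
#'   boundaries count as inside).
#' @export
count_maxima <- function(img, roi, noise_tolerance = 10) {
  img <- as_micrograph(img)
  check_roi_in_image(roi, dim(img$pixels))
  tp <- find_maxima(img, noise_tolerance, invert_first = TRUE)
  sum(points_in_roi(tp$points, roi))
}

#' Partition the image into per-trichome spacing cells
#'
#' Runs the detector, then floods a seeded watershed on the inverted image:
#' each accepted maximum seeds one basin; basins grow in order of decreasing
#' inverted intensity, advancing by synchronous waves within an intensity
#' level; pixels reached simultaneously by two basins become boundary
#' (label 0). Cell area is inversely related to local trichome density,
#' which is what the spacing heat map visualizes.
#'
#' @param img a [micrograph].
#' @param noise_tolerance prominence threshold (default 10).
#' @return An object of class `spacing_cells`: `label_map` (integer matrix,
#'   0 = boundary), `cell_areas` (named integer vector, px^2 per label),
#'   `seeds` (the detected points), `noise_tolerance`.
#' @export
trichome_spacing_cells <- function(img, noise_tolerance = 10) {
  img <- as_micrograph(img)
  tp <- find_maxima(img, noise_tolerance, invert_first = TRUE)
  if (nrow(tp$points) == 0L)
    stop("no trichomes detected; try lowering noise_tolerance")
  w <- 255L - img$pixels
  seeds <- as.matrix(tp$points)
  storage.mode(seeds) <- "integer"
  lab <- cpp_watershed(w, seeds)
  areas <- tabulate(lab[lab > 0L], nbins = nrow(seeds))
  names(areas) <- as.character(seq_len(nrow(seeds)))
  structure(
    list(label_map = lab, cell_areas = areas, seeds = tp,
         noise_tolerance = noise_tolerance),
    class = "spacing_cells"
  )
}

#' @export
print.spacing_cells <- function(x, ...) {
  cat(sprintf("<spacing_cells> %d cells, median area %.0f px^2, %d boundary px\n",
              length(x$cell_areas), stats::median(x$cell_areas),
              sum(x$label_map == 0L)))
  invisible(x)
}

#' Write detected points to CSV
#'
#' Header `row,col`; coordinates 0-based.
#' @param tp a `trichome_points` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(tp, path) {
  utils::write.csv(tp$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detected points from CSV written by [write_points_csv()]
#' @param path CSV path with columns `row,col`.
#' @param noise_tolerance tolerance recorded in the returned object.
#' @param source_dims optional `(height, width)`.
#' @return A `trichome_points` object.
#' @export
read_points_csv <- function(path, noise_tolerance = NA_real_,
                            source_dims = c(NA_integer_, NA_integer_)) {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "col") %in% names(df)))
  structure(
    list(points = df[, c("row", "col")], noise_tolerance = noise_tolerance,
         source_dims = source_dims),
    class = "trichome_points"
  )
}

#' Write or read detected points as JSON
#'
#' JSON object with fields `points` (array of `[row, col]` pairs),
#' `noise_tolerance`, and `source_dims`.
#'
#' @param tp a `trichome_points` object.
#' @param path JSON file path.
#' @return `path` (write) or a `trichome_points` object (read).
#' @export
write_points_json <- function(tp, path) {
  jsonlite::write_json(
    list(points = unname(as.matrix(tp$points)),
         noise_tolerance = tp$noise_tolerance,
         source_dims = unname(tp$source_dims)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points_json
#' @export
read_points_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- matrix(x$points, ncol = 2)
  structure(
    list(points = data.frame(row = pts[, 1], col = pts[, 2]),
         noise_tolerance = x$noise_tolerance,
         source_dims = c(height = x$source_dims[1], width = x$source_dims[2])),
    class = "trichome_points"
  )
}

#' Write a spacing-cell label map as a 16-bit TIFF
#' @param cells a `spacing_cells` object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(cells, path) {
  tiff::writeTIFF(cells$label_map / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
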