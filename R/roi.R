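#' Square region of interest centered on a click point
#'
#' The square is centered on the given pixel: for odd sides the square is
#' symmetric; for even sides it extends one extra pixel down and right.
#' Presets of side 75 and 150 px mirror the two standard density buttons.
#'
#' @param center 0-based `(row, col)` of the click point (length-2 vector).
#' @param side side length in px (>= 1).
#' @param img_dims `(height, width)` of the image the ROI indexes.
#' @return An object of class `c("square_roi", "roi")` with `center`,
#'   `side`, `row_range`, `col_range` (0-based inclusive), `area_px2`.
#' @export
square_roi <- function(center, side, img_dims) {
  if (side < 1) stop("side must be >= 1")
  side <- as.integer(side)
  center <- as.integer(round(center))
  off <- (side - 1L) %/% 2L
  r0 <- center[1] - off; c0 <- center[2] - off
  r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
  if (r0 < 0L || c0 < 0L || r1 > img_dims[1] - 1L || c1 > img_dims[2] - 1L) {
    sug_r <- min(max(center[1], off), img_dims[1] - 1L - (side - 1L - off))
    sug_c <- min(max(center[2], off), img_dims[2] - 1L - (side - 1L - off))
    stop(sprintf(
      "square exits image bounds; nearest valid center is (%d, %d)",
      sug_r, sug_c))
  }
  structure(
    list(kind = "square", center = center, side = side,
         row_range = c(r0, r1), col_range = c(c0, c1),
         area_px2 = as.numeric(side)^2),
    class = c("square_roi", "roi")
  )
}

#' Polygon region of interest
#'
#' Vertices are continuous `(col, row)` points at pixel centers. The polygon
#' must be simple (non-self-intersecting); its area is the shoelace area.
#'
#' @param vertices n x 2 matrix or data.frame of `(col, row)` vertices,
#'   n >= 3.
#' @return An object of class `c("polygon_roi", "roi")` with `vertices`
#'   (matrix, columns `col`, `row`) and `area_px2`.
#' @export
polygon_roi <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  colnames(v) <- c("col", "row")
  if (is_self_intersecting(v)) stop("polygon is self-intersecting")
  a <- shoelace_area(v)
  if (a <= 0) stop("polygon has zero area")
  structure(
    list(kind = "polygon", vertices = v, area_px2 = a),
    class = c("polygon_roi", "roi")
  )
}

#' @export
print.roi <- function(x, ...) {
  if (x$kind == "square") {
    cat(sprintf("<square roi> side %d px at center (%d, %d), area %g px^2\n",
                x$side, x$center[1], x$center[2], x$area_px2))
  } else {
    cat(sprintf("<polygon roi> %d vertices, area %g px^2\n",
                nrow(x$vertices), x$area_px2))
  }
  invisible(x)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of a simple polygon (shoelace formula)
#'
#' Orientation-independent; vertices are continuous `(col, row)` points.
#'
#' @param vertices n x 2 matrix of `(col, row)` vertices, n >= 3.
#' @return Area in px^2.
#' @export
polygon_area <- function(vertices) {
  polygon_roi(vertices)$area_px2
}

# proper or improper intersection of non-adjacent edges => self-intersecting
is_self_intersecting <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  on_seg <- function(px, py, ax, ay, bx, by)
    px >= pmin(ax, bx) - 1e-12 & px <= pmax(ax, bx) + 1e-12 &
    py >= pmin(ay, by) - 1e-12 & py <= pmax(ay, by) + 1e-12
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex), incl. the wrap pair (1, n)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d2 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      d3 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d4 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
      if (abs(d1) < 1e-12 && on_seg(a[1], a[2], b[1], b[2], b[3], b[4]))
        return(TRUE)
      if (abs(d2) < 1e-12 && on_seg(a[3], a[4], b[1], b[2], b[3], b[4]))
        return(TRUE)
      if (abs(d3) < 1e-12 && on_seg(b[1], b[2], a[1], a[2], a[3], a[4]))
        return(TRUE)
      if (abs(d4) < 1e-12 && on_seg(b[3], b[4], a[1], a[2], a[3], a[4]))
        return(TRUE)
    }
  }
  FALSE
}

# Even-odd point-in-polygon, boundary-inclusive. pts: data.frame/matrix with
# columns row, col (integer pixel coords); v: polygon vertex matrix (col,row).
points_in_polygon <- function(pts, v) {
  px <- as.numeric(pts[, "col"]); py <- as.numeric(pts[, "row"])
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # boundary test: point on segment k
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onb <- onb | (abs(cr) < 1e-9 &
                  px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
                  py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9)
    # even-odd ray cast (ray toward +x)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onb
}

points_in_roi <- function(pts, roi) {
  if (roi$kind == "square") {
    pts[, "row"] >= roi$row_range[1] & pts[, "row"] <= roi$row_range[2] &
      pts[, "col"] >= roi$col_range[1] & pts[, "col"] <= roi$col_range[2]
  } else {
    points_in_polygon(pts, roi$vertices)
  }
}

check_roi_in_image <- function(roi, dims) {
  if (roi$kind == "square") {
    if (roi$row_range[1] < 0 || roi$col_range[1] < 0 ||
        roi$row_range[2] > dims[1] - 1 || roi$col_range[2] > dims[2] - 1)
      stop("ROI lies outside the image")
  } else {
    v <- roi$vertices
    if (min(v[, "col"]) < 0 || min(v[, "row"]) < 0 ||
        max(v[, "col"]) > dims[2] - 1 || max(v[, "row"]) > dims[1] - 1)
      stop("polygon exits the image")
  }
  invisible(TRUE)
}

density_result <- function(roi, count, noise_tolerance) {
  structure(
    list(roi = roi, trichome_count = as.integer(count),
         area_px2 = roi$area_px2,
         density = count / roi$area_px2,
         noise_tolerance = noise_tolerance),
    class = "density_result"
  )
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "<density> %d trichomes / %g px^2 = %.6g per px^2 (tolerance %g)\n",
    x$trichome_count, x$area_px2, x$density, x$noise_tolerance))
  invisible(x)
}

#' Trichome density in a centered square
#'
#' @param img a [micrograph].
#' @param center 0-based `(row, col)` click point.
#' @param side square side in px (presets 75 and 150).
#' @param noise_tolerance prominence threshold (default 10).
#' @return A `density_result` with `trichome_count`, `area_px2` (= side^2)
#'   and `density` = count / area.
#' @export
count_in_square <- function(img, center, side = 75, noise_tolerance = 10) {
  img <- as_micrograph(img)
  roi <- square_roi(center, side, dim(img$pixels))
  n <- count_maxima(img, roi, noise_tolerance)
  density_result(roi, n, noise_tolerance)
}

#' Trichome density in a polygon (e.g. a whole compartment)
#'
#' Counts full-image detections inside the polygon (even-odd rule, boundary
#' points count as inside) and divides by the shoelace area.
#'
#' @param img a [micrograph].
#' @param vertices n x 2 matrix of `(col, row)` vertices, or a
#'   [polygon_roi()].
#' @param noise_tolerance prominence threshold (default 10).
#' @return A `density_result`.
#' @export
count_in_polygon <- function(img, vertices, noise_tolerance = 10) {
  img <- as_micrograph(img)
  roi <- if (inherits(vertices, "roi")) vertices else polygon_roi(vertices)
  check_roi_in_image(roi, dim(img$pixels))
  n <- count_maxima(img, roi, noise_tolerance)
  density_result(roi, n, noise_tolerance)
}

#' Ratio of two trichome densities
#'
#' The posterior/anterior density ratio is the standard within-wing
#' comparison: the posterior compartment carries the driven transgene and
#' the anterior compartment serves as internal control.
#'
#' @param a,b `density_result` objects (numerator, denominator).
#' @return `a$density / b$density`.
#' @export
density_ratio <- function(a, b) {
  if (b$density <= 0) stop("denominator density is zero")
  a$density / b$density
}

#' Append a density result to a CSV log
#'
#' Columns `image,roi_id,area_px2,count,density,noise_tolerance`, mirroring
#' an interactive results/log window.
#'
#' @param res a `density_result`.
#' @param path CSV log path (created with header if absent).
#' @param image free-text image identifier.
#' @param roi_id free-text ROI identifier.
#' @return `path`, invisibly.
#' @export
log_density <- function(res, path, image = "", roi_id = "") {
  row <- data.frame(image = image, roi_id = roi_id,
                    area_px2 = res$area_px2, count = res$trichome_count,
                    density = res$density,
                    noise_tolerance = res$noise_tolerance)
  if (!file.exists(path)) {
    utils::write.csv(row, path, row.names = FALSE, quote = FALSE)
  } else {
    suppressWarnings(utils::write.table(
      row, path, sep = ",", col.names = FALSE, row.names = FALSE,
      append = TRUE, quote = FALSE))
  }
  invisible(path)
}

#' Read or write ROI definitions as JSON
#'
#' Squares: `{"kind":"square","center":[row,col],"side":s}`; polygons:
#' `{"kind":"polygon","vertices":[[col,row],...]}`.
#'
#' @param path JSON file path.
#' @param img_dims `(height, width)`, required to validate squares.
#' @return An `roi` object.
#' @export
read_roi_json <- function(path, img_dims) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(spec$kind, "square")) {
    square_roi(spec$center, spec$side, img_dims)
  } else if (identical(spec$kind, "polygon")) {
    polygon_roi(spec$vertices)
  } else {
    stop("roi JSON must have kind 'square' or 'polygon'")
  }
}

#' @rdname read_roi_json
#' @param roi an `roi` object to serialize.
#' @export
write_roi_json <- function(roi, path) {
  spec <- if (roi$kind == "square") {
    list(kind = "square", center = roi$center, side = roi$side)
  } else {
    list(kind = "polygon", vertices = unname(roi$vertices))
  }
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
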