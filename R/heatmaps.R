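# Heat-map rendering: intervein region areas and trichome spacing-cell
# areas, colored on an adjustable value range with a fire-like ramp.

FIRE_STOPS <- list(
  x = c(0, 0.14, 0.29, 0.43, 0.57, 0.71, 0.86, 1),
  r = c(0, 32, 128, 224, 255, 255, 255, 255) / 255,
  g = c(0, 0, 0, 32, 96, 160, 224, 255) / 255,
  b = c(0, 128, 160, 64, 0, 0, 64, 255) / 255
)

#' Map normalized values in \[0, 1\] to RGB colors
#'
#' The default `"fire"` ramp runs black - blue - red - orange - yellow -
#' white, monotone in perceived lightness; `"gray"` is a linear ramp.
#'
#' @param t numeric vector of normalized values (clamped to \[0, 1\]).
#' @param colormap `"fire"` or `"gray"`.
#' @return A length(t) x 3 matrix of RGB in \[0, 1\].
#' @export
colormap_rgb <- function(t, colormap = "fire") {
  t <- pmin(pmax(t, 0), 1)
  if (colormap == "gray") return(cbind(t, t, t))
  if (colormap != "fire") stop("unknown colormap: ", colormap)
  cbind(stats::approx(FIRE_STOPS$x, FIRE_STOPS$r, t)$y,
        stats::approx(FIRE_STOPS$x, FIRE_STOPS$g, t)$y,
        stats::approx(FIRE_STOPS$x, FIRE_STOPS$b, t)$y)
}

#' Heat-map rendering specification
#'
#' @param mode `"intervein_area"` or `"trichome_spacing"`.
#' @param value_min,value_max value range mapped to the ramp endpoints;
#'   `NULL` (default) auto-scales to the observed min/max per image.
#' @param colormap `"fire"` (default) or `"gray"`.
#' @param legend draw a calibration legend bar in the image margin?
#' @return An object of class `heatmap_spec`.
#' @export
heatmap_spec <- function(mode = c("intervein_area", "trichome_spacing"),
                         value_min = NULL, value_max = NULL,
                         colormap = "fire", legend = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(value_min) && !is.null(value_max) && value_min >= value_max)
    stop("value_min must be < value_max")
  structure(list(mode = mode, value_min = value_min, value_max = value_max,
                 colormap = colormap, legend = legend),
            class = "heatmap_spec")
}

resolve_range <- function(spec, values) {
  vmin <- if (is.null(spec$value_min)) min(values) else spec$value_min
  vmax <- if (is.null(spec$value_max)) max(values) else spec$value_max
  if (vmin >= vmax) vmax <- vmin + 1   # all values equal under auto-scale
  c(vmin, vmax)
}

# 3x5 bitmap glyphs for legend labels
GLYPHS <- list(
  "0" = c(7,5,5,5,7), "1" = c(2,6,2,2,7), "2" = c(7,1,7,4,7),
  "3" = c(7,1,7,1,7), "4" = c(5,5,7,1,1), "5" = c(7,4,7,1,7),
  "6" = c(7,4,7,5,7), "7" = c(7,1,1,2,2), "8" = c(7,5,7,5,7),
  "9" = c(7,5,7,1,7), "." = c(0,0,0,0,2), "-" = c(0,0,7,0,0),
  "e" = c(0,7,7,6,7), "+" = c(0,2,7,2,0), " " = c(0,0,0,0,0)
)

draw_text <- function(rgb, text, row, col, value = 0) {
  chars <- strsplit(text, "")[[1]]
  for (ch in chars) {
    gl <- GLYPHS[[ch]]
    if (!is.null(gl)) {
      for (i in 1:5) for (j in 1:3) {
        if (bitwAnd(gl[i], bitwShiftL(1L, 3L - j)) > 0) {
          r <- row + i - 1L; c <- col + j - 1L
          if (r >= 1 && r <= dim(rgb)[1] && c >= 1 && c <= dim(rgb)[2])
            rgb[r, c, ] <- value
        }
      }
    }
    col <- col + 4L
  }
  rgb
}

add_legend <- function(rgb, rng, colormap) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  margin <- 64L
  out <- array(1, dim = c(h, w + margin, 3))
  out[, seq_len(w), ] <- rgb
  bar_h <- max(2L, as.integer(0.6 * h)); bar_w <- 14L
  top <- as.integer((h - bar_h) / 2) + 1L
  bcol <- w + 8L
  tvals <- rev(seq(0, 1, length.out = bar_h))
  cols <- colormap_rgb(tvals, colormap)
  for (k in 1:3)
    out[top:(top + bar_h - 1L), bcol:(bcol + bar_w - 1L), k] <-
      matrix(cols[, k], bar_h, bar_w)
  fmt <- function(v) formatC(v, format = "g", digits = 4)
  out <- draw_text(out, fmt(rng[2]), top - 8L, bcol)
  out <- draw_text(out, fmt(rng[1]), top + bar_h + 3L, bcol)
  out
}

finish_heatmap <- function(rgb, values_df, spec, rng) {
  structure(
    list(rgb = if (spec$legend) add_legend(rgb, rng, spec$colormap) else rgb,
         values = values_df,
         legend_labels = c(value_min = rng[1], value_max = rng[2]),
         spec = spec),
    class = "wing_heatmap"
  )
}

#' @export
print.wing_heatmap <- function(x, ...) {
  cat(sprintf("<wing_heatmap> %s, %d values in [%g, %g], %d x %d px\n",
              x$spec$mode, nrow(x$values), x$legend_labels[1],
              x$legend_labels[2], dim(x$rgb)[1], dim(x$rgb)[2]))
  invisible(x)
}

#' Render the intervein-area heat map
#'
#' Colors each intervein region by its source-resolution area normalized
#' within `[value_min, value_max]` (clamped); non-region pixels are black.
#' Larger regions map to hotter colors, so a growth-promoting genotype
#' shifts posterior regions up the ramp.
#'
#' @param regions list of `intervein_region` objects from
#'   [extract_intervein_regions()].
#' @param spec a [heatmap_spec()] with mode `"intervein_area"`.
#' @return A `wing_heatmap`: `rgb` array, per-region `values`
#'   (`region_id`, `value`, `normalized`), `legend_labels`, `spec`.
#' @export
render_area_heatmap <- function(regions,
                                spec = heatmap_spec("intervein_area")) {
  if (spec$mode != "intervein_area") stop("spec mode must be intervein_area")
  if (length(regions) < 1L) stop("need at least one region")
  areas <- vapply(regions, `[[`, numeric(1), "area_px2")
  rng <- resolve_range(spec, areas)
  tnorm <- pmin(pmax((areas - rng[1]) / (rng[2] - rng[1]), 0), 1)
  cols <- colormap_rgb(tnorm, spec$colormap)
  dm <- dim(regions[[1]]$mask)
  rgb <- array(0, dim = c(dm[1], dm[2], 3))
  for (i in seq_along(regions)) {
    m <- regions[[i]]$mask
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[m] <- cols[i, k]
      rgb[, , k] <- plane
    }
  }
  df <- data.frame(region_id = vapply(regions, `[[`, numeric(1), "region_id"),
                   value = areas, normalized = tnorm)
  finish_heatmap(rgb, df, spec, rng)
}

#' Render the trichome-spacing heat map
#'
#' Colors each watershed spacing cell by its area normalized within
#' `[value_min, value_max]`; boundary lines are black. Cell area is the
#' inverse of local trichome density: sparse (low-density) tissue renders
#' hotter.
#'
#' @param cells a `spacing_cells` object from [trichome_spacing_cells()].
#' @param spec a [heatmap_spec()] with mode `"trichome_spacing"`.
#' @return A `wing_heatmap` with per-cell `values` (`cell_label`, `value`,
#'   `normalized`).
#' @export
render_spacing_heatmap <- function(cells,
                                   spec = heatmap_spec("trichome_spacing")) {
  if (spec$mode != "trichome_spacing") stop("spec mode must be trichome_spacing")
  areas <- cells$cell_areas
  if (length(areas) < 1L) stop("no spacing cells to render")
  rng <- resolve_range(spec, areas)
  tnorm <- pmin(pmax((areas - rng[1]) / (rng[2] - rng[1]), 0), 1)
  cols <- rbind(c(0, 0, 0), colormap_rgb(tnorm, spec$colormap))
  lab <- cells$label_map
  rgb <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (k in 1:3)
    rgb[, , k] <- matrix(cols[lab + 1L, k], nrow(lab), ncol(lab))
  df <- data.frame(cell_label = as.integer(names(areas)),
                   value = as.numeric(areas), normalized = tnorm)
  finish_heatmap(rgb, df, spec, rng)
}

#' Write a rendered heat map as 24-bit PNG
#' @param hm a `wing_heatmap`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  png::writePNG(hm$rgb, path)
  invisible(path)
}

#' Write heat-map values as CSV
#'
#' Columns: region/cell identifier, raw value, normalized value.
#' @param hm a `wing_heatmap`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(hm, path) {
  utils::write.csv(hm$values, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
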