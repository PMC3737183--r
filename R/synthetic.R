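# Synthetic wing generator with full ground truth.
#
# The generator renders a stylized wing blade: a pale field (mounting
# medium), a slightly darker membrane bounded by a darker margin ring, four
# longitudinal veins and two cross veins partitioning the blade into seven
# intervein regions, and a quasi-regular lattice of trichomes placed by a
# hard-core point process. Trichomes are small dark disks (the base — the
# detection target) with a short brighter shaft. Two failure classes seen
# in real transmitted-light micrographs are reproduced on demand:
# coincident dorsal/ventral trichomes sharing one base (a duplicate truth
# point at sub-diameter offset) and undersized faint trichomes whose
# inverted-image prominence straddles the default noise tolerance.

#' Parameters of the synthetic wing generator
#'
#' Defaults emulate a 2080 x 1544 transmitted-light photomicrograph of an
#' adult wing taken with the condenser closed for maximum contrast: pale
#' surround (~235), slightly darker membrane (~222), veins and margin
#' (~115-125), trichome bases (~60). The anterior compartment trichome rate
#' of 0.0035 per px^2 puts roughly 80 trichomes in a 150 px square.
#'
#' @param width,height image size in px (>= 256 each).
#' @param trichome_rate anterior trichome rate, trichomes per px^2 of
#'   intervein area.
#' @param rate_ratio posterior/anterior rate ratio (1 = uniform wing).
#' @param coincident_fraction fraction of trichomes gaining a coincident
#'   duplicate at sub-diameter offset (paper failure class 1).
#' @param small_faint_fraction fraction rendered at half diameter and ~10
#'   grey-level contrast (paper failure class 2).
#' @param noise_sd additive Gaussian pixel noise, grey levels.
#' @param dirt_specks number of dark dirt specks scattered over the field.
#' @param min_spacing hard-core minimum trichome spacing, px.
#' @param base_diameter trichome base diameter, px.
#' @param base_intensity grey level of a normal base.
#' @param small_faint_contrast grey levels below the membrane for the faint
#'   class (straddles the default noise tolerance of 10).
#' @return A named list of generator parameters.
#' @export
wing_params <- function(width = 2080, height = 1544,
                        trichome_rate = 0.0035, rate_ratio = 1,
                        coincident_fraction = 0.02,
                        small_faint_fraction = 0.03,
                        noise_sd = 4, dirt_specks = 0,
                        min_spacing = 10, base_diameter = 7,
                        base_intensity = 60, small_faint_contrast = 10) {
  p <- list(width = as.integer(width), height = as.integer(height),
            trichome_rate = trichome_rate, rate_ratio = rate_ratio,
            coincident_fraction = coincident_fraction,
            small_faint_fraction = small_faint_fraction,
            noise_sd = noise_sd, dirt_specks = as.integer(dirt_specks),
            min_spacing = min_spacing, base_diameter = base_diameter,
            base_intensity = base_intensity,
            small_faint_contrast = small_faint_contrast,
            background_intensity = 235, membrane_intensity = 222,
            vein_intensity = 120, vein_thickness = 16,
            margin_thickness = 18, shaft_length = 6, shaft_intensity = 170)
  stopifnot(p$width >= 256L, p$height >= 256L,
            p$trichome_rate > 0, p$rate_ratio > 0,
            p$coincident_fraction >= 0, p$coincident_fraction <= 1,
            p$small_faint_fraction >= 0, p$small_faint_fraction <= 1)
  p
}

# separable binary erosion by a (2b+1)-square (conservative stand-in for a
# disk of radius b); pixels outside the image count as background
erode_square <- function(mask, b) {
  if (b <= 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  roll_all <- function(x, b) {
    n <- nrow(x)
    cs <- apply(x, 2, cumsum)
    cs <- rbind(matrix(0, 1, ncol(x)), cs)
    lo <- pmax(seq_len(n) - b - 1L, 0L) + 1L
    hi <- pmin(seq_len(n) + b, n) + 1L
    full <- (pmin(seq_len(n) + b, n) - pmax(seq_len(n) - b, 1L) + 1L) == 2L * b + 1L
    (cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]) == (2 * b + 1) & full
  }
  v <- roll_all(m, b)
  t(roll_all(t(matrix(as.numeric(v), nrow(mask), ncol(mask))), b))
}

# wing-blade geometry shared by mask construction and region labelling
wing_geometry <- function(p) {
  h <- p$height; w <- p$width
  rc <- (h - 1) / 2; cc <- (w - 1) / 2
  ar <- 0.36 * h; ac <- 0.46 * w
  vb <- c(-0.55, -0.20, 0.15, 0.50)
  vq <- c(0.10, 0.05, 0.00, -0.05)
  vs <- c(0.15, 0.10, 0.05, -0.05)
  cols <- 0:(w - 1)
  u <- (cols - cc) / ac
  vein_rows <- sapply(1:4, function(k)
    rc + (vb[k] + vq[k] * u + vs[k] * u^2) * ar)   # w x 4
  acv_col <- cc + 0.10 * ac    # anterior cross vein, between veins 2 and 3
  pcv_col <- cc - 0.25 * ac    # posterior cross vein, between veins 3 and 4
  list(rc = rc, cc = cc, ar = ar, ac = ac, vein_rows = vein_rows,
       acv_col = acv_col, pcv_col = pcv_col)
}

#' Generate a synthetic wing micrograph with ground truth
#'
#' Deterministic given `seed`: the same parameters and seed give a
#' bit-identical image and truth record.
#'
#' @param params a [wing_params()] list.
#' @param seed integer RNG seed.
#' @return A list with `image` (a [micrograph]) and `truth`, an object of
#'   class `wing_ground_truth`: `trichomes` (data.frame of 0-based `row`,
#'   `col`, `diameter`, `contrast`, `coincident_pair`, `small_faint`),
#'   disjoint logical `vein_mask` / `intervein_mask` / `background_mask`
#'   tiling the image, `region_ids` (integer matrix, 1..7 on intervein,
#'   0 elsewhere), `posterior_regions` (region ids of the posterior
#'   compartment), and `params` (with the seed).
#' @export
generate_wing <- function(params = wing_params(), seed = 1) {
  p <- params
  max_rate <- max(p$trichome_rate, p$trichome_rate * p$rate_ratio)
  pack_limit <- 2 / (sqrt(3) * p$min_spacing^2)
  if (max_rate > 0.55 * pack_limit)
    stop(sprintf(
      "trichome rate %.4g exceeds feasible hard-core packing (limit %.4g at spacing %g)",
      max_rate, 0.55 * pack_limit, p$min_spacing))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  h <- p$height; w <- p$width
  g <- wing_geometry(p)
  rowm <- matrix(0:(h - 1), h, w)
  e2 <- sweep((matrix(0:(h - 1), h, w) - g$rc)^2 / g$ar^2, 2,
              ((0:(w - 1) - g$cc)^2) / g$ac^2, `+`)
  e <- sqrt(e2)
  inside <- e < 1
  e_in <- 1 - p$margin_thickness / min(g$ar, g$ac)
  margin <- inside & e >= e_in

  th <- p$vein_thickness / 2
  long_vein <- matrix(FALSE, h, w)
  for (k in 1:4) {
    vr <- matrix(g$vein_rows[, k], h, w, byrow = TRUE)
    long_vein <- long_vein | (abs(rowm - vr) <= th)
  }
  long_vein <- long_vein & inside
  colm <- matrix(0:(w - 1), h, w, byrow = TRUE)
  vr2 <- matrix(g$vein_rows[, 2], h, w, byrow = TRUE)
  vr3 <- matrix(g$vein_rows[, 3], h, w, byrow = TRUE)
  vr4 <- matrix(g$vein_rows[, 4], h, w, byrow = TRUE)
  cross_vein <- (abs(colm - g$acv_col) <= th & rowm >= vr2 & rowm <= vr3) |
    (abs(colm - g$pcv_col) <= th & rowm >= vr3 & rowm <= vr4)
  cross_vein <- cross_vein & inside

  vein_mask <- (margin | long_vein | cross_vein) & inside
  intervein <- inside & !vein_mask & e < e_in
  vein_mask <- inside & !intervein           # anything inside that is not intervein
  background <- !inside

  # intervein region ids 1..7: five bands between margin and veins, with
  # bands 3 and 4 split by their cross veins
  nabove <- matrix(0L, h, w)
  for (k in 1:4)
    nabove <- nabove + (rowm > matrix(g$vein_rows[, k], h, w, byrow = TRUE))
  band <- nabove + 1L
  region_ids <- matrix(0L, h, w)
  region_ids[intervein] <- band[intervein]
  rid <- region_ids
  rid[region_ids == 2L] <- 2L
  rid[region_ids == 3L & colm < g$acv_col] <- 3L
  rid[region_ids == 3L & colm >= g$acv_col] <- 4L
  rid[region_ids == 4L & colm < g$pcv_col] <- 5L
  rid[region_ids == 4L & colm >= g$pcv_col] <- 6L
  rid[region_ids == 5L] <- 7L
  region_ids <- rid
  posterior_regions <- c(5L, 6L, 7L)

  # ---- trichome placement: hard-core dart throwing per region ----
  # bases stay clear of veins/margin by a small buffer; shafts may touch a
  # vein, where the darker vein level simply wins
  buffer <- ceiling(p$base_diameter / 2) + 3
  eligible <- erode_square(intervein, buffer)
  total_target <- 0
  pts_r <- integer(0); pts_c <- integer(0); pts_region <- integer(0)
  cell <- p$min_spacing
  grid_nr <- ceiling(h / cell); grid_nc <- ceiling(w / cell)
  grid <- vector("list", grid_nr * grid_nc)
  msq <- p$min_spacing^2
  for (reg in 1:7) {
    sel <- which(eligible & region_ids == reg)
    if (length(sel) == 0L) next
    area <- sum(region_ids == reg)
    rate <- p$trichome_rate *
      if (reg %in% posterior_regions) p$rate_ratio else 1
    n_target <- stats::rpois(1, rate * area)
    total_target <- total_target + n_target
    if (n_target == 0L) next
    accepted <- 0L
    rounds <- 0L
    while (accepted < n_target && rounds < 60L) {
      rounds <- rounds + 1L
      need <- n_target - accepted
      cand <- sel[sample.int(length(sel), min(4L * need, length(sel)),
                             replace = TRUE)]
      cr <- (cand - 1L) %% h
      cc2 <- (cand - 1L) %/% h
      for (i in seq_along(cand)) {
        r <- cr[i]; c <- cc2[i]
        gi <- (r %/% cell) + 1L; gj <- (c %/% cell) + 1L
        ok <- TRUE
        for (di in -1:1) for (dj in -1:1) {
          ii <- gi + di; jj <- gj + dj
          if (ii < 1L || ii > grid_nr || jj < 1L || jj > grid_nc) next
          ids <- grid[[(jj - 1L) * grid_nr + ii]]
          if (length(ids) &&
              any((pts_r[ids] - r)^2 + (pts_c[ids] - c)^2 < msq)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        pts_r <- c(pts_r, r); pts_c <- c(pts_c, c)
        pts_region <- c(pts_region, reg)
        idx <- (gj - 1L) * grid_nr + gi
        grid[[idx]] <- c(grid[[idx]], length(pts_r))
        accepted <- accepted + 1L
        if (accepted >= n_target) break
      }
    }
  }
  n <- length(pts_r)
  if (n < 0.75 * total_target)
    stop("hard-core packing saturated; reduce trichome_rate or min_spacing")
  if (n == 0L) stop("no trichomes placed; increase trichome_rate")

  small_faint <- stats::runif(n) < p$small_faint_fraction
  coin_parent <- stats::runif(n) < p$coincident_fraction & !small_faint
  tri <- data.frame(
    row = pts_r, col = pts_c, region = pts_region,
    diameter = ifelse(small_faint, p$base_diameter / 2, p$base_diameter),
    contrast = ifelse(small_faint, p$small_faint_contrast,
                      p$membrane_intensity - p$base_intensity),
    coincident_pair = coin_parent, small_faint = small_faint,
    duplicate = FALSE
  )
  # coincident duplicates: a second truth point at sub-diameter offset
  if (any(coin_parent)) {
    idx <- which(coin_parent)
    ang <- stats::runif(length(idx), 0, 2 * pi)
    dist <- stats::runif(length(idx), 0.35, 0.65) * p$base_diameter
    dr <- round(sin(ang) * dist); dc <- round(cos(ang) * dist)
    zero <- dr == 0 & dc == 0
    dc[zero] <- 3
    dup <- tri[idx, ]
    dup$row <- pmin(pmax(dup$row + dr, 0L), h - 1L)
    dup$col <- pmin(pmax(dup$col + dc, 0L), w - 1L)
    dup$duplicate <- TRUE
    tri <- rbind(tri, dup)
  }

  # ---- rendering ----
  img <- matrix(p$background_intensity, h, w)
  img[inside] <- p$membrane_intensity
  # veins/margin carry a gentle proximal-distal intensity ramp plus a
  # 1-grey-level deterministic dither, so a noise-free wing has no large
  # flat vein plateau (whose centroid could fall off the vein)
  ramp <- (colm - (g$cc - g$ac)) / (2 * g$ac)
  ramp[ramp < 0] <- 0; ramp[ramp > 1] <- 1
  dith <- (rowm * 7L + colm * 13L) %% 3L - 1L
  img[vein_mask] <- round((p$vein_intensity - 5) + 10 * ramp[vein_mask]) +
    dith[vein_mask]

  disk_offsets <- function(radius) {
    d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
    d[d$dr^2 + d$dc^2 <= radius^2 + 1e-9, ]
  }
  stamp <- function(img, rows, cols, offs, value) {
    rr <- rep(rows, each = nrow(offs)) + offs$dr
    cc <- rep(cols, each = nrow(offs)) + offs$dc
    keep <- rr >= 0 & rr < h & cc >= 0 & cc < w
    img[cbind(rr[keep] + 1L, cc[keep] + 1L)] <- value
    img
  }
  # shafts: short brighter line distal-up from each normal base
  normal <- !tri$small_faint
  if (any(normal)) {
    ang <- stats::runif(sum(normal), -pi / 5, -pi / 12)
    for (t in seq_len(p$shaft_length)) {
      rr <- round(tri$row[normal] + t * sin(ang))
      cc <- round(tri$col[normal] + t * cos(ang))
      keep <- rr >= 0 & rr < h & cc >= 0 & cc < w
      sel2 <- cbind(rr[keep] + 1L, cc[keep] + 1L)
      cur <- img[sel2]
      img[sel2] <- pmin(cur, p$shaft_intensity)
    }
  }
  offs_n <- disk_offsets(floor(p$base_diameter / 2))
  offs_f <- disk_offsets(1)
  img <- stamp(img, tri$row[normal], tri$col[normal], offs_n,
               p$base_intensity)
  if (any(tri$small_faint))
    img <- stamp(img, tri$row[tri$small_faint], tri$col[tri$small_faint],
                 offs_f, p$membrane_intensity - p$small_faint_contrast)
  if (p$noise_sd > 0)
    img <- img + round(matrix(stats::rnorm(h * w, 0, p$noise_sd), h, w))
  if (p$dirt_specks > 0) {
    dr <- sample.int(h, p$dirt_specks, replace = TRUE) - 1L
    dc <- sample.int(w, p$dirt_specks, replace = TRUE) - 1L
    img <- stamp(img, dr, dc, offs_f, 80)
  }
  img[img < 0] <- 0; img[img > 255] <- 255

  truth <- structure(
    list(trichomes = tri[order(tri$row, tri$col), ],
         vein_mask = vein_mask, intervein_mask = intervein,
         background_mask = background, region_ids = region_ids,
         posterior_regions = posterior_regions,
         params = c(p, list(seed = seed))),
    class = "wing_ground_truth"
  )
  list(image = micrograph(img, source = "synthetic",
                          scale_note = "synthetic 200x-equivalent"),
       truth = truth)
}

#' @export
print.wing_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<wing_ground_truth> %d trichomes (%d coincident-pair, %d small-faint), %d intervein regions\n",
    nrow(x$trichomes), sum(x$trichomes$coincident_pair),
    sum(x$trichomes$small_faint), max(x$region_ids)))
  invisible(x)
}

#' Ground-truth class map at the segmentation working resolution
#'
#' Nearest-neighbour downsampling of the true vein/intervein/background
#' masks to a 1/2/3-coded class map, for training fixtures and for particle
#' analysis of a perfect segmentation.
#'
#' @param truth a `wing_ground_truth`.
#' @param width,height target resolution (defaults 512 x 380).
#' @return Integer class map (1 = vein, 2 = intervein, 3 = background).
#' @export
ground_truth_class_map <- function(truth, width = 512, height = 380) {
  cm <- matrix(3L, nrow(truth$vein_mask), ncol(truth$vein_mask))
  cm[truth$vein_mask] <- 1L
  cm[truth$intervein_mask] <- 2L
  upscale_nn(cm, height, width)
}

#' Sparse training labels sampled from ground-truth masks
#'
#' @param truth a `wing_ground_truth`.
#' @param n_per_class labeled pixels per class (default 200).
#' @param seed RNG seed for the sample.
#' @param width,height working resolution.
#' @return Integer label matrix (0 = unlabeled, 1 = vein, 2 = intervein,
#'   3 = background) at the working resolution.
#' @export
ground_truth_labels <- function(truth, n_per_class = 200, seed = 1,
                                width = 512, height = 380) {
  cm <- ground_truth_class_map(truth, width, height)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  lab <- matrix(0L, nrow(cm), ncol(cm))
  for (k in 1:3) {
    sel <- which(cm == k)
    take <- sample(sel, min(n_per_class, length(sel)))
    lab[take] <- k
  }
  lab
}

#' Select non-overlapping audit squares inside intervein tissue
#'
#' Deterministically scans a coarse grid of candidate centers and keeps the
#' first `n` squares that lie entirely inside the intervein mask and do not
#' overlap one another — the synthetic analog of picking audit fields for a
#' manual recount.
#'
#' @param truth a `wing_ground_truth`.
#' @param side square side, px (default 75).
#' @param n number of squares wanted.
#' @param stride grid step between candidate centers, px.
#' @return A list of [square_roi()] objects (length <= n).
#' @export
select_intervein_squares <- function(truth, side = 75, n = 5, stride = 40) {
  half <- (side - 1L) %/% 2L
  ok <- erode_square(truth$intervein_mask, side - 1L - half)
  dims <- dim(truth$intervein_mask)
  rows <- seq(half, dims[1] - side + half, by = stride)
  cols <- seq(half, dims[2] - side + half, by = stride)
  chosen <- list()
  for (r in rows) {
    for (c in cols) {
      if (!ok[r + 1L, c + 1L]) next
      clash <- FALSE
      for (s in chosen)
        if (abs(s$center[1] - r) < side && abs(s$center[2] - c) < side) {
          clash <- TRUE; break
        }
      if (clash) next
      chosen[[length(chosen) + 1L]] <- square_roi(c(r, c), side, dims)
      if (length(chosen) >= n) return(chosen)
    }
  }
  chosen
}

#' Match detections against ground truth
#'
#' Greedy nearest-neighbour matching in increasing distance order; each
#' truth point and each prediction is used at most once; matches only
#' within `radius`.
#'
#' @param pred a `trichome_points` object, or a data.frame/matrix with
#'   columns `row`, `col`.
#' @param truth a `wing_ground_truth`, or a data.frame/matrix with columns
#'   `row`, `col`.
#' @param radius matching radius in px (default 4, at 2080 x 1544 scale).
#' @return An object of class `detection_eval`: `matched`, `missed`,
#'   `spurious`, `recall`, `precision`.
#' @export
evaluate_detection <- function(pred, truth, radius = 4) {
  if (radius <= 0) stop("radius must be > 0")
  pp <- if (inherits(pred, "trichome_points")) pred$points else as.data.frame(pred)
  tt <- if (inherits(truth, "wing_ground_truth")) truth$trichomes else as.data.frame(truth)
  np <- nrow(pp); nt <- nrow(tt)
  if (np == 0L || nt == 0L) {
    matched <- 0L
  } else {
    cell <- max(1, ceiling(radius))
    tr <- tt$row; tc <- tt$col
    key <- function(r, c) paste(r %/% cell, c %/% cell)
    tcells <- split(seq_len(nt), key(tr, tc))
    pairs_p <- integer(0); pairs_t <- integer(0); pairs_d <- numeric(0)
    for (i in seq_len(np)) {
      pr <- pp$row[i]; pc <- pp$col[i]
      gi <- pr %/% cell; gj <- pc %/% cell
      cand <- integer(0)
      for (di in -1:1) for (dj in -1:1) {
        ids <- tcells[[paste(gi + di, gj + dj)]]
        if (!is.null(ids)) cand <- c(cand, ids)
      }
      if (!length(cand)) next
      d <- sqrt((tr[cand] - pr)^2 + (tc[cand] - pc)^2)
      keep <- d <= radius
      pairs_p <- c(pairs_p, rep(i, sum(keep)))
      pairs_t <- c(pairs_t, cand[keep])
      pairs_d <- c(pairs_d, d[keep])
    }
    ord <- order(pairs_d, pairs_t, pairs_p)
    used_p <- logical(np); used_t <- logical(nt)
    matched <- 0L
    for (k in ord) {
      i <- pairs_p[k]; j <- pairs_t[k]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      matched <- matched + 1L
    }
  }
  structure(
    list(matched = matched, missed = nt - matched, spurious = np - matched,
         recall = if (nt > 0) matched / nt else NA_real_,
         precision = if (np > 0) matched / np else NA_real_,
         radius = radius, n_truth = nt, n_pred = np),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "<detection_eval> matched %d / %d truth (recall %.3f), %d spurious (precision %.3f), radius %g px\n",
    x$matched, x$n_truth, x$recall, x$spurious, x$precision, x$radius))
  invisible(x)
}

#' Measured per-compartment trichome densities on a synthetic wing
#'
#' Runs the detector on the full image, assigns detections to the anterior
#' or posterior compartment via the ground-truth intervein region ids, and
#' returns measured densities (per px^2 of intervein area) and the
#' posterior/anterior ratio.
#'
#' @param img the synthetic [micrograph].
#' @param truth its `wing_ground_truth`.
#' @param noise_tolerance prominence threshold (default 10).
#' @return A list with `anterior` and `posterior` (each `count`, `area_px2`,
#'   `density`) and `ratio` (posterior density / anterior density).
#' @export
measure_compartment_densities <- function(img, truth, noise_tolerance = 10) {
  img <- as_micrograph(img)
  tp <- find_maxima(img, noise_tolerance, invert_first = TRUE)
  rid <- truth$region_ids[cbind(tp$points$row + 1L, tp$points$col + 1L)]
  post <- truth$posterior_regions
  ant_ids <- setdiff(seq_len(max(truth$region_ids)), post)
  comp <- function(ids) {
    count <- sum(rid %in% ids)
    area <- sum(truth$region_ids %in% ids)
    list(count = count, area_px2 = area, density = count / area)
  }
  a <- comp(ant_ids); b <- comp(post)
  list(anterior = a, posterior = b, ratio = b$density / a$density)
}

#' Write the synthetic ground truth to plain-text files
#'
#' Writes the truth CSV (`row,col,diameter,contrast,coincident_pair,
#' small_faint`), the class masks as an indexed PNG, and the parameter
#' record as JSON.
#'
#' @param truth a `wing_ground_truth`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"wing"`).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir, stem = "wing") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    truth$trichomes[, c("row", "col", "diameter", "contrast",
                        "coincident_pair", "small_faint", "duplicate")],
    file.path(dir, paste0(stem, "_truth.csv")),
    row.names = FALSE, quote = FALSE)
  cm <- matrix(3L, nrow(truth$vein_mask), ncol(truth$vein_mask))
  cm[truth$vein_mask] <- 1L
  cm[truth$intervein_mask] <- 2L
  png::writePNG(cm / 255, file.path(dir, paste0(stem, "_classes.png")))
  pars <- truth$params
  jsonlite::write_json(pars, file.path(dir, paste0(stem, "_params.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
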