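# Trainable vein segmentation: a per-pixel random forest over the 15-feature
# stack, followed by particle analysis of the intervein class.

CLASS_LABELS <- c("vein", "intervein", "background")

#' Train the vein/intervein/background pixel classifier
#'
#' Fits an ensemble of decision trees (a random forest: each tree on a
#' bootstrap sample of the labeled pixels with sqrt(n_features) candidate
#' features per split) on the feature vectors of labeled pixels.
#'
#' @param img a [micrograph] at the 512 x 380 working resolution (resized
#'   automatically if larger).
#' @param labels integer matrix of the same size as the working-resolution
#'   image: 0 = unlabeled, 1 = vein (incl. margin), 2 = intervein,
#'   3 = background. At least 50 labeled pixels per class are required.
#' @param n_trees number of trees (default 100).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return An object of class `wing_classifier` with the fitted `forest`,
#'   `feature_spec`, `class_labels`, `train_seed` and training-pixel
#'   accuracy `train_acc` (>= 0.95 by construction sanity check).
#' @export
train_classifier <- function(img, labels, n_trees = 100, seed = 1) {
  img <- as_micrograph(img)
  if (nrow(img$pixels) != WORK_HEIGHT || ncol(img$pixels) != WORK_WIDTH)
    img <- resize(img, WORK_WIDTH, WORK_HEIGHT)
  if (!all(dim(labels) == dim(img$pixels)))
    stop("label mask must match the working-resolution image")
  lab <- as.integer(labels)
  counts <- tabulate(lab[lab > 0L], nbins = 3L)
  short <- which(counts < 50L)
  if (length(short) > 0L)
    stop("need >= 50 labeled pixels per class; short: ",
         paste(CLASS_LABELS[short], collapse = ", "))
  feats <- compute_features(img)
  sel <- which(lab > 0L)
  x <- feats[sel, , drop = FALSE]
  y <- factor(CLASS_LABELS[lab[sel]], levels = CLASS_LABELS)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  acc <- mean(predict_class(forest, x) == as.integer(y))
  if (acc < 0.95)
    warning(sprintf("training-pixel accuracy %.3f below the 0.95 sanity floor", acc))
  structure(
    list(forest = forest, feature_spec = attr(feats, "feature_spec"),
         class_labels = CLASS_LABELS, train_seed = seed, train_acc = acc,
         n_trees = n_trees),
    class = "wing_classifier"
  )
}

#' @export
print.wing_classifier <- function(x, ...) {
  cat(sprintf(
    "<wing_classifier> %d trees on %d features, classes: %s; training accuracy %.3f\n",
    x$n_trees, nrow(x$feature_spec), paste(x$class_labels, collapse = "/"),
    x$train_acc))
  invisible(x)
}

#' Save / load a trained classifier
#'
#' Serialized as a single portable file (an RDS container holding the tree
#' tables plus a format-version field).
#'
#' @param model a `wing_classifier`.
#' @param path file path.
#' @return `path` (save) or the `wing_classifier` (load).
#' @export
save_classifier <- function(model, path) {
  model$format_version <- 1L
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "wing_classifier"))
    stop("file does not contain a wing_classifier: ", path)
  model
}

# Deterministic class prediction: argmax over tree votes with ties broken
# by class order. predict.randomForest itself breaks vote ties via the R
# RNG, which would make repeated segmentations differ.
predict_class <- function(forest, x) {
  votes <- stats::predict(forest, x, type = "vote")
  max.col(votes, ties.method = "first")
}

# 3x3 modal (majority) filter on a class map; ties keep the center class if
# it participates in the tie, otherwise the smallest class id wins.
modal3 <- function(cm, n_classes = 3L) {
  nr <- nrow(cm); nc <- ncol(cm)
  counts <- array(0L, dim = c(nr, nc, n_classes))
  for (dr in -1:1) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    for (dc in -1:1) {
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      sh <- cm[rs, cs, drop = FALSE]
      for (k in seq_len(n_classes))
        counts[, , k] <- counts[, , k] + (sh == k)
    }
  }
  best <- matrix(1L, nr, nc)
  bestn <- counts[, , 1]
  for (k in 2:n_classes) {
    better <- counts[, , k] > bestn
    best[better] <- k
    bestn[better] <- counts[, , k][better]
  }
  # center keeps its class on ties it participates in
  center_n <- matrix(0L, nr, nc)
  for (k in seq_len(n_classes))
    center_n[cm == k] <- counts[, , k][cm == k]
  tie_keep <- center_n == bestn
  best[tie_keep] <- cm[tie_keep]
  best
}

#' Segment a wing micrograph into vein / intervein / background
#'
#' Resizes the input to the 512 x 380 working resolution, classifies every
#' pixel by majority vote of the forest, despeckles once with a 3x3 modal
#' filter, and renders a class-boundary outline image upscaled to the
#' source resolution by nearest neighbour.
#'
#' @param img a [micrograph] at source resolution.
#' @param model a `wing_classifier` whose `feature_spec` matches
#'   [compute_features()].
#' @return An object of class `wing_segmentation`: `class_map` (380 x 512
#'   integer matrix, 1 = vein, 2 = intervein, 3 = background), `outline`
#'   (a source-resolution [micrograph]: white with black class boundaries),
#'   `source_dims`.
#' @export
segment_wing <- function(img, model) {
  img <- as_micrograph(img)
  if (!identical(model$feature_spec$name, FEATURE_NAMES))
    stop("classifier feature_spec does not match this package's feature stack")
  src_dims <- dim(img$pixels)
  work <- if (all(src_dims == c(WORK_HEIGHT, WORK_WIDTH))) img
          else resize(img, WORK_WIDTH, WORK_HEIGHT)
  feats <- compute_features(work)
  cm <- matrix(predict_class(model$forest, feats),
               nrow = WORK_HEIGHT, ncol = WORK_WIDTH)
  cm <- modal3(cm, n_classes = length(model$class_labels))
  # class boundaries: pixel with any 4-neighbour of a different class
  nr <- nrow(cm); nc <- ncol(cm)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | (cm[-nr, ] != cm[-1, ])
  b[-1, ] <- b[-1, ] | (cm[-1, ] != cm[-nr, ])
  b[, -nc] <- b[, -nc] | (cm[, -nc] != cm[, -1])
  b[, -1] <- b[, -1] | (cm[, -1] != cm[, -nc])
  outline_small <- matrix(255L, nr, nc)
  outline_small[b] <- 0L
  outline <- micrograph(upscale_nn(outline_small, src_dims[1], src_dims[2]),
                        source = "segmentation outline")
  structure(
    list(class_map = cm, outline = outline, source_dims = src_dims),
    class = "wing_segmentation"
  )
}

#' @export
print.wing_segmentation <- function(x, ...) {
  tab <- tabulate(x$class_map, nbins = 3L)
  cat(sprintf(
    "<wing_segmentation> working map %d x %d: vein %d px, intervein %d px, background %d px\n",
    nrow(x$class_map), ncol(x$class_map), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Particle analysis: extract labeled intervein regions from a class map
#'
#' Takes the 4-connected components of the intervein class, fills holes,
#' discards components below 200 px (at working resolution) and components
#' touching the image border (background leak-through), labels the
#' survivors 1..k in decreasing area order, and upscales each mask to the
#' source resolution by nearest neighbour. Region area is measured at
#' source resolution.
#'
#' @param class_map 380 x 512 integer class map (2 = intervein), e.g. from
#'   [segment_wing()] or a ground-truth map.
#' @param source_dims `(height, width)` of the source image the regions
#'   will be measured on.
#' @param min_area_px minimum component area at working resolution
#'   (default 200).
#' @return A list of `intervein_region` objects, each with `region_id`,
#'   `mask` (working resolution, logical), `mask_fullres`, `area_px2` (at
#'   source resolution), and `trichome_count`/`density` slots filled later
#'   by [intervein_density()].
#' @export
extract_intervein_regions <- function(class_map, source_dims = dim(class_map),
                                      min_area_px = 200) {
  iv <- matrix(as.integer(class_map == 2L), nrow(class_map), ncol(class_map))
  lab <- cpp_label4(iv)
  k <- max(lab)
  if (k == 0L) stop("segmentation produced no intervein pixels; retrain the classifier")
  nr <- nrow(lab); nc <- ncol(lab)
  regions <- list()
  for (i in seq_len(k)) {
    comp <- matrix(as.integer(lab == i), nr, nc)
    comp <- cpp_fill_holes(comp)
    area_work <- sum(comp)
    touches <- any(comp[1, ] > 0L) || any(comp[nr, ] > 0L) ||
      any(comp[, 1] > 0L) || any(comp[, nc] > 0L)
    if (area_work < min_area_px || touches) next
    regions[[length(regions) + 1L]] <- comp
  }
  if (length(regions) == 0L)
    stop("no intervein regions survive particle analysis; retrain the classifier")
  areas_work <- vapply(regions, sum, numeric(1))
  ord <- order(-areas_work)
  out <- vector("list", length(regions))
  for (j in seq_along(ord)) {
    comp <- regions[[ord[j]]]
    full <- upscale_nn(comp, source_dims[1], source_dims[2]) > 0L
    out[[j]] <- structure(
      list(region_id = j, mask = comp > 0L, mask_fullres = full,
           area_px2 = sum(full), trichome_count = NULL, density = NULL),
      class = "intervein_region"
    )
  }
  out
}

#' @export
print.intervein_region <- function(x, ...) {
  cat(sprintf("<intervein_region %d> area %g px^2%s\n", x$region_id,
              x$area_px2,
              if (!is.null(x$density))
                sprintf(", %d trichomes, density %.6g per px^2",
                        x$trichome_count, x$density) else ""))
  invisible(x)
}

#' Trichome count and density within an intervein region
#'
#' Counts full-resolution detections inside the region's full-resolution
#' mask and fills the `trichome_count` and `density` slots.
#'
#' @param img the source-resolution [micrograph].
#' @param region an `intervein_region` with `mask_fullres` matching `img`.
#' @param noise_tolerance prominence threshold (default 10).
#' @return The completed `intervein_region`.
#' @export
intervein_density <- function(img, region, noise_tolerance = 10) {
  img <- as_micrograph(img)
  if (is.null(region$mask_fullres) || sum(region$mask_fullres) == 0)
    stop("region has an empty full-resolution mask")
  if (!all(dim(region$mask_fullres) == dim(img$pixels)))
    stop("region mask does not match image dimensions")
  tp <- find_maxima(img, noise_tolerance, invert_first = TRUE)
  inside <- region$mask_fullres[cbind(tp$points$row + 1L, tp$points$col + 1L)]
  region$trichome_count <- sum(inside)
  region$density <- region$trichome_count / region$area_px2
  region
}

#' Write an intervein ROI table as CSV
#'
#' Columns `region_id,area_px2,count,density` (count/density NA when the
#' regions have not been completed by [intervein_density()]).
#'
#' @param regions list of `intervein_region` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  df <- data.frame(
    region_id = vapply(regions, `[[`, numeric(1), "region_id"),
    area_px2 = vapply(regions, `[[`, numeric(1), "area_px2"),
    count = vapply(regions, function(r)
      if (is.null(r$trichome_count)) NA_real_ else r$trichome_count,
      numeric(1)),
    density = vapply(regions, function(r)
      if (is.null(r$density)) NA_real_ else r$density, numeric(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a class map as an 8-bit indexed PNG
#' @param class_map integer class map (values 1..3).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(class_map, path) {
  png::writePNG(class_map / 255, path)
  invisible(path)
}
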