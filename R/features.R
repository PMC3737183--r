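# Per-pixel feature stack for trainable vein segmentation.
#
# All features are computed at the working resolution (512 x 380). Gaussian
# smoothing is separable and applied as banded row/column operator matrices
# with truncation at 3 sigma and per-row renormalization (replicate-like
# boundary handling). Derivatives are central differences of the smoothed
# image; Hessian eigenvalues come from the closed form for symmetric 2x2
# matrices.

FEATURE_NAMES <- c(
  "raw", "gauss_1", "gauss_2", "gauss_4", "gauss_8", "gauss_16",
  "grad_1", "grad_2", "grad_4", "dog_1_4", "dog_2_8",
  "hess_max_2", "hess_min_2", "hess_max_4", "hess_min_4")

gauss_operator <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  idx_center <- rep(seq_len(n), each = length(x))
  idx_src <- idx_center + rep(x, times = n)
  keep <- idx_src >= 1L & idx_src <= n
  m <- matrix(0, n, n)
  m[cbind(idx_center[keep], idx_src[keep])] <-
    rep(k, times = n)[keep]
  m / rowSums(m)
}

gauss_smooth <- function(px, sigma) {
  kr <- gauss_operator(nrow(px), sigma)
  kc <- gauss_operator(ncol(px), sigma)
  kr %*% px %*% t(kc)
}

central_diff_rows <- function(m) {
  nr <- nrow(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  (dn - up) / 2
}

central_diff_cols <- function(m) {
  nc <- ncol(m)
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  (rt - lf) / 2
}

#' Per-pixel features for the vein/intervein/background classifier
#'
#' 15 features per pixel, in fixed order: raw intensity; Gaussian-smoothed
#' intensity at sigma in {1, 2, 4, 8, 16}; gradient magnitude at sigma in
#' {1, 2, 4}; difference of Gaussians (1, 4) and (2, 8); larger and smaller
#' Hessian eigenvalues at sigma in {2, 4}.
#'
#' @param img a [micrograph] already at the 512 x 380 working resolution.
#' @return A numeric matrix with one row per pixel (column-major pixel
#'   order) and 15 named feature columns; the feature specification is
#'   attached as attribute `feature_spec`.
#' @export
compute_features <- function(img) {
  img <- as_micrograph(img)
  px <- img$pixels
  if (nrow(px) != WORK_HEIGHT || ncol(px) != WORK_WIDTH)
    stop(sprintf("features are computed at the %d x %d working resolution; resize first",
                 WORK_WIDTH, WORK_HEIGHT))
  px <- px * 1.0
  sm <- lapply(c(1, 2, 4, 8, 16), function(s) gauss_smooth(px, s))
  names(sm) <- c("s1", "s2", "s4", "s8", "s16")

  gradmag <- function(m) sqrt(central_diff_rows(m)^2 + central_diff_cols(m)^2)
  hess_eigs <- function(m) {
    hrr <- central_diff_rows(central_diff_rows(m))
    hcc <- central_diff_cols(central_diff_cols(m))
    hrc <- central_diff_cols(central_diff_rows(m))
    tr2 <- (hrr + hcc) / 2
    disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    list(max = tr2 + disc, min = tr2 - disc)
  }
  h2 <- hess_eigs(sm$s2); h4 <- hess_eigs(sm$s4)

  feats <- cbind(
    raw = as.vector(px),
    gauss_1 = as.vector(sm$s1), gauss_2 = as.vector(sm$s2),
    gauss_4 = as.vector(sm$s4), gauss_8 = as.vector(sm$s8),
    gauss_16 = as.vector(sm$s16),
    grad_1 = as.vector(gradmag(sm$s1)),
    grad_2 = as.vector(gradmag(sm$s2)),
    grad_4 = as.vector(gradmag(sm$s4)),
    dog_1_4 = as.vector(sm$s1 - sm$s4),
    dog_2_8 = as.vector(sm$s2 - sm$s8),
    hess_max_2 = as.vector(h2$max), hess_min_2 = as.vector(h2$min),
    hess_max_4 = as.vector(h4$max), hess_min_4 = as.vector(h4$min)
  )
  attr(feats, "feature_spec") <- data.frame(
    name = colnames(feats),
    sigma = c(0, 1, 2, 4, 8, 16, 1, 2, 4, NA, NA, 2, 2, 4, 4)
  )
  feats
}
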