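test_that("generation is bit-reproducible given the seed", {
  a <- generate_wing(small_wing_params(), seed = 2)
  b <- generate_wing(small_wing_params(), seed = 2)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$trichomes, b$truth$trichomes)
  c <- generate_wing(small_wing_params(), seed = 3)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("masks are disjoint, tile the image, and trichomes sit on intervein", {
  w <- cached("wing_small_noisy", generate_wing(small_wing_params(), seed = 4))
  t <- w$truth
  expect_true(all(t$vein_mask + t$intervein_mask + t$background_mask == 1L))
  expect_true(all(t$intervein_mask[cbind(t$trichomes$row + 1L,
                                         t$trichomes$col + 1L)]))
  expect_equal(sort(unique(t$region_ids[t$region_ids > 0])), 1:7)
  expect_true(all((t$region_ids > 0) == t$intervein_mask))
})

test_that("realized counts stay within the Poisson envelope of rate x area", {
  w <- cached("wing_small_noisy", generate_wing(small_wing_params(), seed = 4))
  t <- w$truth
  p <- t$params
  originals <- t$trichomes[!t$trichomes$duplicate, ]
  for (comp in list(setdiff(1:7, t$posterior_regions), t$posterior_regions)) {
    area <- sum(t$region_ids %in% comp)
    expected <- p$trichome_rate * area *
      if (all(comp %in% t$posterior_regions)) p$rate_ratio else 1
    got <- sum(originals$region %in% comp)
    expect_lt(abs(got - expected), 4 * sqrt(expected) + 1)
  }
})

test_that("non-duplicate trichomes respect the hard-core minimum spacing", {
  w <- cached("wing_small_noisy", generate_wing(small_wing_params(), seed = 4))
  tri <- w$truth$trichomes
  pts <- as.matrix(tri[!tri$duplicate, c("row", "col")])
  d2 <- as.matrix(dist(pts))^2
  diag(d2) <- Inf
  expect_gte(min(d2), w$truth$params$min_spacing^2)
})

test_that("clean rendering yields 100% recall at tolerance 10", {
  for (s in 1:2) {
    w <- generate_wing(small_wing_params(
      coincident_fraction = 0, small_faint_fraction = 0,
      noise_sd = 0, dirt_specks = 0), seed = s)
    ev <- evaluate_detection(find_maxima(w$image, 10), w$truth, radius = 2)
    expect_equal(ev$recall, 1.0)
  }
})

test_that("a coincident pair closer than the base diameter merges into one detection", {
  m <- matrix(222L, 41, 41)
  offs <- expand.grid(dr = -3:3, dc = -3:3)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 9, ]
  for (ctr in list(c(20, 18), c(20, 22))) {   # two bases 4 px apart
    m[cbind(ctr[1] + offs$dr + 1, ctr[2] + offs$dc + 1)] <- 60L
  }
  tp <- find_maxima(micrograph(m), 10)
  expect_equal(nrow(tp$points), 1L)
})

test_that("recall degrades monotonically in the failure-class fractions", {
  fracs <- c(0, 0.10)
  seeds <- 1:4
  recall <- array(NA_real_, dim = c(2, 2, length(seeds)))
  for (i in 1:2) for (j in 1:2) for (k in seq_along(seeds)) {
    w <- generate_wing(mid_wing_params(
      coincident_fraction = fracs[i], small_faint_fraction = fracs[j]),
      seed = seeds[k])
    ev <- evaluate_detection(find_maxima(w$image, 10), w$truth, radius = 4)
    recall[i, j, k] <- ev$recall
  }
  mr <- apply(recall, c(1, 2), mean)
  for (j in 1:2) expect_true(all(diff(mr[, j]) <= 0.002))
  for (i in 1:2) expect_true(all(diff(mr[i, ]) <= 0.002))
})

test_that("detection evaluation matches greedily within the radius", {
  truth <- data.frame(row = c(10, 20, 30), col = c(10, 20, 30))
  ev <- evaluate_detection(truth, truth, radius = 4)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
  ev2 <- evaluate_detection(truth[-2, ], truth, radius = 4)
  expect_equal(ev2$missed, 1L)
  # displacements inside vs outside the radius
  set.seed(19)
  shift_in <- truth; shift_in$col <- shift_in$col + 3
  expect_equal(evaluate_detection(shift_in, truth, radius = 4)$matched, 3L)
  shift_out <- truth; shift_out$col <- shift_out$col + 7
  expect_equal(evaluate_detection(shift_out, truth, radius = 4)$matched, 0L)
  expect_error(evaluate_detection(truth, truth, radius = 0), "radius")
})

test_that("impossible packing densities are rejected up front", {
  expect_error(generate_wing(small_wing_params(trichome_rate = 0.02,
                                               min_spacing = 10), seed = 1),
               "packing")
})

test_that("ground truth writes to plain-text files and squares avoid veins", {
  d <- withr::local_tempdir()
  w <- cached("wing_mid_noisy", generate_wing(mid_wing_params(), seed = 4))
  write_ground_truth(w$truth, d, stem = "w")
  expect_true(file.exists(file.path(d, "w_truth.csv")))
  expect_true(file.exists(file.path(d, "w_classes.png")))
  expect_true(file.exists(file.path(d, "w_params.json")))
  tab <- read.csv(file.path(d, "w_truth.csv"))
  expect_equal(nrow(tab), nrow(w$truth$trichomes))
  sqs <- select_intervein_squares(w$truth, side = 75, n = 5)
  expect_gte(length(sqs), 2L)
  for (roi in sqs) {
    block <- w$truth$intervein_mask[
      (roi$row_range[1]:roi$row_range[2]) + 1L,
      (roi$col_range[1]:roi$col_range[2]) + 1L]
    expect_true(all(block))
  }
  # pairwise non-overlap
  if (length(sqs) > 1) {
    for (i in 1:(length(sqs) - 1)) for (j in (i + 1):length(sqs)) {
      expect_true(max(abs(sqs[[i]]$center - sqs[[j]]$center)) >= 75)
    }
  }
})
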