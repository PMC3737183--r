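work_blank <- function(value = 0L) micrograph(matrix(value, 380, 512))

test_that("the feature stack has 15 features with the documented structure", {
  feats <- compute_features(work_blank(128L))
  expect_equal(ncol(feats), 15L)
  spec <- attr(feats, "feature_spec")
  expect_equal(nrow(spec), 15L)
  # constant image: all derivative-based features vanish, smoothers preserve
  expect_true(all(abs(feats[, c("grad_1", "grad_2", "grad_4",
                                "dog_1_4", "dog_2_8")]) < 1e-9))
  expect_true(all(abs(feats[, "gauss_8"] - 128) < 1e-9))
  expect_error(compute_features(micrograph(matrix(0L, 100, 100))),
               "working resolution")
})

test_that("a point impulse peaks at itself after Gaussian smoothing", {
  m <- matrix(0L, 380, 512); m[190, 256] <- 255L
  feats <- compute_features(micrograph(m))
  g1 <- matrix(feats[, "gauss_1"], 380, 512)
  expect_equal(which(g1 == max(g1)), which(m == 255L))
})

test_that("training is seeded-deterministic and reaches the accuracy floor", {
  wing <- cached("wing_full_42", generate_wing(wing_params(), seed = 42))
  lab <- ground_truth_labels(wing$truth, 200, seed = 42)
  m1 <- cached("model_42", train_classifier(wing$image, lab, 100, seed = 42))
  expect_gte(m1$train_acc, 0.95)
  m2 <- train_classifier(wing$image, lab, 100, seed = 42)
  probe <- cached("wing_full_5", generate_wing(wing_params(), seed = 5))
  s1 <- segment_wing(probe$image, m1)
  s2 <- segment_wing(probe$image, m2)
  expect_identical(s1$class_map, s2$class_map)
})

test_that("training demands 50 pixels of each of the three classes", {
  wing <- cached("wing_full_42", generate_wing(wing_params(), seed = 42))
  lab <- ground_truth_labels(wing$truth, 200, seed = 42)
  lab2 <- lab; lab2[lab2 == 3L] <- 0L
  expect_error(train_classifier(wing$image, lab2, 20, seed = 1), "background")
  lab3 <- lab
  sel <- which(lab3 == 1L)
  lab3[sel[-(1:20)]] <- 0L
  expect_error(train_classifier(wing$image, lab3, 20, seed = 1), "vein")
})

test_that("segmentation of a held-out wing recovers intervein tissue (IoU >= 0.8)", {
  wing <- cached("wing_full_42", generate_wing(wing_params(), seed = 42))
  model <- cached("model_42", train_classifier(
    wing$image, ground_truth_labels(wing$truth, 200, seed = 42), 100, seed = 42))
  held <- cached("wing_full_5", generate_wing(wing_params(), seed = 5))
  seg <- cached("seg_5", segment_wing(held$image, model))
  gt <- ground_truth_class_map(held$truth)
  expect_gte(iou(seg$class_map == 2L, gt == 2L), 0.80)
  # classifying the training image itself does at least as well
  seg_self <- segment_wing(wing$image, model)
  gt_self <- ground_truth_class_map(wing$truth)
  expect_gte(iou(seg_self$class_map == 2L, gt_self == 2L), 0.90)
})

test_that("an all-background probe is labeled almost entirely background", {
  wing <- cached("wing_full_42", generate_wing(wing_params(), seed = 42))
  model <- cached("model_42", train_classifier(
    wing$image, ground_truth_labels(wing$truth, 200, seed = 42), 100, seed = 42))
  set.seed(9)
  blank <- micrograph(matrix(pmax(0L, pmin(255L,
    235L + as.integer(round(rnorm(380 * 512, 0, 4))))), 380, 512))
  seg <- segment_wing(blank, model)
  expect_gte(mean(seg$class_map == 3L), 0.95)
})

test_that("particle analysis applies fill/min-area/border rules and area ordering", {
  cm <- matrix(1L, 380, 512)
  cm[50:120, 50:200] <- 2L       # large region with a hole
  cm[80:90, 100:110] <- 1L       # the hole
  cm[200:240, 50:100] <- 2L      # medium region
  cm[300:305, 400:420] <- 2L     # small region, 6x21 = 126 px < 200
  cm[1:60, 300:360] <- 2L        # border-touching region
  regs <- extract_intervein_regions(cm)
  expect_equal(length(regs), 2L)
  expect_equal(vapply(regs, function(r) sum(r$mask), numeric(1)),
               c(71 * 151, 41 * 51))  # hole filled; sorted by area
  expect_equal(regs[[1]]$region_id, 1L)
  # entirely-intervein map: the single component touches the border
  expect_error(extract_intervein_regions(matrix(2L, 380, 512)), "no intervein regions")
  # lone sub-threshold blob
  cm2 <- matrix(1L, 380, 512); cm2[100:109, 100:109] <- 2L
  expect_error(extract_intervein_regions(cm2), "no intervein regions")
})

test_that("particle analysis agrees with a brute-force region filter on random maps", {
  set.seed(17)
  for (i in 1:15) {
    base <- matrix(rnorm(60 * 80), 60, 80)
    sm <- wingtrich:::gauss_smooth(base, 3)
    cm <- matrix(1L, 60, 80)
    cm[sm > quantile(sm, 0.55)] <- 2L
    got <- tryCatch(extract_intervein_regions(cm, min_area_px = 30),
                    error = function(e) list())
    want <- oracle_region_masks(cm, min_area = 30)
    expect_equal(length(got), length(want))
    if (length(got)) {
      got_areas <- sort(vapply(got, function(r) sum(r$mask), numeric(1)))
      want_areas <- sort(vapply(want, sum, numeric(1)))
      expect_equal(got_areas, want_areas)
      # same pixel sets, matched by area rank
      for (r in got) {
        match_found <- any(vapply(want, function(w) identical(unname(which(w)),
                                                              unname(which(r$mask))),
                                  logical(1)))
        expect_true(match_found)
      }
    }
  }
})

test_that("ground-truth particle analysis recovers the generated region count", {
  held <- cached("wing_full_5", generate_wing(wing_params(), seed = 5))
  gt <- ground_truth_class_map(held$truth)
  regs <- extract_intervein_regions(gt, dim(held$image$pixels))
  expect_equal(length(regs), max(held$truth$region_ids))
})

test_that("intervein densities on a clean wing reproduce exact ground-truth counts", {
  wing <- cached("wing_clean_9",
                 generate_wing(wing_params(coincident_fraction = 0,
                                           small_faint_fraction = 0,
                                           noise_sd = 0, dirt_specks = 0),
                               seed = 9))
  gt <- ground_truth_class_map(wing$truth)
  regs <- extract_intervein_regions(gt, dim(wing$image$pixels))
  regs <- lapply(regs, function(r) intervein_density(wing$image, r, 10))
  total <- sum(vapply(regs, `[[`, numeric(1), "trichome_count"))
  expect_equal(total, nrow(wing$truth$trichomes))
  for (r in regs) expect_equal(r$density, r$trichome_count / r$area_px2)
  # counts over disjoint regions can never exceed the whole-image count
  expect_lte(total, nrow(find_maxima(wing$image, 10)$points))
})

test_that("a classifier survives a save/load round trip", {
  d <- withr::local_tempdir()
  wing <- cached("wing_full_42", generate_wing(wing_params(), seed = 42))
  model <- cached("model_42", train_classifier(
    wing$image, ground_truth_labels(wing$truth, 200, seed = 42), 100, seed = 42))
  p <- file.path(d, "model.rds")
  save_classifier(model, p)
  back <- load_classifier(p)
  held <- cached("wing_full_5", generate_wing(wing_params(), seed = 5))
  expect_identical(segment_wing(held$image, back)$class_map,
                   cached("seg_5", segment_wing(held$image, model))$class_map)
})
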