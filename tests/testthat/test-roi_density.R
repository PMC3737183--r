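test_that("square ROI geometry follows the centered-click rule", {
  roi <- square_roi(c(100, 100), 75, c(2080, 1544))
  expect_equal(roi$row_range, c(63, 137))
  expect_equal(roi$col_range, c(63, 137))
  expect_equal(roi$area_px2, 5625)
  expect_error(square_roi(c(0, 0), 75, c(2080, 1544)), "nearest valid center")
  one <- square_roi(c(50, 50), 1, c(100, 100))
  expect_equal(one$row_range, c(50, 50))
  expect_equal(one$area_px2, 1)
  # presets
  expect_equal(square_roi(c(300, 300), 150, c(1000, 1000))$area_px2, 22500)
})

test_that("shoelace polygon area matches closed forms and a Monte-Carlo oracle", {
  expect_equal(polygon_area(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))), 100)
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  # orientation independence
  expect_equal(polygon_area(rbind(c(0, 10), c(10, 10), c(10, 0), c(0, 0))), 100)
  set.seed(7)
  for (i in 1:12) {
    # star-shaped polygons are simple by construction
    k <- sample(5:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 3, 10)
    v <- cbind(10 + rad * cos(ang), 10 + rad * sin(ang))
    a <- polygon_area(v)
    ns <- 2e5
    px <- runif(ns, 0, 20); py <- runif(ns, 0, 20)
    inside <- wingtrich:::points_in_polygon(cbind(row = py, col = px), v)
    mc <- mean(inside) * 400
    expect_lt(abs(a - mc) / a, 0.012)
  }
})

test_that("degenerate polygons are rejected", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(polygon_area(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersecting")
})

test_that("polygon counting is boundary-inclusive and uses the even-odd rule", {
  m <- matrix(255L, 40, 40)
  # points at (10,10), (10,20), (25,25) (0-based)
  m[11, 11] <- 60L; m[11, 21] <- 60L; m[26, 26] <- 60L
  img <- micrograph(m)
  v <- rbind(c(5, 5), c(20, 5), c(20, 15), c(5, 15))  # (col,row) rect
  res <- count_in_polygon(img, v, 10)
  expect_equal(res$trichome_count, 2L)  # (10,10) interior, (10,20) on edge
  expect_equal(res$density, res$trichome_count / res$area_px2)
  empty <- count_in_polygon(img, rbind(c(30, 2), c(36, 2), c(36, 8), c(30, 8)), 10)
  expect_equal(empty$trichome_count, 0L)
  expect_equal(empty$density, 0)
  expect_error(count_in_polygon(img, rbind(c(-2, 5), c(20, 5), c(20, 15)), 10),
               "exits")
})

test_that("counts are additive over a partition when no point sits on the cut", {
  set.seed(12)
  m <- matrix(255L, 60, 60)
  pts <- cbind(sample(c(5:27, 33:55), 12), sample(5:55, 12))
  m[pts] <- 60L
  img <- micrograph(m)
  whole <- count_in_polygon(img, rbind(c(2, 2), c(57, 2), c(57, 57), c(2, 57)), 10)
  left <- count_in_polygon(img, rbind(c(2, 2), c(57, 2), c(57, 29.5), c(2, 29.5)), 10)
  right <- count_in_polygon(img, rbind(c(2, 29.5), c(57, 29.5), c(57, 57), c(2, 57)), 10)
  expect_equal(left$trichome_count + right$trichome_count, whole$trichome_count)
})

test_that("density times area reproduces the count exactly", {
  wing <- cached("wing_mid_noisy", generate_wing(mid_wing_params(), seed = 4))
  sq <- select_intervein_squares(wing$truth, side = 75, n = 2)
  for (roi in sq) {
    res <- count_in_square(wing$image, roi$center, roi$side)
    expect_equal(res$density * res$area_px2, as.numeric(res$trichome_count))
    expect_identical(res$density, res$trichome_count / res$area_px2)
  }
})

test_that("repeat runs return identical density results", {
  wing <- cached("wing_mid_noisy", generate_wing(mid_wing_params(), seed = 4))
  sq <- select_intervein_squares(wing$truth, side = 75, n = 1)[[1]]
  a <- count_in_square(wing$image, sq$center, 75)
  b <- count_in_square(wing$image, sq$center, 75)
  expect_identical(a$trichome_count, b$trichome_count)
  expect_identical(a$density, b$density)
})

test_that("density ratio behaves as a plain density quotient", {
  wing <- cached("wing_mid_noisy", generate_wing(mid_wing_params(), seed = 4))
  sq <- select_intervein_squares(wing$truth, side = 75, n = 1)[[1]]
  a <- count_in_square(wing$image, sq$center, 75)
  expect_equal(density_ratio(a, a), 1.0)
  zero <- a; zero$density <- 0
  expect_error(density_ratio(a, zero), "zero")
})

test_that("upsampling the render scales area but not counts", {
  wing <- cached("wing_clean_mid",
                 generate_wing(mid_wing_params(
                   coincident_fraction = 0, small_faint_fraction = 0,
                   noise_sd = 0, dirt_specks = 0), seed = 6))
  sq <- select_intervein_squares(wing$truth, side = 75, n = 1)[[1]]
  res1 <- count_in_square(wing$image, sq$center, 75)
  d <- dim(wing$image$pixels)
  up <- resize(wing$image, 2 * d[2], 2 * d[1])
  res2 <- count_in_square(up, 2 * sq$center, 150)
  # resampling shifts detected centroids by ~0.5 px, so a boundary-band
  # trichome may cross the square edge: counts agree to sampling tolerance,
  # areas exactly
  expect_lte(abs(res2$trichome_count - res1$trichome_count), 2)
  expect_equal(res2$area_px2, 4 * res1$area_px2)
  expect_lt(abs(res2$density * 4 - res1$density) / res1$density, 0.1)
})

test_that("the density log accumulates CSV rows with the documented header", {
  d <- withr::local_tempdir()
  wing <- cached("wing_mid_noisy", generate_wing(mid_wing_params(), seed = 4))
  sq <- select_intervein_squares(wing$truth, side = 75, n = 1)[[1]]
  res <- count_in_square(wing$image, sq$center, 75)
  p <- file.path(d, "log.csv")
  log_density(res, p, image = "w1", roi_id = "a")
  log_density(res, p, image = "w1", roi_id = "b")
  tab <- read.csv(p)
  expect_equal(names(tab), c("image", "roi_id", "area_px2", "count",
                             "density", "noise_tolerance"))
  expect_equal(nrow(tab), 2L)
})

test_that("ROI JSON round trip preserves squares and polygons", {
  d <- withr::local_tempdir()
  sq <- square_roi(c(100, 120), 75, c(500, 500))
  write_roi_json(sq, file.path(d, "sq.json"))
  back <- read_roi_json(file.path(d, "sq.json"), c(500, 500))
  expect_equal(back$center, sq$center)
  expect_equal(back$area_px2, sq$area_px2)
  pg <- polygon_roi(rbind(c(0, 0), c(10, 0), c(10, 10)))
  write_roi_json(pg, file.path(d, "pg.json"))
  back2 <- read_roi_json(file.path(d, "pg.json"), c(500, 500))
  expect_equal(back2$area_px2, pg$area_px2)
})
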