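make_px <- function(rgb) array(rgb, dim = c(1, 1, 3))

test_that("single pixels classify by box membership", {
  ts <- default_thresholds()
  blue <- classify_pixels(make_px(c(0, 0, 255)), ts)
  expect_equal(blue$counts$blue, 1L)
  expect_equal(blue$counts$total, 1L)
  expect_equal(blue$class_map[1, 1], 2L)

  white <- classify_pixels(make_px(c(255, 255, 255)), ts)
  expect_equal(white$counts$other, 1L)
  expect_equal(white$class_map[1, 1], 0L)
})

test_that("classification recovers exact generated counts at zero jitter", {
  sim <- make_stain_image(stain_image_spec(width = 100, height = 100,
                                           blue_fraction = 0.03,
                                           pink_fraction = 0.97,
                                           jitter_sd = 0, seed = 11))
  expect_equal(sim$counts$blue, 300L)
  expect_equal(sim$counts$pink, 9700L)
  cl <- classify_pixels(sim$image)
  expect_equal(cl$counts$blue, 300L)
  expect_equal(cl$counts$pink, 9700L)
  expect_equal(cl$counts$other, 0L)
  expect_equal(cl$counts$total, 10000L)
})

test_that("input contract: non-8-bit images and mismatched masks rejected", {
  expect_error(classify_pixels(array(0.5, c(2, 2, 3))), "8-bit")
  expect_error(classify_pixels(matrix(1, 2, 2)), "RGB array")
  img <- random_rgb(4, 4)
  expect_error(classify_pixels(img, tissue_mask = matrix(TRUE, 3, 4)),
               "dimensions")
})

test_that("tissue mask removes pixels from map and counts", {
  img <- random_rgb(8, 8)
  mask <- matrix(TRUE, 8, 8); mask[1:2, ] <- FALSE
  cl <- classify_pixels(img, tissue_mask = mask)
  expect_equal(cl$counts$total, sum(mask))
  expect_true(all(is.na(cl$class_map[1:2, ])))
})

test_that("conservation: blue + pink + other == total on random images", {
  set.seed(42)
  for (i in 1:10) {
    cl <- classify_pixels(random_rgb(16, 16))
    with(cl$counts, expect_identical(blue + pink + other, total))
    expect_identical(cl$counts$total, 256L)
  }
})

test_that("vectorized classifier equals the naive per-pixel loop", {
  set.seed(7)
  ts <- default_thresholds()
  for (i in 1:10) {
    img <- random_rgb(32, 32)
    fast <- classify_pixels(img, ts)
    slow <- naive_classify_counts(img, ts)
    expect_equal(fast$counts$blue, unname(slow$counts["blue"]))
    expect_equal(fast$counts$pink, unname(slow$counts["pink"]))
    expect_equal(fast$counts$other, unname(slow$counts["other"]))
    expect_identical(fast$class_map, slow$map)
  }
})

test_that("enlarging the blue box never decreases the blue count", {
  set.seed(13)
  img <- random_rgb(32, 32)
  base <- rgb_threshold_set(c(40, 120, 40, 120, 140, 220),
                            c(150, 255, 60, 210, 100, 220))
  n0 <- classify_pixels(img, base)$counts$blue
  for (pad in c(10, 30, 60)) {
    bb <- base$blue_box
    bb["low", ] <- pmax(0, bb["low", ] - pad)
    bb["high", ] <- pmin(255, bb["high", ] + pad)
    bigger <- rgb_threshold_set(bb, base$pink_box)
    n1 <- classify_pixels(img, bigger)$counts$blue
    expect_gte(n1, n0)
    n0 <- n1
  }
})

test_that("pixels inside both boxes are assigned blue", {
  overlap <- rgb_threshold_set(c(0, 255, 0, 255, 0, 255),
                               c(0, 255, 0, 255, 0, 255))
  cl <- classify_pixels(make_px(c(100, 100, 100)), overlap)
  expect_equal(cl$counts$blue, 1L)
  expect_equal(cl$counts$pink, 0L)
})

test_that("blue/pink ratio follows the count formula and rejects empty denominators", {
  expect_equal(blue_pink_ratio(pixel_class_counts(0, 5000, 5000))$ratio, 0)
  expect_equal(blue_pink_ratio(pixel_class_counts(300, 9700, 0))$ratio, 0.03)
  expect_error(blue_pink_ratio(pixel_class_counts(0, 0, 100)),
               "undefined blue/pink ratio")
})

test_that("estimated ratio tracks ground truth within 0.005 under in-box jitter", {
  fractions <- seq(0, 0.05, length.out = 10)
  for (i in seq_along(fractions)) {
    sim <- make_stain_image(stain_image_spec(
      width = 60, height = 60, blue_fraction = fractions[i],
      pink_fraction = 0.9, jitter_sd = 8, seed = 100 + i))
    truth <- sim$counts$blue / (sim$counts$blue + sim$counts$pink)
    cl <- classify_pixels(sim$image)
    est <- blue_pink_ratio(cl)$ratio
    expect_lte(abs(est - truth), 0.005)
  }
})

test_that("calibration finds a separating box and is deterministic", {
  grid <- list(low = c(0, 64, 128, 192), high = c(63, 127, 191, 255))
  set.seed(5)
  patches <- list(model_patch(150, c(60, 70, 180), 8, "blue"),
                  model_patch(150, c(230, 150, 180), 8, "pink"),
                  model_patch(150, c(245, 245, 245), 3, "other"))
  ts1 <- calibrate_thresholds(patches, grid)
  ts2 <- calibrate_thresholds(patches, grid)
  expect_identical(ts1$blue_box, ts2$blue_box)
  expect_identical(ts1$pink_box, ts2$pink_box)
  expect_identical(ts1$provenance, "calibrated")

  # perfect separation on the training patches
  train <- do.call(rbind, lapply(patches, function(p) p$pixels))
  lab <- rep(c("blue", "pink", "other"),
             vapply(patches, function(p) nrow(p$pixels), integer(1)))
  img <- array(train, dim = c(nrow(train), 1, 3))
  cl <- classify_pixels(img, ts1)
  pred <- c("other", "pink", "blue")[cl$class_map + 1L]
  expect_identical(unname(pred), lab)
})

test_that("calibrated thresholds classify held-out synthetic pixels at >= 99% accuracy", {
  grid <- list(low = c(0, 64, 128, 192), high = c(63, 127, 191, 255))
  set.seed(21)
  train <- list(model_patch(200, c(60, 70, 180), 8, "blue"),
                model_patch(200, c(230, 150, 180), 8, "pink"),
                model_patch(200, c(245, 245, 245), 3, "other"))
  ts <- calibrate_thresholds(train, grid)
  held <- list(model_patch(500, c(60, 70, 180), 8, "blue"),
               model_patch(500, c(230, 150, 180), 8, "pink"),
               model_patch(500, c(245, 245, 245), 3, "other"))
  px <- do.call(rbind, lapply(held, function(p) p$pixels))
  lab <- rep(c("blue", "pink", "other"), each = 500)
  cl <- classify_pixels(array(px, dim = c(nrow(px), 1, 3)), ts)
  pred <- c("other", "pink", "blue")[cl$class_map + 1L]
  expect_gte(mean(pred == lab), 0.99)
})

test_that("calibration contracts: missing classes and degenerate grids error", {
  p_blue <- model_patch(10, c(60, 70, 180), 0, "blue")
  expect_error(calibrate_thresholds(list(p_blue)), "'pink' patch")
  p_pink <- model_patch(10, c(230, 150, 180), 0, "pink")
  expect_error(calibrate_thresholds(list(p_blue, p_pink),
                                    grid = list(low = numeric(),
                                                high = numeric())),
               "degenerate")
  bad <- p_blue; bad$label <- "teal"
  expect_error(calibrate_thresholds(list(bad, p_pink)), "labels")
})

test_that("stain_batch writes one consistent row per image", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    sim <- make_stain_image(stain_image_spec(width = 20, height = 20,
                                             blue_fraction = 0.02 * i,
                                             pink_fraction = 0.9,
                                             seed = i))
    write_image(sim$image, file.path(dir, sprintf("img%d.png", i)))
  }
  res <- stain_batch(list.files(dir, full.names = TRUE))
  expect_equal(nrow(res), 3L)
  expect_equal(res$blue + res$pink + res$other, res$total)
  expect_equal(res$ratio, res$blue / (res$blue + res$pink))
  expect_true(all(res$thresholds == "phhquant-default"))
})
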