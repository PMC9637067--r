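# adaptive thresholding, histogram criteria, parameter search

test_that("adaptive_binarize follows the threshold formula", {
  # constant field: src = local mean > local mean - C, so all background
  const <- matrix(100L, 30, 30)
  m <- adaptive_binarize(const, threshold_params(7, 10))
  expect_true(all(m == 0L))

  # a dark pixel in a bright field is foreground for small C
  g <- matrix(200L, 21, 21); g[11, 11] <- 100L
  m <- adaptive_binarize(g, threshold_params(5, 4))
  expect_equal(m[11, 11], 255L)
  expect_true(all(m[-11, ] == 0L))

  expect_cfu_error(threshold_params(6, 4), "cfuseg_param_error")
  expect_true(all(m %in% c(0L, 255L)))
})

test_that("adaptive_binarize equals the sliding-window oracle exactly", {
  set.seed(3)
  for (rep in 1:5) {
    g <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
    expect_identical(adaptive_binarize(g, threshold_params(5, 4)),
                     oracle_adaptive_binarize(g, 5, 4))
  }
})

test_that("foreground_histogram tallies original gray values", {
  g <- matrix(0L, 20, 20)
  m <- matrix(0L, 20, 20)
  expect_equal(foreground_histogram(g, m), rep(0L, 256))

  g[1:5, 1:10] <- 80L
  m[1:5, 1:10] <- 255L
  h <- foreground_histogram(g, m)
  expect_equal(h[81], 50L)
  expect_equal(sum(h), 50L)

  set.seed(8)
  g2 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  m2 <- matrix(sample(c(0L, 255L), 400, replace = TRUE), 20, 20)
  h2 <- foreground_histogram(g2, m2)
  ref <- integer(256)
  for (i in seq_along(g2)) if (m2[i] == 255L) ref[g2[i] + 1L] <- ref[g2[i] + 1L] + 1L
  expect_equal(h2, ref)
  expect_cfu_error(foreground_histogram(g2, m2[1:10, ]), "cfuseg_param_error")
})

test_that("smooth_savgol preserves low-degree polynomials and matches the fit oracle", {
  x <- 0:255
  quad <- 3 + 0.2 * x - 0.001 * x^2
  expect_equal(smooth_savgol(quad, 11, 3), quad, tolerance = 1e-8)
  expect_equal(smooth_savgol(rep(5, 256), 11, 3), rep(5, 256), tolerance = 1e-10)

  set.seed(12)
  y <- runif(256, 0, 100)
  expect_equal(smooth_savgol(y, 11, 3), oracle_savgol(y, 11, 3), tolerance = 1e-8)

  expect_cfu_error(smooth_savgol(y, 10, 3), "cfuseg_param_error")
  expect_cfu_error(smooth_savgol(y, 11, 11), "cfuseg_param_error")
})

test_that("find_peak_range extends a strictly decreasing run", {
  expect_equal(unname(find_peak_range(c(1, 2, 5, 4, 3, 4, 1))), c(0L, 4L))
  dec <- seq(100, 10, length.out = 12)
  expect_equal(unname(find_peak_range(dec)), c(0L, 11L))
  single <- rep(0, 256); single[129] <- 7
  expect_equal(unname(find_peak_range(single)), c(128L, 128L))
  expect_cfu_error(find_peak_range(rep(0, 256)), "cfuseg_nopeak_error")
})

test_that("assess_binarization applies the three histogram criteria", {
  set.seed(21)
  H <- 120; W <- 120
  g <- matrix(200L, H, W)
  pop1 <- disk_mask(H, W, 40, 60, 18)
  g[pop1] <- as.integer(round(rnorm(sum(pop1), 90, 6)))
  img <- gray_plate(g)
  proto <- extract_prototype(disk_mask(H, W, 40, 60, 10), img, "white")

  m1 <- matrix(0L, H, W); m1[pop1] <- 255L
  a1 <- assess_binarization(g, m1, proto)
  expect_true(a1$unimodal)
  expect_true(a1$contains_prototype_gray)
  expect_true(a1$valid)
  expect_lt(abs(a1$area_under_peak - sum(pop1)) / sum(pop1), 0.2)

  # second well-separated population breaks unimodality
  pop2 <- disk_mask(H, W, 85, 60, 18)
  g2 <- g; g2[pop2] <- as.integer(round(rnorm(sum(pop2), 170, 6)))
  m2 <- m1; m2[pop2] <- 255L
  a2 <- assess_binarization(g2, m2, proto)
  expect_false(a2$unimodal)
  expect_false(a2$valid)

  # prototype gray outside the peak: area left uncomputed
  g3 <- g; g3[pop1] <- as.integer(round(rnorm(sum(pop1), 160, 6)))
  a3 <- assess_binarization(g3, m1, proto)
  expect_false(a3$contains_prototype_gray)
  expect_true(is.na(a3$area_under_peak))
  expect_false(a3$valid)
})

test_that("area under the peak never exceeds the foreground count (5% slack)", {
  set.seed(31)
  for (rep in 1:5) {
    g <- matrix(as.integer(pmin(pmax(round(rnorm(2500, 120, 25)), 0), 255)), 50, 50)
    m <- matrix(sample(c(0L, 255L), 2500, replace = TRUE, prob = c(.3, .7)), 50, 50)
    h <- foreground_histogram(g, m)
    sm <- pmax(smooth_savgol(h, 11, 3), 0)
    pk <- find_peak_range(sm, eps = 0.02 * max(sm))
    area <- sum(sm[(pk[1] + 1):(pk[2] + 1)])
    expect_gte(area, 0)
    expect_lte(area, 1.05 * sum(m == 255L))
  }
})

test_that("search_threshold_params is deterministic and finds a good mask", {
  spec <- plate_spec(counts = c(white = 40L), width = 500L, height = 500L,
                     dish_r = 220, seed = 9L)
  gen <- generate_plate(spec)
  img <- denoise_median(gen$image, 3)
  roi <- detect_plate_roi(img)
  seeds <- center_seed(gen$truth, "white", 250, 250)
  proto <- build_prototypes(img, roi, seeds)$white

  r1 <- search_threshold_params(img$gray, proto, restrict = roi$mask)
  r2 <- search_threshold_params(img$gray, proto, restrict = roi$mask)
  expect_identical(r1$params, r2$params)

  # mask quality against generator ground truth
  truth_fg <- matrix(FALSE, 500, 500)
  for (i in seq_len(nrow(gen$truth)))
    truth_fg <- truth_fg | disk_mask(500, 500, gen$truth$x[i], gen$truth$y[i],
                                     gen$truth$r[i])
  got_fg <- r1$mask == 255L
  expect_gte(sum(got_fg & truth_fg) / sum(truth_fg), 0.80)
  expect_lt(sum(got_fg & !truth_fg) / sum(!truth_fg & roi$mask), 0.05)

  # enlarging the C grid can never reduce the selected area
  r3 <- search_threshold_params(img$gray, proto, restrict = roi$mask,
                                config = list(c_grid = seq(1, 45, 2)))
  expect_gte(r3$assessment$area_under_peak, r1$assessment$area_under_peak)
})

test_that("search fails informatively on a blank dish", {
  spec <- plate_spec(counts = c(white = 10L), width = 400L, height = 400L,
                     dish_r = 180, seed = 10L)
  gen <- generate_plate(spec)
  img <- denoise_median(gen$image, 3)
  roi <- detect_plate_roi(img)
  proto <- build_prototypes(img, roi, center_seed(gen$truth, "white", 200, 200))$white
  # texture-free wall: on a truly featureless dish nothing can satisfy
  # unimodality around the prototype gray (a mottled wall, by contrast, is
  # genuine dark foreground and is rejected later by pruning, not here)
  blank <- generate_plate(plate_spec(counts = c(white = 0L), width = 400L,
                                     height = 400L, dish_r = 180,
                                     ring_texture_sd = 0, seed = 10L))
  blank_img <- denoise_median(blank$image, 3)
  expect_cfu_error(
    search_threshold_params(blank_img$gray, proto,
                            restrict = detect_plate_roi(blank_img)$mask),
    "cfuseg_search_error")
})

test_that("selected s scales with the image (one grid step slack)", {
  spec <- plate_spec(counts = c(white = 30L), width = 600L, height = 600L,
                     dish_r = 270, radius_mean = 12, radius_sd = 1, seed = 14L)
  gen <- generate_plate(spec)
  img1 <- denoise_median(gen$image, 3)
  roi1 <- detect_plate_roi(img1)
  seed1 <- center_seed(gen$truth, "white", 300, 300)
  p1 <- build_prototypes(img1, roi1, seed1)$white
  s_full <- search_threshold_params(img1$gray, p1, restrict = roi1$mask)$params$s

  half <- degrade(gen$image, 0.5, truth = gen$truth)
  img2 <- denoise_median(half$image, 3)
  roi2 <- detect_plate_roi(img2)
  seed2 <- seed1; seed2$x <- round(seed2$x / 2); seed2$y <- round(seed2$y / 2)
  p2 <- build_prototypes(img2, roi2, seed2)$white
  s_half <- search_threshold_params(img2$gray, p2, restrict = roi2$mask)$params$s

  step_half <- 2 * max(2, (p2$bbox_w %/% 4))
  expect_lte(abs(s_half - s_full / 2), step_half + 1)
})

test_that("combine_color_masks is a pixelwise OR", {
  a <- matrix(0L, 10, 10); a[2, 2] <- 255L
  b <- matrix(0L, 10, 10); b[5, 7] <- 255L
  empty <- matrix(0L, 10, 10)
  expect_equal(combine_color_masks(list(a, empty)), a)
  expect_equal(combine_color_masks(list(a, b)), combine_color_masks(list(b, a)))
  expect_equal(combine_color_masks(list(a, a)), a)
  expect_cfu_error(combine_color_masks(list(a, matrix(0L, 5, 5))),
                   "cfuseg_param_error")
})
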