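# local-minima markers, marker watershed, statistical pruning

# two radial pits of given depth in a flat field
two_pit_gray <- function(H = 60, W = 90, c1 = c(25, 30), c2 = c(60, 30),
                         r = 14, depth = 50, base = 200) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  g <- matrix(base, H, W)
  for (cc in list(c1, c2)) {
    d <- sqrt((xs - cc[1])^2 + (ys - cc[2])^2)
    pit <- base - depth * exp(-(d / (r / 2))^2)
    g <- pmin(g, pit)
  }
  matrix(as.integer(round(g)), H, W)
}

test_that("detect_local_minima finds pits above the noise tolerance", {
  g <- two_pit_gray(depth = 50)
  region <- matrix(TRUE, nrow(g), ncol(g))
  mk <- detect_local_minima(g, region, 10)
  expect_equal(nrow(mk$points), 2L)
  d1 <- min(sqrt((mk$points[, 1] - 25)^2 + (mk$points[, 2] - 30)^2))
  d2 <- min(sqrt((mk$points[, 1] - 60)^2 + (mk$points[, 2] - 30)^2))
  expect_lte(d1, 2); expect_lte(d2, 2)

  # constant region: nothing prominent
  expect_equal(nrow(detect_local_minima(matrix(100L, 20, 20),
                                        matrix(TRUE, 20, 20), 10)$points), 0L)

  # pit shallower than the tolerance is not detected
  g5 <- two_pit_gray(depth = 5)
  expect_equal(nrow(detect_local_minima(g5, region, 10)$points), 0L)

  expect_cfu_error(detect_local_minima(g, matrix(FALSE, 60, 90), 10),
                   "cfuseg_param_error")
  expect_cfu_error(detect_local_minima(g, region, 0), "cfuseg_param_error")
})

test_that("marker count is monotonically non-increasing in tolerance", {
  set.seed(19)
  g <- matrix(as.integer(pmin(pmax(round(rnorm(48 * 48, 150, 30)), 0), 255)),
              48, 48)
  g <- denoise_median(g, 3)
  region <- matrix(TRUE, 48, 48)
  counts <- vapply(c(2, 5, 10, 20, 40),
                   function(tol) nrow(detect_local_minima(g, region, tol)$points),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detect_local_minima agrees with the exhaustive prominence oracle", {
  set.seed(23)
  for (rep in 1:6) {
    H <- sample(20:40, 1); W <- sample(20:40, 1)
    g <- matrix(as.integer(sample(0:60, H * W, replace = TRUE)), H, W)
    region <- disk_mask(H, W, W / 2, H / 2, min(H, W) / 2 - 1)
    tol <- sample(c(5, 10, 15), 1)
    got <- detect_local_minima(g, region, tol)$points
    want <- oracle_prominence_markers(255 - g, region, tol)
    expect_equal(unname(got), unname(want))
  }
})

test_that("watershed splits an overlapping pair along the relief", {
  g <- two_pit_gray(c1 = c(35, 30), c2 = c(55, 30), r = 16, depth = 60)
  region <- g < 195
  mk <- detect_local_minima(g, region, 15)
  expect_equal(nrow(mk$points), 2L)
  segs <- watershed_separate(region, mk, g)
  expect_length(segs, 2L)
  # each segment contains its marker and they are pairwise disjoint
  H <- nrow(g)
  for (i in 1:2) {
    lin <- mk$points[i, 1] * H + mk$points[i, 2] + 1
    expect_true(any(vapply(segs, function(s) lin %in% s$contour$pixel_idx,
                           logical(1))))
  }
  expect_length(intersect(segs[[1]]$contour$pixel_idx,
                          segs[[2]]$contour$pixel_idx), 0L)
  # the two segments partition the region
  expect_equal(sort(c(segs[[1]]$contour$pixel_idx, segs[[2]]$contour$pixel_idx)),
               which(region))
  # areas near-equal for a symmetric pair (within 15%)
  a <- vapply(segs, function(s) s$contour$n_pixels, integer(1))
  expect_lt(abs(a[1] - a[2]) / mean(a), 0.15)
})

test_that("zero markers return the region unsplit and flagged", {
  region <- disk_mask(40, 40, 20, 20, 10)
  mk <- detect_local_minima(matrix(100L, 40, 40), region, 10)
  segs <- watershed_separate(region, mk, matrix(100L, 40, 40))
  expect_length(segs, 1L)
  expect_true(segs[[1]]$unverified)
  expect_equal(sort(segs[[1]]$contour$pixel_idx), which(region))
})

test_that("prune_segments keeps population-typical segments and drops artifacts", {
  img <- gray_plate(matrix(100L, 200, 200))
  stats <- structure(list(
    members = 1:5, cluster = 1L, color_label = "white",
    mean = list(area = 320, circularity = 0.9, inertia = 0.95, mean_hue = 0),
    sd = list(area = 40, circularity = 0.03, inertia = 0.03, mean_hue = 3)
  ), class = "single_colony_stats")

  seg_from_mask <- function(mask) {
    lab <- cfuseg:::.label_components_cpp(mask, 8L)
    list(contour = cfuseg:::contour_from_label(lab, 1L, which(mask)),
         unverified = FALSE)
  }
  disk <- seg_from_mask(disk_mask(200, 200, 50, 50, 10))
  # thin arc: a 3-px-wide ring sector
  xs <- matrix(rep(0:199, each = 200), 200, 200)
  ys <- matrix(rep(0:199, 200), 200, 200)
  d <- sqrt((xs - 100)^2 + (ys - 180)^2)
  arc <- seg_from_mask(d >= 60 & d <= 63 & ys < 150 & xs > 100)

  kept <- prune_segments(list(disk, arc), list(stats), img)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$provenance, "watershed")
  expect_equal(kept[[1]]$color_label, "white")

  # correct shape but hue 180 degrees away: rejected
  img2 <- hsv_patch_image(200, 200, disk_mask(200, 200, 50, 50, 10),
                          hue = 240, sat = 0.8, val = 120)
  kept2 <- prune_segments(list(disk), list(stats), img2)
  expect_length(kept2, 0L)
})
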