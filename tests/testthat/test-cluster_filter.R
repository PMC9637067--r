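# contour extraction, feature measurement, DBSCAN, single-colony filtering

test_that("extract_contours finds one outer contour per component", {
  m <- matrix(0L, 100, 100)
  m[disk_mask(100, 100, 20, 20, 8)] <- 255L
  m[disk_mask(100, 100, 60, 30, 10)] <- 255L
  m[disk_mask(100, 100, 40, 75, 6)] <- 255L
  expect_length(extract_contours(m), 3L)
  expect_length(extract_contours(matrix(0L, 50, 50)), 0L)

  # disk with interior hole: outer boundary only
  h <- matrix(0L, 60, 60)
  h[disk_mask(60, 60, 30, 30, 15) & !disk_mask(60, 60, 30, 30, 5)] <- 255L
  cont <- extract_contours(h)
  expect_length(cont, 1L)
  f <- compute_features(cont[[1]], gray_plate(matrix(0L, 60, 60)))
  expect_lt(abs(f$area - pi * 15^2) / (pi * 15^2), 0.1) # outer polygon

  # dust below 4 px discarded
  d <- matrix(0L, 20, 20); d[3, 3] <- 255L; d[10, 10:11] <- 255L
  expect_length(extract_contours(d), 0L)
})

test_that("a perfect square has circularity pi/4 exactly", {
  m <- matrix(0L, 40, 40)
  m[10:29, 10:29] <- 255L
  f <- compute_features(extract_contours(m)[[1]], gray_plate(matrix(0L, 40, 40)))
  expect_equal(f$circularity, pi / 4, tolerance = 1e-12)
})

test_that("circle and ellipse fixtures match analytic shape features", {
  m <- matrix(0L, 100, 100)
  m[disk_mask(100, 100, 50, 50, 30)] <- 255L
  img <- gray_plate(matrix(0L, 100, 100))
  f <- compute_features(extract_contours(m)[[1]], img)
  expect_gte(f$circularity, 0.85); expect_lte(f$circularity, 1.05)
  expect_gte(f$inertia, 0.95)
  expect_gte(f$area_ratio, 0.9)

  # 2:1 axis-ratio ellipse -> inertia 0.5 +- 0.05
  xs <- matrix(rep(0:99, each = 100), 100, 100)
  ys <- matrix(rep(0:99, 100), 100, 100)
  e <- matrix(0L, 100, 100)
  e[((xs - 50) / 40)^2 + ((ys - 50) / 20)^2 <= 1] <- 255L
  fe <- compute_features(extract_contours(e)[[1]], img)
  expect_lt(abs(fe$inertia - 0.5), 0.05)

  # degenerate contour: < 5 boundary points
  t <- matrix(0L, 20, 20); t[5, 5:8] <- 255L
  expect_cfu_error(compute_features(extract_contours(t)[[1]], img),
                   "cfuseg_degenerate_contour")
})

test_that("features are rotation invariant within 5%", {
  img <- gray_plate(matrix(0L, 120, 120))
  xs <- matrix(rep(0:119, each = 120), 120, 120)
  ys <- matrix(rep(0:119, 120), 120, 120)
  feats <- lapply(c(0, pi / 6, pi / 3), function(th) {
    xr <- (xs - 60) * cos(th) + (ys - 60) * sin(th)
    yr <- -(xs - 60) * sin(th) + (ys - 60) * cos(th)
    m <- matrix(0L, 120, 120)
    m[(xr / 36)^2 + (yr / 18)^2 <= 1] <- 255L
    compute_features(extract_contours(m)[[1]], img)
  })
  for (f in c("circularity", "inertia", "area"))
    for (i in 2:3)
      expect_lt(abs(feats[[i]][[f]] - feats[[1]][[f]]) / feats[[1]][[f]], 0.05)
})

test_that("estimate_eps: knee, degenerate fallback, and guards", {
  # collinear equal spacing, k = 1: all k-distances equal -> fallback
  X <- cbind(0:9, 0)
  expect_equal(estimate_eps(X, 1), 1)
  expect_cfu_error(estimate_eps(X[1:3, ], 3), "cfuseg_param_error")

  # two tight clusters far apart: eps between the two distance scales
  set.seed(5)
  X2 <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
              matrix(rnorm(40, 10, 0.1), ncol = 2))
  eps <- estimate_eps(X2, 3)
  expect_gt(eps, 0.01)
  expect_lt(eps, 10)
})

test_that("cluster_contours agrees with the density-reachability oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(2 * n, sd = 3), ncol = 2) +
      matrix(rnorm(2 * n, mean = sample(0:12, 1)), ncol = 2)
    eps <- runif(1, 0.5, 3)
    minPts <- sample(2:6, 1)
    got <- cluster_contours(X, eps, minPts)$labels
    expect_identical(got, oracle_dbscan(X, eps, minPts))
  }
})

test_that("cluster_contours handles edge geometries", {
  X <- matrix(1, 10, 2) # identical points
  expect_equal(unique(cluster_contours(X, 0.5, 3)$labels), 1L)

  # two clear groups plus one isolated point
  X2 <- rbind(matrix(rnorm(20, 0, 0.2), ncol = 2),
              matrix(rnorm(20, 8, 0.2), ncol = 2),
              c(50, 50))
  lab <- cluster_contours(X2, 1, 3)$labels
  expect_equal(length(setdiff(unique(lab), -1L)), 2L)
  expect_equal(lab[21], -1L)
  expect_cfu_error(cluster_contours(X2, -1, 3), "cfuseg_param_error")
  expect_cfu_error(cluster_contours(X2, 1, 1), "cfuseg_param_error")
})

# shared two-population contour fixture: 12 single disks + 4 merged doubles
cluster_fixture <- function() {
  set.seed(33)
  H <- 300; W <- 300
  m <- matrix(0L, H, W)
  centers <- expand.grid(x = seq(30, 270, 60), y = seq(30, 150, 60))[1:12, ]
  for (i in 1:12) m[disk_mask(H, W, centers$x[i], centers$y[i], 11)] <- 255L
  for (i in 1:4) {
    cx <- 40 + (i - 1) * 65
    m[disk_mask(H, W, cx, 230, 11) | disk_mask(H, W, cx + 15, 230, 11)] <- 255L
  }
  img <- gray_plate(matrix(100L, H, W))
  conts <- extract_contours(m)
  list(img = img, contours = conts,
       features = contour_features(conts, img),
       first_single = which.min(abs(vapply(conts, function(cc)
         mean((cc$pixel_idx - 1) %/% H), numeric(1)) - 30)))
}

test_that("single-colony cluster selection follows prototype membership", {
  fx <- cluster_fixture()
  std <- standardize_features(fx$features)
  model <- cluster_contours(std$X, estimate_eps(std$X, 3), 3)
  st <- select_single_colony_cluster(model, std, fx$features,
                                     fx$first_single, "white")
  expect_true(fx$first_single %in% st$members)
  # every member of the selected cluster is a single disk (area ~ 350)
  expect_true(all(fx$features$area[st$members] < 500))
  expect_equal(length(st$members), 12L)
})

test_that("noise prototypes fall back to the nearest cluster with a warning", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2), c(3, 3))
  model <- cluster_contours(X, 0.8, 4)
  expect_equal(model$labels[21], -1L)
  feats <- data.frame(area = X[, 1], circularity = X[, 2], inertia = 1,
                      mean_hue = 0, area_ratio = 1, degenerate = FALSE)
  std <- list(X = X, rows = 1:21)
  expect_warning(
    st <- select_single_colony_cluster(model, std, feats, 21L, "white"),
    "noise")
  expect_equal(st$cluster, 1L)
})

test_that("filter_singles partitions contours by the strict cut-offs", {
  fx <- cluster_fixture()
  std <- standardize_features(fx$features)
  model <- cluster_contours(std$X, estimate_eps(std$X, 3), 3)
  st <- select_single_colony_cluster(model, std, fx$features,
                                     fx$first_single, "white")
  proto <- list(area = fx$features$area[fx$first_single],
                mean_hue = fx$features$mean_hue[fx$first_single])
  fs <- filter_singles(st, fx$features, proto)
  # partition invariant
  expect_setequal(c(fs$accepted, fs$unresolved), seq_len(nrow(fx$features)))
  expect_length(intersect(fs$accepted, fs$unresolved), 0L)
  # the contour identical to the prototype is accepted
  expect_true(fx$first_single %in% fs$accepted)
  # merged doubles (area ~2x, lobed outline) are not accepted singles
  doubles <- which(fx$features$area > 1.7 * proto$area)
  expect_true(all(doubles %in% fs$unresolved))
})

test_that("circularity of simple polygons stays below 1.1 on fixtures", {
  fx <- cluster_fixture()
  expect_true(all(fx$features$circularity <= 1.1))
})
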