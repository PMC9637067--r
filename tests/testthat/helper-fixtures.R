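# Shared fixture builders. All fixtures are generated in code; tests fix
# seeds locally so the suite is deterministic.

# gray matrix -> plate_image with three identical channels
gray_plate <- function(gray) {
  arr <- array(0, c(nrow(gray), ncol(gray), 3))
  arr[, , 1] <- gray; arr[, , 2] <- gray; arr[, , 3] <- gray
  plate_image(arr)
}

# H x W logical disk mask
disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# flat dark disk(s) on a bright field, as a plate_image
disks_image <- function(H, W, centers, r, fg = 80, bg = 200) {
  g <- matrix(bg, H, W)
  for (i in seq_len(nrow(centers)))
    g[disk_mask(H, W, centers[i, 1], centers[i, 2], r)] <- fg
  gray_plate(g)
}

# solid-color plate_image from an HSV spec over a mask
hsv_patch_image <- function(H, W, mask, hue, sat, val, bg = 200) {
  hp <- (hue %% 360) / 60
  C <- val * sat
  X <- C * (1 - abs(hp %% 2 - 1))
  m <- val - C
  base <- switch(floor(hp) %% 6 + 1,
                 c(C, X, 0), c(X, C, 0), c(0, C, X),
                 c(0, X, C), c(X, 0, C), c(C, 0, X)) + m
  arr <- array(bg, c(H, W, 3))
  for (ch in 1:3) {
    plane <- arr[, , ch]
    plane[mask] <- base[ch]
    arr[, , ch] <- plane
  }
  plate_image(arr)
}

# nearest ground-truth seed for a label: the colony closest to the dish
# center (mirrors how a user would click a clean central colony)
center_seed <- function(truth, label, cx, cy) {
  t <- truth[truth$label == label, ]
  i <- which.min((t$x - cx)^2 + (t$y - cy)^2)
  data.frame(x = round(t$x[i]), y = round(t$y[i]), label = label,
             stringsAsFactors = FALSE)
}

# greedy one-to-one matching of detections to ground truth by centroid;
# returns logical per-truth-row matched + count of unmatched detections
match_detections <- function(detections, truth, slack = 2) {
  dx <- vapply(detections, function(d) d$centroid[1], numeric(1))
  dy <- vapply(detections, function(d) d$centroid[2], numeric(1))
  used <- rep(FALSE, length(dx))
  matched <- rep(FALSE, nrow(truth))
  matched_det <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((dx - truth$x[i])^2 + (dy - truth$y[i])^2)
    j <- which(!used & d < truth$r[i] + slack)
    if (length(j)) {
      j <- j[which.min(d[j])]
      matched[i] <- TRUE
      matched_det[i] <- j
      used[j] <- TRUE
    }
  }
  list(matched = matched, matched_det = matched_det,
       false_positives = sum(!used))
}

expect_cfu_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
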