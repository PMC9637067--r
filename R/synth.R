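# Seeded synthetic plate-image generator. Renders the imaging situation the
# algorithm assumes: a bright backlit dish on a dark surround, colonies as
# near-circular blobs darker than the agar whose centers are darker than
# their rims (domed colonies under backlight), a faint dark dish-wall ring,
# optional pairwise overlaps, border-crossing colonies, an illumination
# gradient, and sensor noise. Every placement and noise draw is fixed by the
# spec seed.

default_colony_colors <- function() {
  list(
    white = list(hue = 60, sat = 0.18),  # cream-colored colonies
    blue  = list(hue = 240, sat = 0.55), # lacZ+ colonies on X-gal
    colony = list(hue = 60, sat = 0.18)
  )
}

#' Specification of a synthetic plate
#'
#' Defaults describe a scaled-down backlit smartphone capture: an 800 px
#' frame, dish radius 46% of the frame, colonies of radius ~6 px whose
#' value channel rises from `rim_value - depth` at the center to
#' `rim_value` at the rim along `(1 - (d/r)^2)^2` (single interior minimum
#' per colony), a faint dish-wall ring, a mild horizontal illumination
#' gradient and Gaussian sensor noise.
#'
#' @param width,height frame size in pixels.
#' @param dish_cx,dish_cy,dish_r dish circle; defaults center the dish with
#'   radius `0.46 * min(width, height)`.
#' @param counts named integer vector of colonies per color label.
#' @param radius_mean,radius_sd colony radius distribution (px).
#' @param depth center darkening depth in value levels (> 0 guarantees the
#'   local-minima premise pre-noise).
#' @param rim_value colony value channel at the rim.
#' @param overlap_pairs number of colony pairs placed at 60-80% of the sum
#'   of their radii (pairwise overlaps only; no triples).
#' @param border_count colonies intersecting the dish edge.
#' @param ring_texture_sd mottle SD of the dish wall (the wall of a real
#'   plate is textured and throws many spurious local extrema).
#' @param illumination amplitude of the linear left-right value gradient.
#' @param noise_sd additive Gaussian noise SD per RGB channel.
#' @param seed integer fixing all randomness.
#' @param colony_colors per-label hue/saturation, see
#'   `default_colony_colors()`.
#' @param dish_value,surround_value,ring_value,ring_width scene levels.
#' @param min_gap minimum clearance between non-overlapping colonies (px).
#' @return a `plate_spec`.
#' @export
plate_spec <- function(width = 800L, height = 800L,
                       dish_cx = NULL, dish_cy = NULL, dish_r = NULL,
                       counts = c(white = 150L),
                       radius_mean = 6, radius_sd = 1,
                       depth = 45, rim_value = 150,
                       overlap_pairs = 0L, border_count = 0L,
                       illumination = 20, noise_sd = 2,
                       seed = 1L,
                       colony_colors = default_colony_colors(),
                       dish_value = 210, surround_value = 40,
                       ring_value = 165, ring_width = 2,
                       ring_texture_sd = 10,
                       min_gap = 3) {
  if (is.null(dish_cx)) dish_cx <- (width - 1) / 2
  if (is.null(dish_cy)) dish_cy <- (height - 1) / 2
  if (is.null(dish_r)) dish_r <- 0.46 * min(width, height)
  if (any(counts < 0) || radius_mean <= 0 || depth <= 0)
    cfu_error("cfuseg_param_error", "counts must be >= 0, radii and depth > 0")
  total <- sum(counts)
  if (2L * overlap_pairs + border_count > total)
    cfu_error("cfuseg_param_error",
              "overlap_pairs and border_count exceed the total colony count")
  structure(as.list(environment()), class = "plate_spec")
}

# vectorized HSV -> RGB on matrices; H degrees, S in [0,1], V in [0,255]
hsv_to_rgb_mat <- function(H, S, V) {
  Hp <- (H %% 360) / 60
  C <- V * S
  X <- C * (1 - abs(Hp %% 2 - 1))
  m <- V - C
  R <- G <- B <- matrix(0, nrow(V), ncol(V))
  sec <- floor(Hp) %% 6
  set <- function(mask, r, g, b) {
    R[mask] <<- r[mask]; G[mask] <<- g[mask]; B[mask] <<- b[mask]
  }
  Z <- matrix(0, nrow(V), ncol(V))
  set(sec == 0, C, X, Z); set(sec == 1, X, C, Z); set(sec == 2, Z, C, X)
  set(sec == 3, Z, X, C); set(sec == 4, X, Z, C); set(sec == 5, C, Z, X)
  list(R = R + m, G = G + m, B = B + m)
}

label_color <- function(colors, label, k = 1L) {
  if (!is.null(colors[[label]])) return(colors[[label]])
  list(hue = (30 * k) %% 360, sat = 0.3)
}

# sequential placement with rejection; returns the ground-truth frame
place_colonies <- function(spec) {
  counts <- spec$counts
  labels <- rep(names(counts), counts)
  n <- length(labels)
  truth <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      r = numeric(0), label = character(0),
                      border = logical(0), pair_id = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(truth)
  radii <- pmax(stats::rnorm(n, spec$radius_mean, spec$radius_sd), 2)
  # roles: the first 2*overlap_pairs entries form same-label pairs, the next
  # border_count touch the dish edge, the rest are interior
  placed <- matrix(numeric(0), 0, 2)
  placed_r <- numeric(0)
  conflicts <- function(x, y, r, skip = integer(0)) {
    if (nrow(placed) == 0L) return(FALSE)
    d <- sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)
    lim <- placed_r + r + spec$min_gap
    if (length(skip)) { d <- d[-skip]; lim <- lim[-skip] }
    any(d < lim)
  }
  rand_in_dish <- function(rmax) {
    # uniform over the disk where a colony of radius rmax fits fully inside
    rr <- (spec$dish_r - rmax - 2) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    c(spec$dish_cx + rr * cos(th), spec$dish_cy + rr * sin(th))
  }
  add <- function(x, y, r, label, border, pair_id) {
    placed <<- rbind(placed, c(x, y))
    placed_r <<- c(placed_r, r)
    truth <<- rbind(truth, data.frame(
      id = nrow(truth) + 1L, x = x, y = y, r = r, label = label,
      border = border, pair_id = pair_id, stringsAsFactors = FALSE))
  }
  i <- 1L
  pair_no <- 0L
  n_pair <- 2L * spec$overlap_pairs
  n_border <- spec$border_count
  while (i <= n) {
    r <- radii[i]
    if (i <= n_pair && i %% 2L == 1L) {
      # place a pair: anchor + partner at 60-80% of the summed radii
      r2 <- radii[i + 1L]
      ok <- FALSE
      for (a in 1:4000) {
        p <- rand_in_dish(r + r2 + spec$min_gap + (r + r2))
        if (conflicts(p[1], p[2], r)) next
        f <- stats::runif(1, 0.6, 0.8)
        th <- stats::runif(1, 0, 2 * pi)
        q <- p + f * (r + r2) * c(cos(th), sin(th))
        dd <- sqrt((q[1] - spec$dish_cx)^2 + (q[2] - spec$dish_cy)^2)
        if (dd + r2 + 2 > spec$dish_r) next
        if (conflicts(q[1], q[2], r2)) next
        pair_no <- pair_no + 1L
        add(p[1], p[2], r, labels[i], FALSE, pair_no)
        add(q[1], q[2], r2, labels[i + 1L], FALSE, pair_no)
        ok <- TRUE
        break
      }
      if (!ok) cfu_error("cfuseg_generation_error",
                         "could not place an overlapping pair; dish too crowded")
      i <- i + 2L
    } else {
      is_border <- i > n_pair && i <= n_pair + n_border
      ok <- FALSE
      for (a in 1:4000) {
        if (is_border) {
          # a border colony grows on agar up to the wall: a near-full disk
          # whose rim crosses into the dish-wall band
          th <- stats::runif(1, 0, 2 * pi)
          rr <- spec$dish_r - spec$ring_width - 0.8 * r
          x <- spec$dish_cx + rr * cos(th); y <- spec$dish_cy + rr * sin(th)
        } else {
          p <- rand_in_dish(r); x <- p[1]; y <- p[2]
        }
        if (conflicts(x, y, r)) next
        add(x, y, r, labels[i], is_border, NA_integer_)
        ok <- TRUE
        break
      }
      if (!ok) cfu_error("cfuseg_generation_error", sprintf(
        "could not place colony %d of %d; too many colonies for the dish area", i, n))
      i <- i + 1L
    }
  }
  truth
}

#' Generate a synthetic plate image with ground truth
#'
#' @param spec a [plate_spec()].
#' @return list with `image` (a [plate_image()]) and `truth` (data frame:
#'   `id`, `x`, `y`, `r`, `label`, `border`, `pair_id`). Bit-identical for
#'   identical specs.
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  with_local_seed(spec$seed, {
    truth <- place_colonies(spec)
    W <- spec$width; H <- spec$height
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    dd <- sqrt((xs - spec$dish_cx)^2 + (ys - spec$dish_cy)^2)
    V <- matrix(spec$surround_value, H, W)
    Hm <- matrix(45, H, W)
    S <- matrix(0.05, H, W)
    inside <- dd <= spec$dish_r
    V[inside] <- spec$dish_value
    S[inside] <- 0.06
    ring <- dd <= spec$dish_r & dd > spec$dish_r - spec$ring_width
    # the dish wall is mottled translucent plastic: textured, so it throws
    # many local extrema (the border noise the pruning stage must reject)
    V[ring] <- spec$ring_value +
      if (spec$ring_texture_sd > 0)
        stats::rnorm(sum(ring), 0, spec$ring_texture_sd) else 0
    # colonies: value = min over covering colonies (keeps both dark centers
    # of an overlapping pair, with a bright saddle on the contact line)
    colV <- matrix(Inf, H, W)
    colLab <- matrix(NA_character_, H, W)
    for (i in seq_len(nrow(truth))) {
      cx <- truth$x[i]; cy <- truth$y[i]; r <- truth$r[i]
      x0 <- max(0, floor(cx - r)); x1 <- min(W - 1, ceiling(cx + r))
      y0 <- max(0, floor(cy - r)); y1 <- min(H - 1, ceiling(cy + r))
      if (x0 > x1 || y0 > y1) next
      jx <- (x0:x1) + 1L; jy <- (y0:y1) + 1L
      lx <- matrix(rep(x0:x1, each = length(jy)), length(jy))
      ly <- matrix(rep(y0:y1, length(jx)), length(jy))
      d <- sqrt((lx - cx)^2 + (ly - cy)^2)
      prof <- spec$rim_value - spec$depth * (1 - (d / r)^2)^2
      hit <- d <= r & prof < colV[jy, jx]
      sub <- colV[jy, jx]; sub[hit] <- prof[hit]; colV[jy, jx] <- sub
      subl <- colLab[jy, jx]; subl[hit] <- truth$label[i]; colLab[jy, jx] <- subl
    }
    col_px <- is.finite(colV) & inside
    V[col_px] <- colV[col_px]
    k <- 0L
    for (l in unique(truth$label)) {
      k <- k + 1L
      cc <- label_color(spec$colony_colors, l, k)
      sel <- col_px & !is.na(colLab) & colLab == l
      Hm[sel] <- cc$hue
      S[sel] <- cc$sat
    }
    V <- V + spec$illumination * (xs / max(W - 1, 1) - 0.5)
    V <- pmin(pmax(V, 0), 255)
    rgbl <- hsv_to_rgb_mat(Hm, S, V)
    arr <- array(0, c(H, W, 3))
    arr[, , 1] <- rgbl$R; arr[, , 2] <- rgbl$G; arr[, , 3] <- rgbl$B
    if (spec$noise_sd > 0)
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
    arr <- round(pmin(pmax(arr, 0), 255))
    list(image = plate_image(arr, source_path = sprintf("synthetic(seed=%d)", spec$seed)),
         truth = truth)
  })
}

#' Degrade a plate image (downscale and re-encode)
#'
#' Bilinear downscale by `scale`, then lossy JPEG re-encode at the given
#' quality (quality 100 skips re-encoding and is lossless). Ground-truth
#' annotations, when supplied, are rescaled by the same factor.
#'
#' @param image a [plate_image()].
#' @param scale factor in (0, 1].
#' @param quality JPEG quality in (0, 100]; 100 = no re-encoding.
#' @param truth optional ground-truth frame to rescale.
#' @return the degraded `plate_image`, or `list(image, truth)` when `truth`
#'   is given.
#' @export
degrade <- function(image, scale, quality = 100, truth = NULL) {
  stopifnot(inherits(image, "plate_image"))
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    cfu_error("cfuseg_param_error", "scale must lie in (0, 1]")
  if (quality <= 0 || quality > 100)
    cfu_error("cfuseg_param_error", "quality must lie in (0, 100]")
  H2 <- max(1L, as.integer(round(image$height * scale)))
  W2 <- max(1L, as.integer(round(image$width * scale)))
  out <- image$rgb
  if (scale < 1) {
    out <- array(0, c(H2, W2, 3))
    for (ch in 1:3)
      out[, , ch] <- .bilinear_resize_cpp(image$rgb[, , ch] * 1.0, H2, W2)
  }
  if (quality < 100) {
    enc <- jpeg::writeJPEG(clamp01(out / 255), raw(), quality = quality / 100)
    out <- round(jpeg::readJPEG(enc) * 255)
  } else {
    out <- round(out)
  }
  img <- plate_image(out, source_path = image$source_path)
  if (is.null(truth)) return(img)
  t2 <- truth
  t2$x <- truth$x * scale
  t2$y <- truth$y * scale
  t2$r <- truth$r * scale
  list(image = img, truth = t2)
}
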