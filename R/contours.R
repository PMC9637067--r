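# Contour extraction and per-contour feature measurement. A "contour" is the
# ordered outer boundary of one 8-connected foreground component together
# with the component's pixel set.

# build a contour object for one label of a label matrix
contour_from_label <- function(lab, label, pixel_idx) {
  H <- nrow(lab); W <- ncol(lab)
  yy <- (pixel_idx - 1L) %% H
  xx <- (pixel_idx - 1L) %/% H
  first <- which.min(yy * W + xx) # first row-major pixel: trace start
  pts <- .trace_boundary_cpp(lab, as.integer(label), xx[first], yy[first],
                             length(pixel_idx))
  structure(list(
    id = as.integer(label),
    points = pts,                 # m x 2 ordered boundary, 0-based (x, y)
    pixel_idx = pixel_idx,        # linear indices into the image matrix
    n_pixels = length(pixel_idx),
    bbox = c(xmin = min(xx), xmax = max(xx), ymin = min(yy), ymax = max(yy))
  ), class = "cfu_contour")
}

#' Extract contours from a binary mask
#'
#' One contour per 8-connected foreground component (outer boundary only;
#' interior holes are ignored). Components smaller than `min_pixels` are
#' discarded as dust.
#'
#' @param mask logical matrix, or integer matrix where foreground is nonzero
#'   (e.g. the 0/255 output of [adaptive_binarize()]).
#' @param min_pixels dust threshold in pixels, default 4.
#' @return list of contour objects (possibly empty).
#' @export
extract_contours <- function(mask, min_pixels = 4L) {
  if (!is.matrix(mask)) cfu_error("cfuseg_param_error", "mask must be a matrix")
  m <- if (is.logical(mask)) mask else mask != 0L
  lab <- .label_components_cpp(m, 8L)
  K <- max(lab)
  if (K == 0L) return(list())
  idx <- which(lab > 0L)
  by_label <- split(idx, lab[idx])
  out <- list()
  new_id <- 0L
  for (l in seq_len(K)) {
    px <- by_label[[as.character(l)]]
    if (length(px) < min_pixels) next
    new_id <- new_id + 1L
    cont <- contour_from_label(lab, l, px)
    cont$id <- new_id
    out[[new_id]] <- cont
  }
  out
}

# translate a contour measured on a cropped window back to full-image
# coordinates (H_local / H_global are the matrix row counts)
shift_contour <- function(cont, x0, y0, H_local, H_global) {
  ly <- (cont$pixel_idx - 1L) %% H_local
  lx <- (cont$pixel_idx - 1L) %/% H_local
  cont$pixel_idx <- (lx + x0) * H_global + (ly + y0) + 1L
  if (nrow(cont$points)) {
    cont$points[, 1] <- cont$points[, 1] + x0
    cont$points[, 2] <- cont$points[, 2] + y0
  }
  cont$bbox <- cont$bbox + c(x0, x0, y0, y0)
  cont
}

polygon_area <- function(pts) {
  # shoelace over the closed polygon of boundary pixel centers
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((pts[j, 1] - pts[, 1])^2 + (pts[j, 2] - pts[, 2])^2))
}

#' Measure the feature vector of a contour
#'
#' Area and perimeter come from the traced boundary polygon; circularity is
#' `4 * pi * area / perimeter^2`; inertia is the minor/major axis-length
#' ratio of the moment-equivalent ellipse of the component's pixels
#' (`sqrt(lambda_min / lambda_max)` of the coordinate covariance); mean hue
#' is the circular mean of the hue view over interior pixels; area ratio is
#' the polygon area over the area of the minimum enclosing circle of the
#' boundary (a convexity/compactness proxy).
#'
#' @param contour a contour from [extract_contours()].
#' @param image the [plate_image()] the mask came from.
#' @return list with `area`, `perimeter`, `circularity`, `inertia`,
#'   `mean_hue`, `area_ratio`, centroid `cx`, `cy`, `n_pixels`.
#' @export
compute_features <- function(contour, image) {
  pts <- contour$points
  if (is.null(pts) || nrow(pts) < 5L)
    cfu_error("cfuseg_degenerate_contour",
              sprintf("contour %s has %d boundary points; >= 5 required for the ellipse fit",
                      contour$id, NROW(pts)))
  area <- polygon_area(pts)
  per <- polygon_perimeter(pts)
  if (area <= 0 || per <= 0)
    cfu_error("cfuseg_degenerate_contour",
              sprintf("contour %s is degenerate (zero area or perimeter)", contour$id))
  H <- nrow(image$gray)
  yy <- (contour$pixel_idx - 1L) %% H
  xx <- (contour$pixel_idx - 1L) %/% H
  # moment-equivalent ellipse from the pixel coordinate covariance
  mx <- mean(xx); my <- mean(yy)
  cxx <- mean((xx - mx)^2); cyy <- mean((yy - my)^2); cxy <- mean((xx - mx) * (yy - my))
  tr <- cxx + cyy
  disc <- sqrt(max((cxx - cyy)^2 + 4 * cxy^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  inertia <- if (l1 <= 1e-12) 1 else sqrt(max(l2, 0) / l1)
  mec <- .min_enclosing_circle_cpp(pts * 1.0)
  area_ratio <- if (mec[3] <= 0) 1 else min(area / (pi * mec[3]^2), 1)
  list(
    area = area,
    perimeter = per,
    circularity = 4 * pi * area / per^2,
    inertia = inertia,
    mean_hue = circular_mean_deg(image$hue[contour$pixel_idx]),
    area_ratio = area_ratio,
    cx = mx, cy = my,
    n_pixels = contour$n_pixels
  )
}

#' Feature table for a list of contours
#'
#' Computes [compute_features()] per contour; degenerate contours (< 5
#' boundary points) get `NA` features and `degenerate = TRUE`, routing them
#' to noise instead of aborting the run.
#'
#' @param contours list from [extract_contours()].
#' @param image the [plate_image()].
#' @return data frame with one row per contour.
#' @export
contour_features <- function(contours, image) {
  n <- length(contours)
  cols <- c("area", "perimeter", "circularity", "inertia", "mean_hue",
            "area_ratio", "cx", "cy", "n_pixels")
  df <- as.data.frame(matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols)))
  df <- cbind(contour_id = seq_len(n), df, degenerate = logical(n))
  for (i in seq_len(n)) {
    f <- tryCatch(compute_features(contours[[i]], image),
                  cfuseg_degenerate_contour = function(e) NULL)
    if (is.null(f)) {
      df$degenerate[i] <- TRUE
      df$n_pixels[i] <- contours[[i]]$n_pixels
      H <- nrow(image$gray)
      df$cx[i] <- mean((contours[[i]]$pixel_idx - 1L) %/% H)
      df$cy[i] <- mean((contours[[i]]$pixel_idx - 1L) %% H)
    } else {
      for (cn in cols) df[[cn]][i] <- f[[cn]]
    }
  }
  df
}
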