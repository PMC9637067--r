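# Dish region-of-interest detection. The dish is a bright disk on a dark
# surround (backlit plate); everything downstream is constrained to it.

#' Circular plate region of interest
#'
#' @param center_x,center_y circle center in pixels (0-based x = column,
#'   y = row).
#' @param radius circle radius in pixels.
#' @param dim image dimensions `c(height, width)` used to rasterize the mask.
#' @param margin optional inward margin in pixels subtracted from the radius
#'   when building the mask (default 0 so border colonies stay countable).
#' @return a `plate_roi` with the boolean `mask` and the circle parameters.
#' @export
plate_roi <- function(center_x, center_y, radius, dim, margin = 0) {
  if (radius <= 0) cfu_error("cfuseg_param_error", "ROI radius must be > 0")
  H <- dim[1]; W <- dim[2]
  if (center_x + radius < 0 || center_x - radius >= W ||
      center_y + radius < 0 || center_y - radius >= H)
    cfu_error("cfuseg_param_error", "ROI circle lies entirely outside the image")
  r <- max(radius - margin, 1)
  dx2 <- (seq_len(W) - 1 - center_x)^2
  dy2 <- (seq_len(H) - 1 - center_y)^2
  mask <- outer(dy2, dx2, "+") <= r^2
  structure(list(center_x = center_x, center_y = center_y, radius = radius,
                 margin = margin, mask = mask),
            class = "plate_roi")
}

#' @export
print.plate_roi <- function(x, ...) {
  cat(sprintf("<plate_roi center (%.1f, %.1f) radius %.1f px>\n",
              x$center_x, x$center_y, x$radius))
  invisible(x)
}

# Otsu's threshold on an 8-bit grayscale matrix
otsu_threshold <- function(gray) {
  h <- tabulate(as.integer(gray) + 1L, 256L)
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

#' Detect the dish region of interest
#'
#' Binarizes the grayscale view at Otsu's threshold (dish bright, surround
#' dark), takes the largest 8-connected bright component, and fits the
#' minimum enclosing circle of its traced outer boundary. Dark colonies
#' inside the dish become holes in the component and do not disturb the
#' outer circle.
#'
#' @param image a [plate_image()].
#' @param margin inward margin passed to [plate_roi()].
#' @return a `plate_roi`.
#' @export
detect_plate_roi <- function(image, margin = 0) {
  stopifnot(inherits(image, "plate_image"))
  gray <- image$gray
  thr <- otsu_threshold(gray)
  fg <- gray >= thr
  frac <- mean(fg)
  if (frac < 0.10 || frac > 0.90)
    cfu_error("cfuseg_detect_error", paste0(
      "no circular dish structure found (bright fraction ",
      sprintf("%.2f", frac), "); pass an explicit ROI via --roi cx,cy,r"))
  lab <- .label_components_cpp(fg, 8L)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  if (sizes[big] < 0.10 * length(gray))
    cfu_error("cfuseg_detect_error",
              "largest bright component covers < 10% of the frame; pass --roi cx,cy,r")
  bnd <- .trace_boundary_cpp(lab, big)
  mec <- .min_enclosing_circle_cpp(bnd * 1.0)
  # the component should essentially fill its enclosing circle
  fill <- sizes[big] / (pi * mec[3]^2)
  if (!is.finite(fill) || fill < 0.70)
    cfu_error("cfuseg_detect_error", sprintf(
      "largest bright component is not disk-like (fill ratio %.2f); pass --roi cx,cy,r",
      fill))
  plate_roi(mec[1], mec[2], mec[3], dim(gray), margin = margin)
}
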