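# A priori colony prototypes. The user clicks one representative colony per
# color class; its measured attributes (gray level, hue, size, shape) are the
# ground truth that parameterizes thresholding, clustering cut-offs and
# pruning.

#' Flood-fill a colony region from a seed point
#'
#' Grows the 4-connected region of pixels reachable from `seed` whose gray
#' value differs from the seed's gray value by at most `tolerance`
#' (fixed-range fill), restricted to the plate ROI.
#'
#' @param image a [plate_image()] (typically median-denoised).
#' @param seed `c(x, y)` pixel coordinates (0-based).
#' @param roi a [plate_roi()].
#' @param tolerance gray-level tolerance, default 20.
#' @param max_frac region-size cap as a fraction of the ROI area; a fill
#'   exceeding it means the seed hit background (default 0.2).
#' @return logical region mask (H x W).
#' @export
flood_fill_colony <- function(image, seed, roi, tolerance = 20L, max_frac = 0.2) {
  stopifnot(inherits(image, "plate_image"), inherits(roi, "plate_roi"))
  x <- as.integer(seed[1]); y <- as.integer(seed[2])
  if (x < 0 || x >= image$width || y < 0 || y >= image$height ||
      !roi$mask[y + 1, x + 1])
    cfu_error("cfuseg_param_error",
              sprintf("seed (%d, %d) lies outside the plate ROI", x, y))
  region <- .flood_fill_cpp(image$gray, roi$mask, x, y, as.integer(tolerance))
  if (sum(region) > max_frac * sum(roi$mask))
    cfu_error("cfuseg_seed_error", sprintf(
      "seed (%d, %d) hit background: fill grew to more than %.0f%% of the ROI; pick a point inside a colony",
      x, y, 100 * max_frac))
  region
}

#' Measure a colony prototype from its region mask
#'
#' Computes every attribute later referenced by the pipeline: mean gray,
#' circular mean hue, area, perimeter, circularity, inertia (shape features
#' use the same formulas as contour features, see [compute_features()]), and
#' the enclosing bounding box that initializes the threshold subregion size.
#'
#' @param region_mask logical H x W mask, one connected region.
#' @param image the [plate_image()] the mask was derived from.
#' @param color_label user-assigned class label, e.g. `"blue"`.
#' @param seed optional `c(x, y)` seed recorded on the prototype.
#' @param min_area smallest usable region, default 9 px^2 (degenerate shape
#'   statistics below that).
#' @return a `colony_prototype`.
#' @export
extract_prototype <- function(region_mask, image, color_label = "colony",
                              seed = NULL, min_area = 9L) {
  stopifnot(inherits(image, "plate_image"), is.logical(region_mask))
  npix <- sum(region_mask)
  if (npix == 0L)
    cfu_error("cfuseg_param_error", "empty prototype region")
  if (npix < min_area)
    cfu_error("cfuseg_param_error", sprintf(
      "prototype region of %d px is below the %d px minimum", npix, min_area))
  lab <- .label_components_cpp(region_mask, 8L)
  if (max(lab) != 1L)
    cfu_error("cfuseg_param_error", "prototype region must be a single connected component")
  idx <- which(region_mask)
  cont <- contour_from_label(lab, 1L, idx)
  f <- compute_features(cont, image)
  yy <- (idx - 1L) %% nrow(region_mask)
  xx <- (idx - 1L) %/% nrow(region_mask)
  structure(list(
    seed = if (is.null(seed)) round(c(f$cx, f$cy)) else as.integer(seed),
    region_mask = region_mask,
    mean_gray = mean(image$gray[idx]),
    mean_hue = f$mean_hue,
    area = f$area,
    n_pixels = npix,
    perimeter = f$perimeter,
    circularity = f$circularity,
    inertia = f$inertia,
    area_ratio = f$area_ratio,
    bbox_w = max(xx) - min(xx) + 1L,
    bbox_h = max(yy) - min(yy) + 1L,
    color_label = color_label
  ), class = "colony_prototype")
}

#' @export
print.colony_prototype <- function(x, ...) {
  cat(sprintf(
    "<colony_prototype '%s': gray %.1f, hue %.1f deg, area %.1f px^2, circ %.2f, inertia %.2f, bbox %dx%d>\n",
    x$color_label, x$mean_gray, x$mean_hue, x$area, x$circularity, x$inertia,
    x$bbox_w, x$bbox_h))
  invisible(x)
}

# average several same-label prototypes into one (plural seeds per color are
# permitted); bounding box takes the max so the threshold window stays larger
# than the largest clicked colony
combine_prototypes <- function(protos) {
  if (length(protos) == 1L) return(protos[[1]])
  p <- protos[[1]]
  for (f in c("mean_gray", "area", "n_pixels", "perimeter", "circularity",
              "inertia", "area_ratio"))
    p[[f]] <- mean(vapply(protos, `[[`, numeric(1), f))
  p$mean_hue <- circular_mean_deg(vapply(protos, `[[`, numeric(1), "mean_hue"))
  p$bbox_w <- max(vapply(protos, `[[`, integer(1), "bbox_w"))
  p$bbox_h <- max(vapply(protos, `[[`, integer(1), "bbox_h"))
  p
}

#' Build one prototype per color label from seed points
#'
#' Flood-fills each seed and measures it; multiple seeds sharing a label are
#' averaged into a single prototype for that label.
#'
#' @param image a [plate_image()].
#' @param roi a [plate_roi()].
#' @param seeds data frame with columns `x`, `y` and optionally `label`
#'   (default label `"colony"`).
#' @param tolerance flood-fill gray tolerance.
#' @return named list of `colony_prototype`, one per label, in order of
#'   first appearance.
#' @export
build_prototypes <- function(image, roi, seeds, tolerance = 20L) {
  if (NROW(seeds) < 1L)
    cfu_error("cfuseg_param_error", "at least one seed point is required")
  if (is.null(seeds$label)) seeds$label <- "colony"
  out <- list()
  for (i in seq_len(nrow(seeds))) {
    region <- flood_fill_colony(image, c(seeds$x[i], seeds$y[i]), roi,
                                tolerance = tolerance)
    p <- extract_prototype(region, image, color_label = seeds$label[i],
                           seed = c(seeds$x[i], seeds$y[i]))
    out[[seeds$label[i]]] <- c(out[[seeds$label[i]]], list(p))
  }
  lapply(out, combine_prototypes)
}
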