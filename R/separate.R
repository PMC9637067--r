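# Separation of unresolved regions: colony centers are darker than their
# rims under backlight (convex elevation), so local gray-level minima mark
# individual colonies; marker-based watershed then splits merged regions,
# and segments are verified against the single-colony statistics.

#' Detect local minima markers inside a region
#'
#' Finds the maxima of the inverted grayscale (255 - gray) within the
#' region whose prominence — height above the highest saddle connecting
#' them to a dominating maximum — strictly exceeds `noise_tolerance`.
#' Plateau maxima are reduced to the plateau centroid (snapped to the
#' nearest plateau pixel). Equivalent to ImageJ-style "find maxima" with a
#' noise tolerance, run on the inverted image.
#'
#' @param gray integer grayscale matrix (use the denoised view).
#' @param region_mask logical matrix delimiting the search region.
#' @param noise_tolerance prominence threshold in gray levels (> 0).
#' @return a `marker_set`: `points` (m x 2, 0-based x/y, ordered by x then
#'   y) and the tolerance used. May be empty.
#' @export
detect_local_minima <- function(gray, region_mask, noise_tolerance) {
  if (!any(region_mask))
    cfu_error("cfuseg_param_error", "region mask is empty")
  if (noise_tolerance <= 0)
    cfu_error("cfuseg_param_error", "noise_tolerance must be > 0")
  pts <- .local_maxima_prominence_cpp(255 - gray * 1.0, region_mask,
                                      noise_tolerance)
  structure(list(points = pts, noise_tolerance = noise_tolerance),
            class = "marker_set")
}

#' Split a region by marker-based watershed
#'
#' Floods the grayscale relief upward from the markers (dark colony centers
#' are basins), restricted to the region; every marker claims one segment
#' and the segments partition the region. With no markers the region is
#' returned as a single unsplit segment flagged `unverified` — it still
#' passes through pruning so isolated matte colonies without a dark center
#' are not lost.
#'
#' @param region_mask logical matrix.
#' @param markers a [detect_local_minima()] marker set.
#' @param gray integer grayscale matrix (the flooding relief).
#' @return list of segments, each holding a contour object and flags.
#' @export
watershed_separate <- function(region_mask, markers, gray) {
  idx_all <- which(region_mask)
  if (length(idx_all) == 0L) return(list())
  pts <- markers$points
  if (is.null(pts) || nrow(pts) == 0L) {
    lab <- .label_components_cpp(region_mask, 8L)
    seg <- list(contour = contour_from_label(lab, 1L, idx_all),
                marker = NULL, unverified = TRUE)
    return(list(seg))
  }
  lab <- .watershed_cpp(gray * 1.0, region_mask, pts)
  out <- vector("list", nrow(pts))
  li <- lab[idx_all]
  by_lab <- split(idx_all, li)
  for (l in seq_len(nrow(pts))) {
    px <- by_lab[[as.character(l)]]
    if (is.null(px) || length(px) == 0L) next
    out[[l]] <- list(contour = contour_from_label(lab, l, px),
                     marker = pts[l, ], unverified = FALSE)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Prune watershed segments against the single-colony statistics
#'
#' A segment is accepted as a colony iff each of mean hue (circular
#' distance), circularity, inertia and area lies within `m` standard
#' deviations of the single-colony cluster statistics; SDs are floored at
#' `sd_floor_frac` of the corresponding mean so tiny clusters (SD near 0)
#' do not reject everything. Segments failing every color's statistics are
#' the plate-border noise and are dropped.
#'
#' @param segments list from [watershed_separate()].
#' @param stats_list list of [select_single_colony_cluster()] statistics,
#'   one per color class.
#' @param image the [plate_image()] (for feature measurement).
#' @param m SD multiplier, default 3.
#' @param sd_floor_frac SD floor as a fraction of the mean, default 0.1.
#' @return list of `colony_detection` objects (possibly empty).
#' @export
prune_segments <- function(segments, stats_list, image, m = 3,
                           sd_floor_frac = 0.1) {
  if (inherits(stats_list, "single_colony_stats")) stats_list <- list(stats_list)
  out <- list()
  for (seg in segments) {
    f <- tryCatch(compute_features(seg$contour, image),
                  cfuseg_degenerate_contour = function(e) NULL)
    if (is.null(f)) next
    best <- NULL
    for (st in stats_list) {
      band <- function(feat) m * max(st$sd[[feat]],
                                     sd_floor_frac * abs(st$mean[[feat]]))
      pass <- hue_distance(f$mean_hue, st$mean$mean_hue) <= band("mean_hue") &&
        abs(f$circularity - st$mean$circularity) <= band("circularity") &&
        abs(f$inertia - st$mean$inertia) <= band("inertia") &&
        abs(f$area - st$mean$area) <= band("area")
      if (pass) {
        d <- hue_distance(f$mean_hue, st$mean$mean_hue)
        if (is.null(best) || d < best$d) best <- list(stats = st, d = d)
      }
    }
    if (is.null(best)) next
    out[[length(out) + 1L]] <- colony_detection(
      centroid = c(f$cx, f$cy), contour = seg$contour, area = f$area,
      mean_hue = f$mean_hue, color_label = best$stats$color_label,
      provenance = "watershed")
  }
  out
}
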