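# End-to-end pipeline: load -> ROI -> denoise -> prototypes -> per-color
# threshold search -> OR composite -> contours/features -> DBSCAN -> singles
# filter -> minima/watershed -> prune -> color assignment -> report.

default_pipeline_config <- function() {
  list(
    median_kernel = 3L,
    flood_tolerance = 20L,
    roi_margin = 0,
    search = list(),     # overrides for default_search_config()
    cutoffs = list(),    # overrides for default_single_cutoffs()
    prune_m = 3,
    prune_sd_floor = 0.1,
    noise_tolerance = NULL, # NULL = auto from prototype contrast
    min_contour_pixels = 4L
  )
}

stage <- function(name, expr) {
  withCallingHandlers(expr, cfuseg_error = function(e) {
    e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
    stop(e)
  })
}

# per-pixel competitive hue assignment: index of the prototype with minimum
# circular hue distance (the per-color masks of a multi-color plate)
nearest_prototype_matrix <- function(hue, prototypes) {
  best_d <- matrix(Inf, nrow(hue), ncol(hue))
  best_i <- matrix(1L, nrow(hue), ncol(hue))
  for (i in seq_along(prototypes)) {
    d <- hue_distance(hue, prototypes[[i]]$mean_hue)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- i
  }
  best_i
}

#' Run the full colony-counting pipeline
#'
#' Executes every stage from raster to count report. Deterministic: a fixed
#' image, seed set and configuration always yield the same report.
#'
#' @param image a [plate_image()] or a path to a PNG/JPEG file.
#' @param seeds data frame of seed points (`x`, `y`, optional `label`), one
#'   or more user-clicked representative colonies.
#' @param roi optional `c(cx, cy, r)` override for the dish circle; default
#'   is automatic detection.
#' @param out_dir optional output directory; when given, `counts.json`,
#'   `detections.csv` and `overlay.png` are written there.
#' @param config named overrides of `default_pipeline_config()`.
#' @param verbose emit per-stage object counts via `message()`.
#' @return a `count_report`; the full detection objects are attached as
#'   attribute `"detections"`.
#' @export
run_pipeline <- function(image, seeds, roi = NULL, out_dir = NULL,
                         config = list(), verbose = FALSE) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  say <- function(...) if (verbose) message(sprintf(...))

  img <- stage("load", {
    if (is.character(image)) load_image(image)
    else if (inherits(image, "plate_image")) image
    else cfu_error("cfuseg_param_error", "image must be a plate_image or a file path")
  })
  say("load: %d x %d px", img$width, img$height)

  roi_obj <- stage("roi", {
    if (is.null(roi)) detect_plate_roi(img, margin = cfg$roi_margin)
    else plate_roi(roi[1], roi[2], roi[3], dim(img$gray), margin = cfg$roi_margin)
  })
  say("roi: center (%.0f, %.0f) radius %.0f", roi_obj$center_x,
      roi_obj$center_y, roi_obj$radius)

  den <- stage("denoise", denoise_median(img, cfg$median_kernel))

  protos <- stage("prototype",
                  build_prototypes(den, roi_obj, seeds,
                                   tolerance = cfg$flood_tolerance))
  say("prototype: %d color class(es): %s", length(protos),
      paste(names(protos), collapse = ", "))

  # per-color restriction: ROI, plus competitive hue assignment when the
  # plate carries more than one color class
  nearest <- if (length(protos) > 1L)
    nearest_prototype_matrix(den$hue, protos) else NULL
  searches <- stage("threshold_search", {
    lapply(seq_along(protos), function(i) {
      restrict <- if (is.null(nearest)) roi_obj$mask
                  else roi_obj$mask & (nearest == i)
      search_threshold_params(den$gray, protos[[i]], cfg$search,
                              restrict = restrict)
    })
  })
  names(searches) <- names(protos)
  for (nm in names(searches))
    say("threshold '%s': s = %d, C = %g, peak area %.0f", nm,
        searches[[nm]]$params$s, searches[[nm]]$params$C,
        searches[[nm]]$assessment$area_under_peak)

  composite <- stage("composite",
                     combine_color_masks(lapply(searches, `[[`, "mask")))

  contours <- stage("contours",
                    extract_contours(composite, cfg$min_contour_pixels))
  if (length(contours) == 0L)
    cfu_error("cfuseg_pipeline_error",
              "[stage contours] no contours in the composite mask; check the seed points")
  features <- contour_features(contours, den)
  say("contours: %d (of which %d degenerate)", nrow(features),
      sum(features$degenerate))

  # locate each prototype's own contour (the component containing its seed)
  H <- nrow(den$gray)
  proto_cid <- vapply(protos, function(p) {
    lin <- p$seed[1] * H + p$seed[2] + 1L
    for (i in seq_along(contours))
      if (lin %in% contours[[i]]$pixel_idx) return(i)
    d2 <- (features$cx - p$seed[1])^2 + (features$cy - p$seed[2])^2
    which.min(d2)
  }, integer(1))

  clustering <- stage("dbscan", {
    std <- standardize_features(features)
    nd <- length(std$rows)
    if (nd >= 5L) {
      ms <- min(default_min_samples(nd), nd - 1L)
      eps <- estimate_eps(std$X, k = ms)
      model <- cluster_contours(std$X, eps, ms)
    } else {
      # too few contours for density estimation: treat them as one cluster
      model <- structure(list(eps = NA_real_, min_samples = 2L,
                              labels = rep(1L, nd),
                              core = rep(TRUE, nd)),
                         class = "cluster_model")
    }
    list(std = std, model = model)
  })
  say("dbscan: eps %.3f, min_samples %d, %d cluster(s), %d noise",
      clustering$model$eps, clustering$model$min_samples,
      length(setdiff(unique(clustering$model$labels), -1L)),
      sum(clustering$model$labels == -1L))

  # the flood-filled region only covers the darker colony core (fixed-range
  # fill), so for morphology cut-offs the a priori colony is re-measured
  # from its own contour in the chosen binarization
  protos_m <- lapply(seq_along(protos), function(i) {
    p <- protos[[i]]
    cid <- proto_cid[[i]]
    if (!features$degenerate[cid]) {
      for (f in c("area", "circularity", "inertia", "mean_hue", "area_ratio"))
        p[[f]] <- features[[f]][cid]
      bb <- contours[[cid]]$bbox
      p$bbox_w <- as.integer(bb["xmax"] - bb["xmin"] + 1)
      p$bbox_h <- as.integer(bb["ymax"] - bb["ymin"] + 1)
    }
    p
  })
  names(protos_m) <- names(protos)

  singles <- stage("singles", {
    accepted_by <- list()
    stats_list <- list()
    for (i in seq_along(protos)) {
      st <- select_single_colony_cluster(
        clustering$model, clustering$std, features, proto_cid[[i]],
        color_label = names(protos)[i])
      fs <- filter_singles(st, features, protos_m[[i]], cfg$cutoffs)
      stats_list[[names(protos)[i]]] <- st
      accepted_by[[names(protos)[i]]] <- fs$accepted
    }
    list(accepted_by = accepted_by, stats = stats_list)
  })

  # resolve contours accepted under more than one color by nearest hue
  all_acc <- sort(unique(unlist(singles$accepted_by)))
  acc_label <- vapply(all_acc, function(id) {
    hits <- names(singles$accepted_by)[vapply(singles$accepted_by,
                                              function(v) id %in% v, logical(1))]
    if (length(hits) == 1L) return(hits)
    hues <- vapply(protos[hits], `[[`, numeric(1), "mean_hue")
    hits[which.min(hue_distance(features$mean_hue[id], hues))]
  }, character(1))
  unresolved <- setdiff(seq_len(nrow(features)), all_acc)
  say("singles: %d accepted, %d unresolved", length(all_acc), length(unresolved))

  detections <- lapply(seq_along(all_acc), function(j) {
    id <- all_acc[j]
    colony_detection(
      centroid = c(features$cx[id], features$cy[id]),
      contour = contours[[id]], area = features$area[id],
      mean_hue = features$mean_hue[id], color_label = acc_label[j],
      provenance = "single")
  })

  ws_dets <- stage("watershed", {
    bg_px <- roi_obj$mask & composite == 0L
    bg_gray <- if (any(bg_px)) mean(den$gray[bg_px]) else 255
    proto_hues <- vapply(protos, `[[`, numeric(1), "mean_hue")
    out <- list()
    Wg <- ncol(den$gray)
    for (id in unresolved) {
      # work on the region's bounding box, not the full frame
      bb <- contours[[id]]$bbox
      x0 <- max(bb[["xmin"]] - 2L, 0L); x1 <- min(bb[["xmax"]] + 2L, Wg - 1L)
      y0 <- max(bb[["ymin"]] - 2L, 0L); y1 <- min(bb[["ymax"]] + 2L, H - 1L)
      subg <- den$gray[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
      Hl <- nrow(subg)
      idxg <- contours[[id]]$pixel_idx
      gy <- (idxg - 1L) %% H; gx <- (idxg - 1L) %/% H
      region <- matrix(FALSE, Hl, ncol(subg))
      region[cbind(gy - y0 + 1L, gx - x0 + 1L)] <- TRUE
      # noise tolerance tied to the contrast of the governing color class
      gi <- if (length(protos) == 1L || is.na(features$mean_hue[id])) 1L
            else which.min(hue_distance(features$mean_hue[id], proto_hues))
      # 0.10 x contrast: the saddle between two overlapping colonies keeps
      # only ~30-60% of the center-to-rim depth, while noise extrema stay
      # below ~5 gray levels (see the methods vignette)
      tol <- if (!is.null(cfg$noise_tolerance)) cfg$noise_tolerance
             else max(5, 0.10 * (bg_gray - protos[[gi]]$mean_gray))
      markers <- detect_local_minima(subg, region, tol)
      segs <- watershed_separate(region, markers, subg)
      segs <- lapply(segs, function(s) {
        s$contour <- shift_contour(s$contour, x0, y0, Hl, H)
        s
      })
      out <- c(out, prune_segments(segs, singles$stats, den,
                                   m = cfg$prune_m,
                                   sd_floor_frac = cfg$prune_sd_floor))
    }
    out
  })
  say("watershed: %d detections recovered from %d unresolved regions",
      length(ws_dets), length(unresolved))

  detections <- assign_color_groups(c(detections, ws_dets), protos)

  params <- list(
    threshold = lapply(searches, function(s) list(s = s$params$s, C = s$params$C)),
    dbscan = list(eps = clustering$model$eps,
                  min_samples = clustering$model$min_samples),
    cutoffs = utils::modifyList(default_single_cutoffs(), cfg$cutoffs),
    prune = list(m = cfg$prune_m, sd_floor_frac = cfg$prune_sd_floor),
    median_kernel = cfg$median_kernel,
    flood_tolerance = cfg$flood_tolerance,
    roi = list(cx = roi_obj$center_x, cy = roi_obj$center_y,
               r = roi_obj$radius)
  )
  report <- summarize_detections(detections, labels = names(protos),
                                 parameters = params,
                                 image_id = img$source_path)
  say("report: %d colonies total", report$total)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report(report, file.path(out_dir, "counts.json"), "json")
    write_report(report, file.path(out_dir, "detections.csv"), "csv")
    render_overlay(img, detections, file.path(out_dir, "overlay.png"))
  }
  attr(report, "detections") <- detections
  report
}
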