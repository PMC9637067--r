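# Color-group assignment, count summaries, overlay rendering, and tabular
# report I/O.

#' One accepted colony detection
#'
#' @param centroid `c(x, y)` in pixels.
#' @param contour the contour object.
#' @param area px^2 (boundary-polygon area).
#' @param mean_hue degrees.
#' @param color_label prototype label, or `NA` until assigned.
#' @param provenance `"single"` (accepted directly from the single-colony
#'   cluster) or `"watershed"` (recovered by separation).
#' @return a `colony_detection`.
#' @export
colony_detection <- function(centroid, contour, area, mean_hue,
                             color_label = NA_character_,
                             provenance = c("single", "watershed")) {
  provenance <- match.arg(provenance)
  structure(list(centroid = as.numeric(centroid), contour = contour,
                 area = area, mean_hue = mean_hue,
                 color_label = color_label, provenance = provenance),
            class = "colony_detection")
}

#' Assign detections to color groups
#'
#' Detections that already carry a label (inherited from a single-label
#' mask or from pruning statistics) keep it; unlabeled detections get the
#' label of the prototype with the minimum circular hue distance.
#'
#' @param detections list of [colony_detection()].
#' @param prototypes named list of prototypes (one per label).
#' @return the detections, all labeled.
#' @export
assign_color_groups <- function(detections, prototypes) {
  if (length(prototypes) == 0L)
    cfu_error("cfuseg_param_error", "at least one prototype is required")
  hues <- vapply(prototypes, `[[`, numeric(1), "mean_hue")
  labels <- vapply(prototypes, `[[`, character(1), "color_label")
  lapply(detections, function(d) {
    if (is.na(d$color_label))
      d$color_label <- unname(labels[which.min(hue_distance(d$mean_hue, hues))])
    d
  })
}

detections_frame <- function(detections) {
  data.frame(
    id = seq_along(detections),
    x = vapply(detections, function(d) d$centroid[1], numeric(1)),
    y = vapply(detections, function(d) d$centroid[2], numeric(1)),
    area = vapply(detections, `[[`, numeric(1), "area"),
    hue = vapply(detections, `[[`, numeric(1), "mean_hue"),
    label = vapply(detections, `[[`, character(1), "color_label"),
    provenance = vapply(detections, `[[`, character(1), "provenance"),
    stringsAsFactors = FALSE
  )
}

#' Summarize detections into a count report
#'
#' @param detections list of labeled [colony_detection()].
#' @param labels labels to report even when their count is zero (defaults
#'   to the labels present).
#' @param parameters named list echoed for reproducibility (threshold
#'   parameters per label, DBSCAN settings, prune configuration, ...).
#' @param image_id identifier of the processed image.
#' @return a `count_report` with per-label counts and the total.
#' @export
summarize_detections <- function(detections, labels = NULL,
                                 parameters = list(), image_id = "") {
  got <- vapply(detections, `[[`, character(1), "color_label")
  if (is.null(labels)) labels <- unique(got)
  counts <- vapply(labels, function(l) sum(got == l), integer(1))
  names(counts) <- labels
  structure(list(counts = as.list(counts), total = length(detections),
                 parameters = parameters, image = image_id,
                 detections = detections_frame(detections)),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("<count_report: %d colonies", x$total))
  if (length(x$counts))
    cat(" (", paste(sprintf("%s: %d", names(x$counts), unlist(x$counts)),
                    collapse = ", "), ")", sep = "")
  cat(">\n")
  invisible(x)
}

overlay_palette <- function(labels) {
  # blue colonies circled in blue, everything else cycles from green
  pal <- list(c(0L, 200L, 0L), c(230L, 160L, 0L), c(200L, 0L, 200L),
              c(255L, 0L, 0L))
  out <- list()
  j <- 0L
  for (l in labels) {
    if (grepl("blue", tolower(l))) out[[l]] <- c(40L, 40L, 255L)
    else { j <- j + 1L; out[[l]] <- pal[[(j - 1L) %% length(pal) + 1L]] }
  }
  out
}

#' Render a detection overlay
#'
#' Draws the minimum enclosing circle of every detection in a per-label
#' stroke color on a copy of the input raster; optionally writes it as PNG.
#' Pure rendering: counts are never altered.
#'
#' @param image the [plate_image()].
#' @param detections labeled detections.
#' @param path optional PNG output path.
#' @param stroke stroke thickness in pixels, default 2.
#' @return the annotated `plate_image`, invisibly if written to `path`.
#' @export
render_overlay <- function(image, detections, path = NULL, stroke = 2L) {
  rgb <- image$rgb
  H <- nrow(rgb); W <- ncol(rgb)
  labels <- unique(vapply(detections, `[[`, character(1), "color_label"))
  pal <- overlay_palette(labels)
  for (d in detections) {
    mec <- .min_enclosing_circle_cpp(d$contour$points * 1.0)
    r <- mec[3] + 2
    col <- pal[[d$color_label]]
    theta <- seq(0, 2 * pi, length.out = max(16L, ceiling(4 * pi * r)))
    for (t in seq_len(stroke)) {
      xs <- round(mec[1] + (r + t - 1) * cos(theta))
      ys <- round(mec[2] + (r + t - 1) * sin(theta))
      ok <- xs >= 0 & xs < W & ys >= 0 & ys < H
      ii <- cbind(ys[ok] + 1L, xs[ok] + 1L)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[ii] <- col[ch]
        rgb[, , ch] <- plane
      }
    }
  }
  out <- plate_image(rgb, source_path = image$source_path)
  if (!is.null(path)) {
    write_image(out, path)
    return(invisible(out))
  }
  out
}

#' Write a count report
#'
#' JSON carries the full report (round-trips losslessly through
#' [read_report()]); CSV has one row per detection plus `#`-prefixed
#' summary footer lines. Comma separator, UTF-8, `.` decimal.
#'
#' @param report a [summarize_detections()] report.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  ok <- tryCatch(suppressWarnings({
    if (format == "json") {
      jsonlite::write_json(
        list(image = report$image, total = report$total,
             counts = report$counts, parameters = report$parameters,
             detections = report$detections),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    } else {
      con <- file(path, "w", encoding = "UTF-8")
      on.exit(close(con))
      utils::write.csv(report$detections, con, row.names = FALSE)
      writeLines(sprintf("# total,%d", report$total), con)
      for (l in names(report$counts))
        writeLines(sprintf("# count_%s,%d", l, report$counts[[l]]), con)
    }
    TRUE
  }), error = function(e) FALSE)
  if (!ok) cfu_error("cfuseg_io_error", sprintf("cannot write report to '%s'", path))
  invisible(path)
}

#' Read back a JSON count report
#'
#' @param path a file written by [write_report()] with `format = "json"`.
#' @return a `count_report` (without the in-memory detection objects).
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    cfu_error("cfuseg_io_error", sprintf("no report at '%s'", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(counts = as.list(x$counts), total = x$total,
                 parameters = x$parameters, image = x$image,
                 detections = x$detections),
            class = "count_report")
}
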