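# Unsupervised identification of the single-colony population: DBSCAN over
# standardized contour features, selection of the cluster containing the
# a priori colony, and strict morphology cut-offs.

#' Standardize the contour feature matrix for clustering
#'
#' Builds the clustered feature matrix: area, circularity, inertia, area
#' ratio, and hue embedded as a sin/cos pair (so 359 degrees sits next to
#' 1 degree), each column z-scored. Mixing raw units (px^2 against degrees)
#' would let one feature dominate the distances.
#'
#' @param features data frame from [contour_features()].
#' @return list with `X` (matrix over non-degenerate rows) and `rows`
#'   (their indices in `features`).
#' @export
standardize_features <- function(features) {
  rows <- which(!features$degenerate)
  hr <- features$mean_hue[rows] * pi / 180
  X <- cbind(
    area = features$area[rows],
    circularity = features$circularity[rows],
    inertia = features$inertia[rows],
    area_ratio = features$area_ratio[rows],
    hue_sin = sin(hr),
    hue_cos = cos(hr)
  )
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, "/"), rows = rows,
       center = mu, scale = sd)
}

#' Default DBSCAN minimum-neighbors parameter
#'
#' One fifth of the number of detected contours, floored at 2 and capped at
#' 20 (the uncapped rule grows pathologically strict on dense plates).
#'
#' @param n number of contours.
#' @return integer.
#' @export
default_min_samples <- function(n) min(20L, max(2L, n %/% 5L))

#' Estimate the DBSCAN radius by the k-th nearest neighbor method
#'
#' Computes every point's distance to its k-th nearest neighbor, sorts the
#' distances, and returns the value at the knee of the curve (the point of
#' maximum perpendicular distance from the chord joining its endpoints).
#' When the curve is degenerate (straight within tolerance) the 90th
#' percentile of the k-distances is returned instead.
#'
#' @param X numeric feature matrix (standardized).
#' @param k neighbor rank; the pipeline uses `k = min_samples`.
#' @return positive scalar eps.
#' @export
estimate_eps <- function(X, k) {
  n <- nrow(X)
  if (n <= k)
    cfu_error("cfuseg_param_error",
              sprintf("need more than k = %d points to estimate eps (have %d)", k, n))
  D <- as.matrix(stats::dist(X))
  kd <- apply(D, 1, function(r) sort(r)[k + 1L]) # +1: self at distance 0
  y <- sort(kd)
  if (n >= 3L) {
    i <- seq_len(n)
    dx <- n - 1; dy <- y[n] - y[1]
    nrm <- sqrt(dx^2 + dy^2)
    d <- abs(dy * (i - 1) - dx * (y - y[1])) / max(nrm, 1e-12)
    if (max(d) > 1e-9 * max(1, abs(y[n]))) {
      eps <- y[which.max(d)]
      if (eps > 0) return(eps)
    }
  }
  eps <- as.numeric(stats::quantile(y, 0.9, names = FALSE))
  max(eps, 1e-9)
}

#' DBSCAN clustering of contour features
#'
#' Standard DBSCAN semantics: a point is core when its eps-neighborhood
#' (itself included) holds at least `min_samples` points; clusters are the
#' maximal density-connected sets, grown deterministically in index order;
#' everything else is labeled -1 (noise). Border points reachable from
#' several clusters go to the cluster whose expansion reaches them first
#' (the one holding the lowest-index core point among their neighbors).
#'
#' @param X numeric feature matrix.
#' @param eps neighborhood radius (> 0).
#' @param min_samples minimum neighborhood size for a core point (>= 2);
#'   defaults to [default_min_samples()] of `nrow(X)`.
#' @return a `cluster_model`: list with `eps`, `min_samples`, and integer
#'   `labels` (-1 noise, clusters numbered from 1 in discovery order).
#' @export
cluster_contours <- function(X, eps, min_samples = NULL) {
  n <- nrow(X)
  if (is.null(min_samples)) min_samples <- default_min_samples(n)
  if (eps <= 0) cfu_error("cfuseg_param_error", "eps must be > 0")
  if (min_samples < 2) cfu_error("cfuseg_param_error", "min_samples must be >= 2")
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == -1L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  structure(list(eps = eps, min_samples = as.integer(min_samples),
                 labels = labels, core = core),
            class = "cluster_model")
}

#' Select the single-colony cluster and summarize it
#'
#' The cluster whose members include the a priori colony's own contour is
#' the single-colony population. If that contour was labeled noise, the
#' cluster whose centroid (in standardized feature space) lies nearest the
#' prototype contour's feature vector is used instead, with a warning.
#'
#' @param model a [cluster_contours()] result.
#' @param std the [standardize_features()] result the model was fitted on.
#' @param features the full [contour_features()] data frame.
#' @param prototype_contour_id row index (in `features`) of the contour
#'   containing the prototype.
#' @param color_label label carried onto the statistics.
#' @return a `single_colony_stats`: member ids plus per-feature mean and SD
#'   (hue uses the circular mean and circular SD).
#' @export
select_single_colony_cluster <- function(model, std, features,
                                         prototype_contour_id,
                                         color_label = "colony") {
  if (all(model$labels == -1L))
    cfu_error("cfuseg_pipeline_error",
              "DBSCAN produced no clusters; inspect the threshold search diagnostics")
  pos <- match(prototype_contour_id, std$rows)
  if (is.na(pos))
    cfu_error("cfuseg_pipeline_error",
              "prototype contour is degenerate and was not clustered")
  lab <- model$labels[pos]
  if (lab == -1L) {
    cls <- sort(unique(model$labels[model$labels != -1L]))
    cent <- vapply(cls, function(cl)
      colMeans(std$X[model$labels == cl, , drop = FALSE]), numeric(ncol(std$X)))
    d2 <- colSums((cent - std$X[pos, ])^2)
    lab <- cls[which.min(d2)]
    warning(sprintf(
      "prototype contour fell into DBSCAN noise; using nearest cluster %d for '%s'",
      lab, color_label))
  }
  members <- std$rows[model$labels == lab]
  fm <- features[members, , drop = FALSE]
  sds <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(
    members = members,
    cluster = lab,
    color_label = color_label,
    mean = list(area = mean(fm$area), circularity = mean(fm$circularity),
                inertia = mean(fm$inertia),
                mean_hue = circular_mean_deg(fm$mean_hue)),
    sd = list(area = sds(fm$area), circularity = sds(fm$circularity),
              inertia = sds(fm$inertia),
              mean_hue = circular_sd_deg(fm$mean_hue))
  ), class = "single_colony_stats")
}

default_single_cutoffs <- function() {
  list(area_lo = 0.3, area_hi = 3.0, circularity = 0.6, inertia = 0.5,
       hue = 30)
}

#' Split contours into accepted single colonies and unresolved regions
#'
#' A member of the single-colony cluster is accepted as a single colony iff
#' its area lies within `[area_lo, area_hi] x prototype area`, circularity
#' and inertia meet their floors, and its mean hue lies within `hue` degrees
#' (circular) of the prototype. Every other contour — members failing the
#' cut-offs, other clusters, and noise — is returned as an unresolved region
#' for watershed processing.
#'
#' @param stats a [select_single_colony_cluster()] result.
#' @param features the [contour_features()] data frame.
#' @param prototype the governing prototype.
#' @param cutoffs overrides for the default cut-offs (`area_lo = 0.3`,
#'   `area_hi = 3`, `circularity = 0.6`, `inertia = 0.5`, `hue = 30`).
#' @return list with integer vectors `accepted` and `unresolved`
#'   partitioning `seq_len(nrow(features))`.
#' @export
filter_singles <- function(stats, features, prototype, cutoffs = list()) {
  co <- utils::modifyList(default_single_cutoffs(), cutoffs)
  ok <- rep(FALSE, nrow(features))
  m <- stats$members
  ok[m] <- !features$degenerate[m] &
    features$area[m] >= co$area_lo * prototype$area &
    features$area[m] <= co$area_hi * prototype$area &
    features$circularity[m] >= co$circularity &
    features$inertia[m] >= co$inertia &
    hue_distance(features$mean_hue[m], prototype$mean_hue) <= co$hue
  list(accepted = which(ok), unresolved = which(!ok))
}
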