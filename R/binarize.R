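# Iterative adaptive thresholding. A candidate binarization is valid when
# the grayscale histogram of its foreground pixels is unimodal, the peak
# contains the prototype's mean gray value, and the area under the peak is
# large; the (s, C) pair maximizing that area wins.

#' Adaptive-threshold parameters
#'
#' @param s subregion (window) size in pixels; odd, >= 3.
#' @param C offset subtracted from the local Gaussian mean, in gray levels.
#' @return a `threshold_params` object.
#' @export
threshold_params <- function(s, C) {
  check_odd_kernel(s, "subregion size s")
  structure(list(s = as.integer(s), C = as.numeric(C)), class = "threshold_params")
}

#' 1-D Gaussian kernel for the local-mean window
#'
#' Normalized Gaussian of odd length `s` with the conventional size-derived
#' width `sigma = 0.3 * ((s - 1) / 2 - 1) + 0.8`. This kernel, applied
#' separably, defines the Gaussian-weighted window mean `T(x, y)` of the
#' threshold formula; it is exported so independent checks can use the same
#' weights.
#'
#' @param s odd window size.
#' @return numeric vector of length `s` summing to 1.
#' @export
gaussian_kernel1d <- function(s) {
  check_odd_kernel(s, "kernel size")
  sigma <- 0.3 * ((s - 1) * 0.5 - 1) + 0.8
  x <- seq_len(s) - 1 - (s - 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian-weighted local mean with edge replication (separable)
local_gaussian_mean <- function(gray, s) {
  .gaussian_local_mean_cpp(gray * 1.0, gaussian_kernel1d(s))
}

#' Adaptive binarization
#'
#' Per-pixel thresholding against the local statistic
#' `T(x, y) = GaussianMean_s(x, y) - C`: the output is 255 (foreground)
#' where `src(x, y) < T(x, y)` and 0 where `src(x, y) > T(x, y)`; equality
#' is assigned to background. Foreground therefore captures pixels darker
#' than their local surround — dark colonies on a backlit plate.
#'
#' @param gray integer grayscale matrix (0-255).
#' @param params a [threshold_params()].
#' @return integer matrix valued in `{0, 255}`.
#' @export
adaptive_binarize <- function(gray, params) {
  stopifnot(inherits(params, "threshold_params"))
  M <- local_gaussian_mean(gray, params$s)
  out <- matrix(0L, nrow(gray), ncol(gray))
  out[gray < M - params$C] <- 255L
  out
}

#' Grayscale histogram of foreground pixels
#'
#' 256-bin histogram of the *original* gray values at mask-foreground
#' pixels. (A histogram of the binary image itself would have two bins and
#' could never be unimodal around the prototype gray; see the methods
#' vignette.)
#'
#' @param gray integer grayscale matrix.
#' @param mask matrix of the same shape; foreground where nonzero/TRUE.
#' @return integer vector of 256 counts (bin i = gray level i - 1).
#' @export
foreground_histogram <- function(gray, mask) {
  if (!all(dim(gray) == dim(mask)))
    cfu_error("cfuseg_param_error", "gray and mask must have identical dimensions")
  fg <- if (is.logical(mask)) mask else mask != 0L
  tabulate(as.integer(gray[fg]) + 1L, 256L)
}

#' Savitzky-Golay smoothing
#'
#' Each output value is the center evaluation of the least-squares
#' polynomial of degree `polyorder` fitted over a sliding window. At the two
#' ends (where the window does not fit) the polynomial fitted to the first /
#' last full window is evaluated at the edge positions.
#'
#' @param signal numeric vector.
#' @param window odd window length, default 11.
#' @param polyorder polynomial degree, must be `< window`; default 3.
#' @return numeric vector of the same length.
#' @export
smooth_savgol <- function(signal, window = 11L, polyorder = 3L) {
  n <- length(signal)
  if (window %% 2 == 0 || window < 3 || polyorder < 0 || polyorder >= window)
    cfu_error("cfuseg_param_error",
              "window must be odd >= 3 and polyorder < window")
  if (window > n)
    cfu_error("cfuseg_param_error", "window longer than the signal")
  h <- (window - 1L) %/% 2L
  x <- (-h):h
  A <- outer(x, 0:polyorder, `^`)
  # center-evaluation weights: first row of (A'A)^-1 A'
  w <- solve(crossprod(A), t(A))[1, ]
  out <- numeric(n)
  for (i in (h + 1):(n - h))
    out[i] <- sum(w * signal[(i - h):(i + h)])
  # edge handling: polynomial fitted to the first/last window, evaluated
  # at the positions the sliding window cannot reach
  xe <- 0:(window - 1L)
  Ae <- outer(xe, 0:polyorder, `^`)
  Pe <- Ae %*% solve(crossprod(Ae), t(Ae))
  out[1:h] <- (Pe %*% signal[1:window])[1:h]
  out[(n - h + 1):n] <- (Pe %*% signal[(n - window + 1):n])[(window - h + 1):window]
  out
}

#' Peak range of a smoothed histogram
#'
#' Locates the global maximum bin (first bin on ties) and extends the range
#' to each side while values keep decreasing, stopping at the last bin of
#' the decreasing run; zero bins end the run (the peak spans positive
#' support only). With `eps = 0` (the default) the decrease is strict —
#' equal adjacent values end the run; a positive `eps` tolerates rises
#' smaller than `eps` (used by the parameter search to ride out counting
#' noise on the flanks).
#'
#' @param smoothed numeric vector (e.g. 256 smoothed counts).
#' @param eps plateau/rise tolerance, absolute units of the signal.
#' @return integer `c(peak_lo, peak_hi)`, 0-based bin indices.
#' @export
find_peak_range <- function(smoothed, eps = 0) {
  n <- length(smoothed)
  if (n == 0L || max(smoothed) <= 0)
    cfu_error("cfuseg_nopeak_error", "signal has no positive values: no peak")
  m <- which.max(smoothed)
  hi <- m
  while (hi < n && smoothed[hi + 1] > 0 &&
         smoothed[hi + 1] < smoothed[hi] + eps) hi <- hi + 1L
  lo <- m
  while (lo > 1L && smoothed[lo - 1] > 0 &&
         smoothed[lo - 1] < smoothed[lo] + eps) lo <- lo - 1L
  c(peak_lo = lo - 1L, peak_hi = hi - 1L)
}

# Count modes whose prominence exceeds rel * global max. Run-collapsed local
# maxima; prominence = height above the higher of the two flanking valley
# minima on the way to a taller run (classic 1-D persistence walk).
count_prominent_modes <- function(v, rel = 0.05) {
  r <- rle(v)
  vals <- r$values
  k <- length(vals)
  if (k == 1L) return(as.integer(vals[1] > 0))
  ends <- cumsum(r$lengths)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || vals[i] > vals[i - 1]
    right_ok <- i == k || vals[i] > vals[i + 1]
    left_ok && right_ok
  }, logical(1))
  thr <- rel * max(v)
  n_modes <- 0L
  for (i in which(is_max)) {
    h <- vals[i]
    lmin <- h; lhigher <- FALSE
    j <- i - 1L
    while (j >= 1L) {
      if (vals[j] > h) { lhigher <- TRUE; break }
      lmin <- min(lmin, vals[j]); j <- j - 1L
    }
    rmin <- h; rhigher <- FALSE
    j <- i + 1L
    while (j <= k) {
      if (vals[j] > h) { rhigher <- TRUE; break }
      rmin <- min(rmin, vals[j]); j <- j + 1L
    }
    # key saddle: higher of the minima on the sides that reach a taller run;
    # a maximum with no taller run keys off its lower flank (the global max)
    base <- if (lhigher && rhigher) max(lmin, rmin)
            else if (lhigher) lmin
            else if (rhigher) rmin
            else min(lmin, rmin)
    if (h - base > thr) n_modes <- n_modes + 1L
  }
  n_modes
}

#' Assess a candidate binarization against the histogram criteria
#'
#' Computes the foreground grayscale histogram, smooths it, finds the peak
#' range, and evaluates the three validity criteria: the histogram must be
#' unimodal, the peak must contain the prototype's mean gray value, and
#' (as the search objective) the area under the peak must be large. The
#' area is only computed when the prototype gray lies inside the peak.
#'
#' @param gray integer grayscale matrix.
#' @param mask binarization mask (0/255 or logical).
#' @param prototype a [extract_prototype()] result.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param unimodal_rel_height relative prominence a mode must exceed to
#'   count against unimodality (default 0.05 of the global maximum).
#' @param peak_eps rise tolerance forwarded to [find_peak_range()].
#' @param min_area smallest acceptable area under the peak (default 0).
#' @return a `histogram_assessment`; `valid` is FALSE (never an error) when
#'   any criterion fails, with the failure named in `reason`.
#' @export
assess_binarization <- function(gray, mask, prototype,
                                sg_window = 11L, sg_polyorder = 3L,
                                unimodal_rel_height = 0.05,
                                peak_eps = 0, min_area = 0) {
  raw <- foreground_histogram(gray, mask)
  res <- structure(list(
    raw_hist = raw, smoothed = NULL, peak_lo = NA_integer_,
    peak_hi = NA_integer_, unimodal = FALSE,
    contains_prototype_gray = FALSE, area_under_peak = NA_real_,
    valid = FALSE, reason = ""
  ), class = "histogram_assessment")
  if (sum(raw) == 0L) {
    res$reason <- "empty foreground"
    return(res)
  }
  sm <- pmax(smooth_savgol(raw, sg_window, sg_polyorder), 0)
  res$smoothed <- sm
  pk <- tryCatch(find_peak_range(sm, eps = peak_eps * max(sm)),
                 cfuseg_nopeak_error = function(e) NULL)
  if (is.null(pk)) {
    res$reason <- "no peak"
    return(res)
  }
  res$peak_lo <- pk[[1]]; res$peak_hi <- pk[[2]]
  res$unimodal <- count_prominent_modes(sm, unimodal_rel_height) == 1L
  res$contains_prototype_gray <-
    pk[[1]] <= prototype$mean_gray && prototype$mean_gray <= pk[[2]]
  if (!res$contains_prototype_gray) {
    res$reason <- "prototype gray outside peak"
    return(res) # area deliberately left uncomputed (short-circuit)
  }
  res$area_under_peak <- sum(sm[(pk[[1]] + 1):(pk[[2]] + 1)])
  if (!res$unimodal) {
    res$reason <- "multimodal"
  } else if (res$area_under_peak < min_area) {
    res$reason <- "peak area too small"
  } else {
    res$valid <- TRUE
  }
  res
}

default_search_config <- function() {
  list(
    s_steps = 8L,
    c_grid = seq(1, 29, by = 2),
    sg_window = 11L,
    sg_polyorder = 3L,
    unimodal_rel_height = 0.05,
    peak_eps = 0.02
  )
}

#' Search the adaptive-threshold parameter grid
#'
#' Iterates the subregion size `s` upward from the prototype's largest
#' bounding-box dimension (rounded up to odd; `s` must exceed the colony
#' size or segments go donut-shaped) and the offset `C` over a bounded
#' grid. Every (s, C) binarization is assessed against the histogram
#' criteria; among valid assessments the pair with the largest area under
#' the peak wins (ties resolved toward smaller s, then smaller C, by
#' iteration order).
#'
#' @param gray integer grayscale matrix.
#' @param prototype the governing [extract_prototype()] prototype.
#' @param config list overriding [default_search_config()] entries
#'   (`s_steps`, `c_grid`, `sg_window`, `sg_polyorder`,
#'   `unimodal_rel_height`, `peak_eps`).
#' @param restrict optional logical matrix; pixels outside it (e.g. outside
#'   the plate ROI, or belonging to another color class) are forced to
#'   background before assessment.
#' @param min_area minimum area under the peak for a valid assessment;
#'   defaults to the prototype pixel count (a valid binarization must
#'   capture at least one colony's worth of foreground).
#' @return list with `params` ([threshold_params()]), `mask` (0/255
#'   matrix, restricted), and `assessment`.
#' @export
search_threshold_params <- function(gray, prototype, config = list(),
                                    restrict = NULL, min_area = NULL) {
  cfg <- utils::modifyList(default_search_config(), config)
  if (is.null(min_area)) min_area <- prototype$n_pixels
  s0 <- max(prototype$bbox_w, prototype$bbox_h)
  if (s0 %% 2 == 0) s0 <- s0 + 1L
  s0 <- max(s0, 3L)
  delta <- max(2L, s0 %/% 4L)
  s_grid <- s0 + 2L * delta * (seq_len(cfg$s_steps) - 1L)
  keep <- if (is.null(restrict)) NULL else which(restrict)
  best <- NULL
  best_partial <- NULL
  grayv <- as.integer(gray)
  for (s in s_grid) {
    M <- local_gaussian_mean(gray, s)
    margin <- M - gray # foreground at offset C <=> margin > C
    if (!is.null(keep)) {
      mv <- margin[keep]; gv <- grayv[keep]
    } else {
      mv <- as.numeric(margin); gv <- grayv
    }
    for (C in cfg$c_grid) {
      hist_raw <- tabulate(gv[mv > C] + 1L, 256L)
      a <- assess_histogram(hist_raw, prototype, cfg, min_area)
      if (a$valid) {
        if (is.null(best) || a$area_under_peak > best$assessment$area_under_peak)
          best <- list(params = threshold_params(s, C), assessment = a)
      } else if (is.null(best_partial) ||
                 isTRUE(a$contains_prototype_gray) > isTRUE(best_partial$assessment$contains_prototype_gray)) {
        best_partial <- list(params = threshold_params(s, C), assessment = a)
      }
    }
  }
  if (is.null(best))
    cfu_error("cfuseg_search_error", paste0(
      "no (s, C) combination produced a valid binarization for prototype '",
      prototype$color_label, "' (last failure: ",
      if (is.null(best_partial)) "none assessed" else best_partial$assessment$reason,
      "); check the seed point or widen the search grids"),
      data = best_partial)
  mask <- adaptive_binarize(gray, best$params)
  if (!is.null(restrict)) mask[!restrict] <- 0L
  list(params = best$params, mask = mask, assessment = best$assessment)
}

# assessment from a precomputed raw histogram (search fast path; identical
# criteria to assess_binarization)
assess_histogram <- function(raw, prototype, cfg, min_area) {
  res <- structure(list(
    raw_hist = raw, smoothed = NULL, peak_lo = NA_integer_,
    peak_hi = NA_integer_, unimodal = FALSE,
    contains_prototype_gray = FALSE, area_under_peak = NA_real_,
    valid = FALSE, reason = ""
  ), class = "histogram_assessment")
  if (sum(raw) == 0L) { res$reason <- "empty foreground"; return(res) }
  sm <- pmax(smooth_savgol(raw, cfg$sg_window, cfg$sg_polyorder), 0)
  res$smoothed <- sm
  pk <- tryCatch(find_peak_range(sm, eps = cfg$peak_eps * max(sm)),
                 cfuseg_nopeak_error = function(e) NULL)
  if (is.null(pk)) { res$reason <- "no peak"; return(res) }
  res$peak_lo <- pk[[1]]; res$peak_hi <- pk[[2]]
  res$unimodal <- count_prominent_modes(sm, cfg$unimodal_rel_height) == 1L
  res$contains_prototype_gray <-
    pk[[1]] <= prototype$mean_gray && prototype$mean_gray <= pk[[2]]
  if (!res$contains_prototype_gray) {
    res$reason <- "prototype gray outside peak"
    return(res)
  }
  res$area_under_peak <- sum(sm[(pk[[1]] + 1):(pk[[2]] + 1)])
  if (!res$unimodal) res$reason <- "multimodal"
  else if (res$area_under_peak < min_area) res$reason <- "peak area too small"
  else res$valid <- TRUE
  res
}

#' Combine per-color masks with a logical OR
#'
#' @param masks list of 0/255 (or logical) matrices of identical shape.
#' @return integer 0/255 matrix, the pixelwise union.
#' @export
combine_color_masks <- function(masks) {
  if (length(masks) == 0L) cfu_error("cfuseg_param_error", "no masks supplied")
  d <- dim(masks[[1]])
  acc <- matrix(FALSE, d[1], d[2])
  for (m in masks) {
    if (!all(dim(m) == d))
      cfu_error("cfuseg_param_error", "masks must share the same shape")
    acc <- acc | (if (is.logical(m)) m else m != 0L)
  }
  out <- matrix(0L, d[1], d[2])
  out[acc] <- 255L
  out
}
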