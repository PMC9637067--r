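# Independent brute-force oracles. Each re-derives an operation's expected
# output by direct enumeration / per-window fitting, sharing no code path
# with the implementation it checks.

# per-pixel kxk neighborhood median with edge replication
oracle_median <- function(mat, k) {
  H <- nrow(mat); W <- ncol(mat); r <- k %/% 2
  out <- mat
  for (y in 1:H) for (x in 1:W) {
    ys <- pmin(pmax((y - r):(y + r), 1), H)
    xs <- pmin(pmax((x - r):(x + r), 1), W)
    out[y, x] <- sort(as.vector(mat[ys, xs]))[(k * k) %/% 2 + 1]
  }
  out
}

# per-pixel Gaussian-weighted window mean + threshold formula, evaluated by
# explicit 2-D window gathering with replicate padding
oracle_adaptive_binarize <- function(gray, s, C) {
  g1 <- gaussian_kernel1d(s)
  Wt <- outer(g1, g1)
  H <- nrow(gray); W <- ncol(gray); r <- s %/% 2
  out <- matrix(0L, H, W)
  for (y in 1:H) for (x in 1:W) {
    ys <- pmin(pmax((y - r):(y + r), 1), H)
    xs <- pmin(pmax((x - r):(x + r), 1), W)
    Tm <- sum(Wt * gray[ys, xs]) - C
    if (gray[y, x] < Tm) out[y, x] <- 255L
  }
  out
}

# explicit per-window least-squares polynomial fit, center evaluation;
# edges by fitting the first/last full window and predicting the margin
oracle_savgol <- function(y, window, polyorder) {
  n <- length(y); h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in (h + 1):(n - h)) {
    xs <- (-h):h
    fit <- stats::lm.fit(outer(xs, 0:polyorder, `^`), y[(i - h):(i + h)])
    out[i] <- fit$coefficients[1]
  }
  xs <- 0:(window - 1)
  fit <- stats::lm.fit(outer(xs, 0:polyorder, `^`), y[1:window])
  out[1:h] <- drop(outer(0:(h - 1), 0:polyorder, `^`) %*% fit$coefficients)
  fit <- stats::lm.fit(outer(xs, 0:polyorder, `^`), y[(n - window + 1):n])
  out[(n - h + 1):n] <-
    drop(outer((window - h):(window - 1), 0:polyorder, `^`) %*% fit$coefficients)
  out
}

# density-reachability DBSCAN oracle: clusters as connected components of
# the core-point graph (BFS over cores), numbered by their lowest core
# index; border points go to the earliest-numbered cluster owning a core
# neighbor; everything else is -1
oracle_dbscan <- function(X, eps, minPts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  core <- rowSums(D <= eps) >= minPts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    comp <- i
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        nb <- which(core & D[p, ] <= eps)
        nb <- setdiff(nb, comp)
        comp <- c(comp, nb)
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    labels[comp] <- cl
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != -1L) next
    owners <- labels[core & D[i, ] <= eps]
    owners <- owners[owners != -1L]
    if (length(owners)) labels[i] <- min(owners)
  }
  labels
}

# exhaustive prominence oracle: enumerate plateau regional maxima of v
# within region; a maximum is a marker iff no dominating maximum is
# connected to it at threshold (peak - tol), i.e. its saddle lies deeper
# than tol below the peak (the global maximum keys off the region minimum).
# Returns marker coordinates (plateau centroid snapped to nearest plateau
# pixel), sorted by (x, y), as the implementation emits them.
oracle_prominence_markers <- function(v, region, tol) {
  H <- nrow(v); W <- ncol(v)
  vr <- v
  vr[!region] <- -Inf
  lab8 <- function(mask) cfuseg:::.label_components_cpp(mask, 8L)
  # plateau components of equal value
  maxima <- list()
  seen <- matrix(FALSE, H, W)
  for (idx in which(region)) {
    if (seen[idx]) next
    val <- vr[idx]
    plat <- lab8(region & vr == val)
    comp <- plat == plat[idx] & plat > 0L
    seen[comp] <- TRUE
    # regional maximum: no neighbor (8) outside comp with higher value
    ys <- (which(comp) - 1L) %% H + 1L
    xs <- (which(comp) - 1L) %/% H + 1L
    is_max <- TRUE
    for (j in seq_along(xs)) {
      for (ddx in -1:1) for (ddy in -1:1) {
        xx <- xs[j] + ddx; yy <- ys[j] + ddy
        if (xx < 1 || xx > W || yy < 1 || yy > H) next
        if (!comp[yy, xx] && region[yy, xx] && vr[yy, xx] > val) is_max <- FALSE
      }
      if (!is_max) break
    }
    if (is_max)
      maxima[[length(maxima) + 1L]] <-
        list(value = val, pixels = which(comp), rank = min(which(comp)))
  }
  if (!length(maxima)) return(matrix(integer(0), 0, 2))
  vmin <- min(vr[region])
  pts <- list()
  for (m in maxima) {
    thr <- m$value - tol
    above <- region & vr >= thr
    cc <- lab8(above)
    my <- cc[m$pixels[1]]
    dominated <- FALSE
    for (o in maxima) {
      if (identical(o$pixels, m$pixels)) next
      stronger <- o$value > m$value ||
        (o$value == m$value && o$rank < m$rank)
      if (stronger && any(cc[o$pixels] == my)) { dominated <- TRUE; break }
    }
    prom_ok <- if (dominated) FALSE else TRUE
    # for never-dominated maxima (global or isolated), prominence is
    # height above the region minimum (or the saddle below every stronger
    # peak, already > tol if not dominated at thr)
    if (!dominated && m$value - vmin <= tol) prom_ok <- FALSE
    if (prom_ok) {
      py <- (m$pixels - 1L) %% H
      px <- (m$pixels - 1L) %/% H
      cx <- mean(px); cy <- mean(py)
      d2 <- (px - cx)^2 + (py - cy)^2
      j <- which(d2 == min(d2))
      j <- j[which.min(m$pixels[j])]
      pts[[length(pts) + 1L]] <- c(px[j], py[j])
    }
  }
  out <- do.call(rbind, pts)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
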