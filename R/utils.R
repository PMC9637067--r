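# Shared small helpers: circular hue arithmetic, error constructors,
# seeded evaluation.

#' Circular distance between hue angles
#'
#' Hue lives on a 360-degree circle, so the distance between two hues is the
#' shorter arc: `min(|a - b|, 360 - |a - b|)`. Vectorized over both arguments.
#'
#' @param a,b hue angles in degrees (any real; reduced mod 360).
#' @return numeric vector of distances in `[0, 180]`.
#' @export
hue_distance <- function(a, b) {
  d <- abs((a %% 360) - (b %% 360))
  pmin(d, 360 - d)
}

#' Circular mean of hue angles
#'
#' Mean direction of angles in degrees, computed from the resultant vector.
#' An empty input or a zero resultant (perfectly balanced angles) returns 0.
#'
#' @param h hue angles in degrees.
#' @param w optional non-negative weights.
#' @return mean angle in `[0, 360)`.
#' @export
circular_mean_deg <- function(h, w = NULL) {
  if (length(h) == 0L) return(0)
  r <- h * pi / 180
  if (is.null(w)) w <- rep(1, length(h))
  s <- sum(w * sin(r)); c <- sum(w * cos(r))
  if (abs(s) < 1e-12 && abs(c) < 1e-12) return(0)
  (atan2(s, c) * 180 / pi) %% 360
}

#' Circular standard deviation of hue angles
#'
#' `sqrt(-2 log R)` (in degrees), where R is the mean resultant length; 0 for
#' fewer than two angles.
#'
#' @param h hue angles in degrees.
#' @return circular SD in degrees.
#' @export
circular_sd_deg <- function(h) {
  if (length(h) < 2L) return(0)
  r <- h * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

# classed conditions so callers/tests can discriminate failure modes
cfu_error <- function(class, msg, ..., data = NULL) {
  stop(structure(
    class = c(class, "cfuseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  ))
}

check_odd_kernel <- function(k, what = "kernel") {
  if (length(k) != 1L || is.na(k) || k < 3 || k %% 2 == 0)
    cfu_error("cfuseg_param_error",
              sprintf("%s must be an odd integer >= 3 (got %s)", what,
                      paste(k, collapse = ",")))
  invisible(as.integer(k))
}

# run code with a private RNG stream, restoring .Random.seed afterwards
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
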