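#' Detect ladder band peaks in a reference lane
#'
#' Finds local maxima in a lightly smoothed ladder profile, keeps those whose
#' topographic prominence exceeds `prominence` times the median absolute
#' deviation of the profile, refines each center by parabolic interpolation,
#' and assigns peaks to the expected band sizes in rank order of distance
#' (largest size = smallest distance, since mobility is monotone in size).
#'
#' @param ladder_profile an [intensity_profile()] of the size-reference lane.
#' @param expected_sizes band sizes in nt (at least 2).
#' @param prominence multiple of the profile MAD a peak's prominence must
#'   exceed (default 5).
#' @param smooth_k width, in samples, of the light running-mean smoothing
#'   applied before peak search (default 3).
#'
#' @return A `data.frame` with columns `distance_mm` and `size_nt`, one row
#'   per detected band.  Expected sizes that could not be matched to a peak
#'   are reported in the `unmatched_sizes` attribute and via a warning,
#'   never silently dropped.  Errors if fewer than 2 peaks are found or if
#'   more peaks than expected bands survive the prominence filter.
#' @export
detect_ladder_peaks <- function(ladder_profile, expected_sizes,
                                prominence = 5, smooth_k = 3) {
  stopifnot(inherits(ladder_profile, "intensity_profile"))
  expected_sizes <- sort(unique(as.numeric(expected_sizes)),
                         decreasing = TRUE)
  if (length(expected_sizes) < 2L) {
    stop("at least 2 expected band sizes are required", call. = FALSE)
  }
  d <- ladder_profile$distance_mm
  y <- ladder_profile$intensity_au
  ys <- roll_mean(y, smooth_k)
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  if (n < 3L || stats::sd(ys) == 0) {
    stop("no peaks detected in ladder profile", call. = FALSE)
  }
  cand <- which(ys[-c(1L, n)] > ys[-c(n - 1L, n)] &
                  ys[-c(1L, n)] >= ys[-c(1L, 2L)]) + 1L
  if (length(cand) == 0L) {
    stop("no peaks detected in ladder profile", call. = FALSE)
  }
  prom <- vapply(cand, function(i) {
    higher_l <- which(ys[seq_len(i - 1L)] > ys[i])
    lo_l <- min(ys[seq(if (length(higher_l)) max(higher_l) else 1L, i)])
    higher_r <- which(ys[seq(i, n)] > ys[i])
    lo_r <- min(ys[seq(i, if (length(higher_r)) i - 1L + min(higher_r) else n)])
    ys[i] - max(lo_l, lo_r)
  }, numeric(1))
  thr <- prominence * stats::mad(ys)
  keep <- cand[prom > thr & prom > 0]
  if (length(keep) < 2L) {
    stop("fewer than 2 ladder peaks detected after prominence filtering",
         call. = FALSE)
  }
  if (length(keep) > length(expected_sizes)) {
    stop(sprintf(paste0("detected %d peaks but only %d expected band sizes; ",
                        "raise the prominence threshold or review the lane"),
                 length(keep), length(expected_sizes)), call. = FALSE)
  }
  # parabolic sub-sample refinement of each center
  centers <- vapply(keep, function(i) {
    if (i <= 1L || i >= n) return(d[i])
    den <- ys[i - 1L] - 2 * ys[i] + ys[i + 1L]
    if (den >= 0) return(d[i])
    d[i] + 0.5 * (ys[i - 1L] - ys[i + 1L]) / den * (d[i + 1L] - d[i])
  }, numeric(1))
  centers <- sort(centers)
  matched <- expected_sizes[seq_along(centers)]
  unmatched <- setdiff(expected_sizes, matched)
  if (length(unmatched)) {
    warning("unmatched expected ladder sizes (nt): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  structure(data.frame(distance_mm = centers, size_nt = matched),
            unmatched_sizes = unmatched)
}

#' Fit the log-linear electrophoretic mobility model to ladder peaks
#'
#' Ordinary least squares of migration distance on the natural log of band
#' size, `lm(distance ~ log(size))`, exactly in that direction; the inverse
#' map `size = exp((d - a) / b)` is then applied analytically by
#' [size_at()].  Under the model, a fragment of 1 nt would migrate to
#' `d = a`.
#'
#' @param peaks `data.frame` with columns `distance_mm` and `size_nt` (at
#'   least 2 distinct sizes), e.g. from [detect_ladder_peaks()].
#' @param size_range optional `c(min, max)` size filter (nt) restricting the
#'   fit to bands within the gel's resolving range.
#'
#' @return An object of class `ladder_calibration` with elements `a`
#'   (intercept, mm), `b` (slope, mm per ln nt), `peaks`, `r_squared` and
#'   `residual_sd` (mm).
#' @export
fit_ladder <- function(peaks, size_range = NULL) {
  peaks <- as.data.frame(peaks)
  if (!all(c("distance_mm", "size_nt") %in% names(peaks))) {
    stop("`peaks` needs columns distance_mm and size_nt", call. = FALSE)
  }
  if (!is.null(size_range)) {
    peaks <- peaks[peaks$size_nt >= size_range[1] &
                     peaks$size_nt <= size_range[2], , drop = FALSE]
  }
  if (nrow(peaks) < 2L || length(unique(peaks$size_nt)) < 2L) {
    stop("ladder fit needs at least 2 peaks with distinct sizes",
         call. = FALSE)
  }
  fit <- stats::lm(distance_mm ~ log(size_nt), data = peaks)
  cf <- stats::coef(fit)
  if (!is.finite(cf[2L]) || cf[2L] == 0) {
    stop("degenerate ladder fit: slope is zero", call. = FALSE)
  }
  res <- stats::residuals(fit)
  tss <- sum((peaks$distance_mm - mean(peaks$distance_mm))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  rsd <- if (fit$df.residual > 0) sqrt(sum(res^2) / fit$df.residual) else 0
  structure(list(a = unname(cf[1L]), b = unname(cf[2L]),
                 peaks = peaks[order(-peaks$size_nt), ],
                 r_squared = r2, residual_sd = rsd,
                 distance_range = range(peaks$distance_mm)),
            class = "ladder_calibration")
}

#' Convert electrophoretic distance to fragment size
#'
#' The inverse of the fitted mobility model: `size = exp((d - a) / b)`.
#' Strictly monotone in `d` (decreasing for `b < 0`).  Extrapolation beyond
#' the fitted peak range is allowed; the returned vector carries a logical
#' `extrapolated` attribute flagging such distances.
#'
#' @param d distances in mm (vectorized).
#' @param cal a `ladder_calibration` from [fit_ladder()].
#' @return Sizes in nt.
#' @export
size_at <- function(d, cal) {
  stopifnot(inherits(cal, "ladder_calibration"))
  sz <- exp((d - cal$a) / cal$b)
  structure(sz, extrapolated = d < cal$distance_range[1L] |
              d > cal$distance_range[2L])
}

#' Migration distance of a fragment size under a calibration
#' @param size_nt sizes in nt.
#' @param cal a `ladder_calibration`.
#' @return Distances in mm.
#' @export
distance_at <- function(size_nt, cal) {
  stopifnot(inherits(cal, "ladder_calibration"))
  cal$a + cal$b * log(size_nt)
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat("Ladder calibration: d = a + b * ln(size)\n")
  cat(sprintf("  a = %.4g mm, b = %.4g mm/ln(nt)\n", x$a, x$b))
  cat(sprintf("  %d peaks, r^2 = %.5f, residual SD = %.3g mm\n",
              nrow(x$peaks), x$r_squared, x$residual_sd))
  invisible(x)
}

#' @export
coef.ladder_calibration <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.ladder_calibration <- function(object, newdata, ...) {
  size_at(newdata, object)
}

#' @export
plot.ladder_calibration <- function(x, ...) {
  graphics::plot(x$peaks$size_nt, x$peaks$distance_mm, log = "x",
                 xlab = "band size (nt)", ylab = "distance (mm)",
                 main = "ladder calibration", ...)
  sz <- exp(seq(log(min(x$peaks$size_nt)), log(max(x$peaks$size_nt)),
                length.out = 100))
  graphics::lines(sz, x$a + x$b * log(sz), col = 2)
  invisible(x)
}
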