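#' Subtract the background intensity from a lane profile
#'
#' Three estimators are offered: `"constant"` removes the minimum intensity
#' of the lane; `"linear_baseline"` iteratively fits a straight line and
#' clamps the working copy to it, converging to the lower linear envelope of
#' the profile; `"empty_lane"` subtracts the running-median trend of an
#' empty-lane profile measured on the same gel.  Negative residuals are
#' clipped to zero and the background estimate is stored in the profile
#' metadata.
#'
#' @param profile an [intensity_profile()].
#' @param method background model, see above.
#' @param empty an [intensity_profile()] of an empty lane; required for
#'   `method = "empty_lane"`.
#' @param iterations iterations of the envelope fit for
#'   `"linear_baseline"`.
#' @return A background-subtracted [intensity_profile()] (clipped at 0).
#' @export
subtract_background <- function(profile,
                                method = c("constant", "linear_baseline",
                                           "empty_lane"),
                                empty = NULL, iterations = 30) {
  stopifnot(inherits(profile, "intensity_profile"))
  method <- match.arg(method)
  d <- profile$distance_mm
  y <- profile$intensity_au
  bg <- switch(method,
    constant = rep(min(y), length(y)),
    linear_baseline = {
      w <- y
      X <- cbind(1, d)
      base <- y
      for (i in seq_len(iterations)) {
        cf <- stats::lm.fit(X, w)$coefficients
        base <- cf[1L] + cf[2L] * d
        w <- pmin(w, base)
      }
      # staining backgrounds are nonnegative; a steep lane must not push
      # the envelope line below zero and inflate the opposite end
      pmax(base, 0)
    },
    empty_lane = {
      if (is.null(empty)) {
        stop("method = \"empty_lane\" requires an empty-lane profile",
             call. = FALSE)
      }
      stopifnot(inherits(empty, "intensity_profile"))
      ei <- stats::approx(empty$distance_mm, empty$intensity_au, xout = d,
                          rule = 2)$y
      k <- max(3L, 2L * floor(2.5 / max(diff(d))) + 1L)
      k <- min(k, 2L * floor((length(ei) - 1L) / 2L) + 1L)
      stats::runmed(ei, k)
    })
  update_profile(profile, pmax(y - bg, 0),
                 extra_meta = list(background_method = method,
                                   background_mean_au = mean(bg)))
}

#' Smooth a lane profile with a penalized cubic spline
#'
#' Fits a cubic smoothing spline with a fixed set of 15 interior knots
#' (plus the two boundary knots) and a roughness penalty chosen by
#' generalized cross-validation.  By default the interior knots are placed
#' at quantiles of the cumulative absolute intensity gradient, concentrating
#' flexibility where the profile changes fast; uniform placement is
#' available as an alternative.  Smoothed values are clipped at 0, since
#' staining intensity cannot be negative.
#'
#' @param profile an [intensity_profile()] (background-subtracted).
#' @param n_knots number of interior knots (default 15).
#' @param knot_placement `"gradient"` (default) or `"uniform"`.
#' @return The smoothed [intensity_profile()], evaluated at the input
#'   distances.
#' @export
smooth_profile <- function(profile, n_knots = 15,
                           knot_placement = c("gradient", "uniform")) {
  stopifnot(inherits(profile, "intensity_profile"))
  knot_placement <- match.arg(knot_placement)
  d <- profile$distance_mm
  y <- profile$intensity_au
  n <- length(d)
  if (n < n_knots + 4L) {
    stop(sprintf("profile has %d samples; at least %d required for %d knots",
                 n, n_knots + 4L, n_knots), call. = FALSE)
  }
  interior <- NULL
  if (knot_placement == "gradient") {
    g <- abs(diff(y))
    total <- sum(g)
    if (total > 0) {
      # gradient-weighted knot measure with a uniform floor: sharp bands
      # attract knots, but long low-signal stretches always keep coverage
      # (an unconstrained cubic tail next to a tall peak oscillates badly)
      m <- length(g)
      F <- 2 / 3 * cumsum(g) / total + 1 / 3 * seq_len(m) / m
      mid <- (d[-1L] + d[-n]) / 2
      targets <- seq_len(n_knots) / (n_knots + 1)
      interior <- stats::approx(F, mid, xout = targets, rule = 2,
                                ties = "ordered")$y
    }
  }
  if (is.null(interior)) {
    interior <- stats::quantile(d, probs = seq_len(n_knots) / (n_knots + 1),
                                names = FALSE)
  }
  knots <- sort(unique(c(d[1L], interior, d[n])))
  if (length(knots) < 4L) {
    knots <- seq(d[1L], d[n], length.out = n_knots + 2L)
  }
  kn <- (knots - d[1L]) / (d[n] - d[1L])
  fit <- stats::smooth.spline(d, y, all.knots = kn, keep.data = FALSE)
  ys <- pmax(stats::predict(fit, d)$y, 0)
  update_profile(profile, ys,
                 extra_meta = list(smoothing = list(n_knots = n_knots,
                                                    placement = knot_placement,
                                                    lambda = fit$lambda,
                                                    knots_mm = knots)))
}

#' Resample a smoothed profile into constant-width distance intervals
#'
#' Partitions the lane into intervals of width `delta_d` (default 1 mm),
#' integrates the smoothed intensity over each interval (AU x mm) and
#' attaches the characteristic fragment size of the interval midpoint via
#' the ladder calibration.
#'
#' @param profile a smoothed [intensity_profile()].
#' @param cal a `ladder_calibration` from [fit_ladder()].
#' @param delta_d interval width in mm (> 0).
#' @return An `interval_series`: a `data.frame` with columns `mid_mm`,
#'   `width_mm`, `size_nt`, `intensity_au` (integrated) and `excluded`
#'   (all `FALSE` until [determine_cutoff()] is applied), carrying the
#'   calibration and lane id as attributes.
#' @export
resample_intervals <- function(profile, cal, delta_d = 1.0) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(cal, "ladder_calibration"))
  if (delta_d <= 0) stop("delta_d must be > 0", call. = FALSE)
  d <- profile$distance_mm
  n_int <- floor((d[length(d)] - d[1L]) / delta_d)
  if (n_int < 1L) stop("profile shorter than one interval", call. = FALSE)
  edges <- d[1L] + delta_d * (0:n_int)
  f <- stats::approxfun(d, profile$intensity_au, rule = 2)
  nsub <- 20L
  I <- vapply(seq_len(n_int), function(j) {
    xs <- seq(edges[j], edges[j + 1L], length.out = nsub + 1L)
    trapz(xs, f(xs))
  }, numeric(1))
  mids <- (edges[-1L] + edges[-(n_int + 1L)]) / 2
  sz <- as.numeric(size_at(mids, cal))
  structure(
    data.frame(mid_mm = mids, width_mm = delta_d, size_nt = sz,
               intensity_au = I, excluded = FALSE),
    calibration = cal,
    lane_id = lane_id(profile),
    cutoff = NULL,
    class = c("interval_series", "data.frame")
  )
}

#' Determine the signal-to-noise cutoff distance of a lane
#'
#' Finds the distance beyond which fluctuations of the raw (unsmoothed)
#' lane intensities become comparable in magnitude to those of an empty
#' lane, indicating that no reliable DNA signal remains.  Both profiles are
#' detrended with a running median and their rolling standard deviations
#' compared; the cutoff `d_max` is the smallest distance from which the
#' lane's local SD stays below `ratio_threshold` times the empty lane's
#' local SD for the remainder of the gel.  The implied minimum detectable
#' fragment size is `sz_min = exp((d_max - a) / b)`.  A manual `d_max`
#' override is supported, honoring supervised cutoff selection.
#'
#' @param series an `interval_series` from [resample_intervals()].
#' @param lane_profile the raw (unsmoothed) lane [intensity_profile()].
#' @param empty_profile the empty-lane [intensity_profile()] (interpolated
#'   onto the lane grid if sampled differently).
#' @param window rolling window width in mm (default 3).
#' @param ratio_threshold lane-to-empty SD ratio below which the signal is
#'   considered lost (default 1.5).
#' @param d_max optional manual cutoff in mm, bypassing the automatic rule.
#' @return The series with intervals beyond `d_max` flagged `excluded` and a
#'   `cutoff` attribute `list(d_max_mm, sz_min_nt, manual, crossed)`.  If
#'   the SD ratio never crosses the threshold, `d_max` is set to the lane
#'   end and a warning is issued.
#' @export
determine_cutoff <- function(series, lane_profile = NULL,
                             empty_profile = NULL, window = 3,
                             ratio_threshold = 1.5, d_max = NULL) {
  stopifnot(inherits(series, "interval_series"))
  cal <- attr(series, "calibration")
  crossed <- TRUE
  manual <- !is.null(d_max)
  if (is.null(d_max)) {
    if (is.null(lane_profile) || is.null(empty_profile)) {
      stop("automatic cutoff needs both the raw lane and an empty lane",
           call. = FALSE)
    }
    d <- lane_profile$distance_mm
    y <- lane_profile$intensity_au
    e <- stats::approx(empty_profile$distance_mm,
                       empty_profile$intensity_au, xout = d, rule = 2)$y
    step <- stats::median(diff(d))
    k <- max(3L, 2L * floor(window / step / 2) + 1L)
    detrend <- function(v) v - stats::runmed(v, min(k, 2L *
                                                      floor((length(v) - 1L) / 2L) + 1L))
    r_lane <- detrend(y)
    r_empty <- detrend(e)
    # fluctuation magnitude of everything beyond each distance: tail SDs
    # pool hundreds of samples, so the comparison is far more stable than a
    # single rolling window deep in the noise region
    tail_sd <- function(r) {
      n <- length(r)
      s2 <- rev(cumsum(rev(r^2)))
      s1 <- rev(cumsum(rev(r)))
      cnt <- n - seq_len(n) + 1L
      sqrt(pmax(s2 / cnt - (s1 / cnt)^2, 0))
    }
    ok <- tail_sd(r_lane) < ratio_threshold * tail_sd(r_empty)
    # judge only where the tail still holds enough samples for a stable SD
    valid <- seq_len(max(1L, length(d) - max(k, 20L)))
    i <- which(ok[valid])
    if (length(i) == 0L) {
      d_max <- d[length(d)]
      crossed <- FALSE
      warning("lane fluctuations never fell to the empty-lane level; ",
              "d_max set to the lane end", call. = FALSE)
    } else {
      d_max <- d[valid[min(i)]]
    }
  }
  sz_min <- as.numeric(size_at(d_max, cal))
  series$excluded <- series$mid_mm > d_max
  attr(series, "cutoff") <- list(d_max_mm = d_max, sz_min_nt = sz_min,
                                 manual = manual, crossed = crossed)
  series
}

#' @export
print.interval_series <- function(x, ...) {
  co <- attr(x, "cutoff")
  cat(sprintf("Interval series '%s': %d intervals of %.3g mm\n",
              attr(x, "lane_id") %||% NA, nrow(x), x$width_mm[1L]))
  if (!is.null(co)) {
    cat(sprintf("  cutoff d_max = %.4g mm (sz_min = %.4g nt), %d excluded\n",
                co$d_max_mm, co$sz_min_nt, sum(x$excluded)))
  }
  invisible(x)
}
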