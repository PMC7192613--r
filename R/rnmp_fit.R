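#' Estimate genomic ribonucleotides from one gel lane
#'
#' End-to-end per-lane quantitation: calibrates the distance-to-size map
#' from the ladder, subtracts background from the sample lane, smooths it
#' with a 15-knot penalized cubic spline, resamples into constant-width
#' intervals, determines the signal-to-noise cutoff against an empty lane,
#' converts intensities to molar fragment counts, normalizes per Gb,
#' estimates the ribonucleotide total per genome with the truncation
#' correction, and (optionally) subtracts a matched control lane.
#'
#' @param lane raw [intensity_profile()] of the sample lane.
#' @param ladder the size reference: a fitted `ladder_calibration`, a
#'   ladder-lane [intensity_profile()], or a `data.frame` of
#'   `(distance_mm, size_nt)` peaks.
#' @param ladder_sizes expected ladder band sizes in nt, used when `ladder`
#'   is a profile (default [ladder_1kb_plus()]).
#' @param empty empty-lane [intensity_profile()] for the automatic cutoff
#'   and (optionally) for background subtraction.
#' @param control a fitted `rnmp_fit` or corrected `rnmp_estimate` of the
#'   matched control lane; when supplied, `N_net` is computed.
#' @param background background-subtraction method, see
#'   [subtract_background()].
#' @param n_knots interior spline knots (default 15).
#' @param delta_d resampling interval width in mm (default 1).
#' @param genome_size haploid genome length in nt (default 24e6).
#' @param d_max manual cutoff distance in mm (overrides the automatic
#'   rule).
#' @param window,ratio_threshold automatic-cutoff parameters, see
#'   [determine_cutoff()].
#' @param size_range optional ladder size filter passed to [fit_ladder()].
#' @param subtraction_order see [subtract_control()].
#'
#' @return An object of class `rnmp_fit` with components `calibration`,
#'   `profiles` (raw, corrected, smoothed), `intervals`, `counts`
#'   (normalized `fragment_count_table`), `estimate` (`rnmp_estimate`) and
#'   `cutoff`.  Methods: `print`, `summary`, `coef`, `plot`, `fitted`,
#'   `residuals`.
#'
#' @examples
#' brk <- genome_break_config(n_rnmp = 5000, n_molecules = 50, seed = 1)
#' gel <- gel_render_config(noise_sd = 1, background = 5, seed = 2)
#' fit <- rnmp_fit(render_lane(simulate_fragments(brk), gel, "mut"),
#'                 ladder = render_ladder(gel),
#'                 empty  = render_empty_lane(gel))
#' coef(fit)
#' @export
rnmp_fit <- function(lane, ladder, ladder_sizes = ladder_1kb_plus(),
                     empty = NULL, control = NULL,
                     background = c("linear_baseline", "constant",
                                    "empty_lane"),
                     n_knots = 15, delta_d = 1.0, genome_size = 24e6,
                     d_max = NULL, window = 3, ratio_threshold = 1.5,
                     size_range = NULL,
                     subtraction_order = c("correct_then_subtract",
                                           "subtract_then_correct")) {
  stopifnot(inherits(lane, "intensity_profile"))
  background <- match.arg(background)
  subtraction_order <- match.arg(subtraction_order)
  cal <- if (inherits(ladder, "ladder_calibration")) {
    ladder
  } else if (inherits(ladder, "intensity_profile")) {
    fit_ladder(detect_ladder_peaks(ladder, ladder_sizes),
               size_range = size_range)
  } else {
    fit_ladder(ladder, size_range = size_range)
  }
  corrected <- subtract_background(lane, method = background, empty = empty)
  smoothed <- smooth_profile(corrected, n_knots = n_knots)
  intervals <- resample_intervals(smoothed, cal, delta_d = delta_d)
  if (is.null(d_max) && is.null(empty)) {
    warning("no empty lane and no manual d_max; cutoff set to the lane end",
            call. = FALSE)
    d_max <- max(lane$distance_mm)
  }
  intervals <- determine_cutoff(intervals, lane_profile = lane,
                                empty_profile = empty, window = window,
                                ratio_threshold = ratio_threshold,
                                d_max = d_max)
  counts <- normalize_per_gb(counts_from_intensity(intervals))
  est <- correct_truncation(estimate_total(counts,
                                           genome_size = genome_size),
                            counts)
  if (!is.null(control)) {
    cest <- if (inherits(control, "rnmp_fit")) control$estimate else control
    est <- subtract_control(est, cest, order = subtraction_order)
  }
  structure(list(call = match.call(),
                 calibration = cal,
                 profiles = list(raw = lane, corrected = corrected,
                                 smoothed = smoothed),
                 intervals = intervals,
                 counts = counts,
                 estimate = est,
                 cutoff = attr(intervals, "cutoff"),
                 lane_id = lane_id(lane)),
            class = "rnmp_fit")
}

#' @export
print.rnmp_fit <- function(x, ...) {
  cat(sprintf("Genomic rNMP quantitation, lane '%s'\n", x$lane_id))
  cat(sprintf("  calibration: a = %.4g mm, b = %.4g mm/ln(nt), r^2 = %.4f\n",
              x$calibration$a, x$calibration$b, x$calibration$r_squared))
  co <- x$cutoff
  cat(sprintf("  cutoff: d_max = %.4g mm, sz_min = %.4g nt%s\n",
              co$d_max_mm, co$sz_min_nt,
              if (isTRUE(co$manual)) " (manual)" else ""))
  print(x$estimate)
  invisible(x)
}

#' @export
coef.rnmp_fit <- function(object, ...) {
  e <- object$estimate
  c(N_prelim = e$N_prelim, N_corr = e$N_corr, N_net = e$N_net,
    density_per_gb = density_per_gb(e))
}

#' @export
summary.rnmp_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rnmp_fit")
}

#' @export
print.summary.rnmp_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$calibration)
  inc <- !f$counts$excluded
  cat(sprintf("  %d/%d intervals included; mass check sum(sz*n_perGb) = %.6g\n",
              sum(inc), nrow(f$counts),
              sum(f$counts$size_nt[inc] * f$counts$n_per_gb[inc])))
  invisible(x)
}

#' @export
fitted.rnmp_fit <- function(object, ...) {
  object$profiles$smoothed$intensity_au
}

#' @export
residuals.rnmp_fit <- function(object, ...) {
  object$profiles$corrected$intensity_au -
    object$profiles$smoothed$intensity_au
}

#' @export
plot.rnmp_fit <- function(x, which = c("profile", "spectrum"), ...) {
  which <- match.arg(which)
  if (which == "profile") {
    p <- x$profiles$corrected
    graphics::plot(p$distance_mm, p$intensity_au, type = "l", col = "grey60",
                   xlab = "distance from well (mm)", ylab = "intensity (AU)",
                   main = sprintf("lane '%s'", x$lane_id), ...)
    graphics::lines(x$profiles$smoothed$distance_mm,
                    x$profiles$smoothed$intensity_au, col = 2, lwd = 2)
    graphics::abline(v = x$cutoff$d_max_mm, lty = 2)
  } else {
    ct <- x$counts[!x$counts$excluded, ]
    graphics::plot(ct$size_nt, ct$n_per_gb, log = "x", type = "h",
                   xlab = "fragment size (nt)", ylab = "fragments per Gb",
                   main = sprintf("size spectrum, lane '%s'", x$lane_id), ...)
  }
  invisible(x)
}
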