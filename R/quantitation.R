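#' Convert interval intensities to molar fragment counts
#'
#' Staining intensity is proportional to DNA mass, so the number of
#' molecules in a size interval is the integrated intensity divided by the
#' characteristic fragment size: `n_sz = I_sz / sz`.  Excluded (below
#' signal-to-noise) intervals are carried through but never counted.
#'
#' @param series an `interval_series` from [resample_intervals()]
#'   (optionally after [determine_cutoff()]).
#' @return A `fragment_count_table`: a `data.frame` with columns `mid_mm`,
#'   `size_nt`, `intensity_au`, `n_sz`, `n_per_gb` (`NA` until
#'   [normalize_per_gb()]) and `excluded`, with the cutoff and lane id as
#'   attributes.
#' @export
counts_from_intensity <- function(series) {
  stopifnot(inherits(series, "interval_series"))
  if (any(series$size_nt <= 0)) {
    stop("non-positive fragment size in interval series", call. = FALSE)
  }
  structure(
    data.frame(mid_mm = series$mid_mm, size_nt = series$size_nt,
               intensity_au = series$intensity_au,
               n_sz = series$intensity_au / series$size_nt,
               n_per_gb = NA_real_, excluded = series$excluded),
    cutoff = attr(series, "cutoff"),
    lane_id = attr(series, "lane_id"),
    class = c("fragment_count_table", "data.frame")
  )
}

#' Normalize fragment counts per 1 Gb of loaded DNA
#'
#' Rescales the molar counts so that the total DNA mass over the included
#' intervals is exactly 1 Gb: `n_sz(per 1Gb) = n_sz * 1e9 / sum(sz * n_sz)`.
#' This makes all downstream estimates independent of the amount of DNA
#' loaded in the lane.
#'
#' @param table a `fragment_count_table` from [counts_from_intensity()].
#' @return The table with `n_per_gb` filled in; after normalization
#'   `sum(size_nt * n_per_gb)` over included intervals equals `1e9` to
#'   numerical tolerance.
#' @export
normalize_per_gb <- function(table) {
  stopifnot(inherits(table, "fragment_count_table"))
  inc <- !table$excluded
  denom <- sum(table$size_nt[inc] * table$n_sz[inc])
  if (!is.finite(denom) || denom <= 0) {
    stop("cannot normalize: total included intensity mass is zero",
         call. = FALSE)
  }
  table$n_per_gb <- table$n_sz * 1e9 / denom
  table
}

#' Preliminary estimate of ribonucleotides per genome
#'
#' Sums the per-Gb fragment counts over the included intervals and rescales
#' from 1 Gb to the genome size: `N = sum(n_per_gb) * genome_size / 1e9`.
#' Each alkali fragment boundary marks one break, so the fragment count per
#' genome equivalent of DNA estimates the break (ribonucleotide) count.
#'
#' @param table a normalized `fragment_count_table`.
#' @param genome_size haploid genome length in nt (default 24e6).
#' @return An `rnmp_estimate` with `N_prelim` set.
#' @export
estimate_total <- function(table, genome_size = 24e6) {
  stopifnot(inherits(table, "fragment_count_table"))
  if (all(is.na(table$n_per_gb))) {
    stop("table is not normalized; run normalize_per_gb() first",
         call. = FALSE)
  }
  inc <- !table$excluded
  sum_n <- sum(table$n_per_gb[inc])
  structure(list(N_prelim = sum_n * genome_size / 1e9,
                 N_corr = NA_real_, N_net = NA_real_,
                 sum_n_per_gb = sum_n,
                 genome_size = genome_size,
                 cutoff = attr(table, "cutoff"),
                 lane_id = attr(table, "lane_id"),
                 control_lane_id = NA_character_,
                 subtraction_order = NA_character_),
            class = "rnmp_estimate")
}

#' Correct the ribonucleotide total for fragments beyond the cutoff
#'
#' Fragments smaller than `sz_min` migrate beyond `d_max` and are not
#' counted.  Assuming break points fall uniformly along the genome, the
#' censored count is recovered as
#' `N_corr = N * (2 - exp(-sz_min * sum(n_per_gb) / 1e9))`, where the sum
#' runs over the included intervals.  The correction factor lies in
#' `[1, 2]`; for non-uniform break placement it is conservative (it does
#' not overestimate the true total).
#'
#' @param est an `rnmp_estimate` from [estimate_total()].
#' @param table the normalized `fragment_count_table` the estimate came
#'   from (supplies `sz_min` and the per-Gb sum if absent from `est`).
#' @return The estimate with `N_corr` set.
#' @export
correct_truncation <- function(est, table = NULL) {
  stopifnot(inherits(est, "rnmp_estimate"))
  cutoff <- est$cutoff %||% attr(table, "cutoff")
  if (is.null(cutoff)) {
    stop("no cutoff metadata: run determine_cutoff() before correcting",
         call. = FALSE)
  }
  lambda <- cutoff$sz_min_nt * est$sum_n_per_gb / 1e9
  est$N_corr <- est$N_prelim * (2 - exp(-lambda))
  est$cutoff <- cutoff
  est
}

#' Subtract control-strain breakage from a ribonucleotide estimate
#'
#' Ribonucleotide-independent breaks arising during alkaline heat treatment
#' are measured in a matched control lane and subtracted:
#' `N_net = max(0, N_corr - N_corr(control))`.  Matching of control to
#' sample condition is the caller's responsibility and is recorded in the
#' estimate.  With `order = "subtract_then_correct"` the preliminary totals
#' are differenced first and the sample's truncation factor applied to the
#' difference.
#'
#' @param est corrected `rnmp_estimate` of the sample lane.
#' @param control corrected `rnmp_estimate` of the control lane.
#' @param order subtraction order (default corrects each lane, then
#'   subtracts).
#' @return The estimate with `N_net` set (floored at 0, with a warning when
#'   the control exceeds the sample).
#' @export
subtract_control <- function(est, control,
                             order = c("correct_then_subtract",
                                       "subtract_then_correct")) {
  stopifnot(inherits(est, "rnmp_estimate"),
            inherits(control, "rnmp_estimate"))
  order <- match.arg(order)
  if (is.na(est$N_corr) || is.na(control$N_corr)) {
    stop("both estimates must be truncation-corrected before subtraction",
         call. = FALSE)
  }
  net <- if (order == "correct_then_subtract") {
    est$N_corr - control$N_corr
  } else {
    (est$N_prelim - control$N_prelim) * est$N_corr / est$N_prelim
  }
  if (net < 0) {
    warning("control exceeds sample; net ribonucleotide count floored at 0",
            call. = FALSE)
    net <- 0
  }
  est$N_net <- net
  est$control_lane_id <- control$lane_id %||% NA_character_
  est$subtraction_order <- order
  est
}

#' Ribonucleotide density per Gb of DNA
#'
#' Converts a per-genome ribonucleotide count to a density per 1e9 nt, the
#' unit used for cross-genome comparisons.  For an `rnmp_estimate` the most
#' refined available count (`N_net`, else `N_corr`, else `N_prelim`) is
#' used.
#'
#' @param x an `rnmp_estimate`, or a bare per-genome count.
#' @param genome_size genome length in nt (taken from the estimate when
#'   available; default 24e6).
#' @param ... unused.
#' @return Density in ribonucleotides per Gb (full precision; see
#'   [format_density_k()] for reporting rounded to the nearest 1000).
#' @export
density_per_gb <- function(x, ...) UseMethod("density_per_gb")

#' @rdname density_per_gb
#' @export
density_per_gb.rnmp_estimate <- function(x, ...) {
  N <- if (!is.na(x$N_net)) x$N_net else if (!is.na(x$N_corr)) x$N_corr
       else x$N_prelim
  N * 1e9 / x$genome_size
}

#' @rdname density_per_gb
#' @export
density_per_gb.numeric <- function(x, genome_size = 24e6, ...) {
  x * 1e9 / genome_size
}

#' Format a per-Gb density rounded to the nearest thousand
#' @param x density in rNMPs per Gb.
#' @return Character, e.g. `"350K"`.
#' @export
format_density_k <- function(x) {
  sprintf("%.0fK", round(x / 1000))
}

#' @export
print.rnmp_estimate <- function(x, ...) {
  cat(sprintf("rNMP estimate for lane '%s' (genome %.3g nt)\n",
              x$lane_id %||% NA, x$genome_size))
  cat(sprintf("  N_prelim = %.1f", x$N_prelim))
  if (!is.na(x$N_corr)) cat(sprintf("  N_corr = %.1f", x$N_corr))
  if (!is.na(x$N_net)) {
    cat(sprintf("  N_net = %.1f (control '%s')", x$N_net,
                x$control_lane_id))
  }
  cat("\n")
  cat(sprintf("  density = %.0f per Gb (%s)\n", density_per_gb(x),
              format_density_k(density_per_gb(x))))
  invisible(x)
}
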