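#' Binned fragment-size distribution of a lane
#'
#' Sums the per-Gb fragment counts into half-open size bins `[k*w, (k+1)*w)`
#' of width `w` nt (default 50) and normalizes the binned values to sum to
#' 1.  Bins whose lower edge falls below the lane's minimum detectable size
#' `sz_min` are dropped before normalization, so only sizes the gel can
#' actually resolve are reported.
#'
#' @param table a normalized `fragment_count_table`.
#' @param bin_width bin width in nt (default 50).
#' @return A `binned_size_distribution`: `data.frame` with columns
#'   `bin_lo_nt`, `bin_hi_nt`, `count_per_gb` and `fraction`
#'   (`sum(fraction) == 1`), carrying `sz_min`, `bin_width` and the lane id
#'   as attributes.
#' @export
bin_distribution <- function(table, bin_width = 50) {
  stopifnot(inherits(table, "fragment_count_table"))
  stop_if_not_scalar_pos(bin_width, "bin_width")
  inc <- !table$excluded & !is.na(table$n_per_gb)
  if (!any(inc)) stop("no included, normalized intervals to bin",
                      call. = FALSE)
  sz <- table$size_nt[inc]
  v <- table$n_per_gb[inc]
  k <- floor(sz / bin_width)
  agg <- rowsum(v, k)
  lo <- as.numeric(rownames(agg)) * bin_width
  cnt <- agg[, 1L]
  sz_min <- attr(table, "cutoff")$sz_min_nt %||% 0
  keep <- lo >= sz_min
  if (!any(keep)) stop("no bins at or above sz_min", call. = FALSE)
  lo <- lo[keep]
  cnt <- cnt[keep]
  ord <- order(lo)
  lo <- unname(lo[ord])
  cnt <- unname(cnt[ord])
  structure(
    data.frame(bin_lo_nt = lo, bin_hi_nt = lo + bin_width,
               count_per_gb = cnt, fraction = cnt / sum(cnt)),
    sz_min = sz_min, bin_width = bin_width,
    lane_id = attr(table, "lane_id"),
    class = c("binned_size_distribution", "data.frame")
  )
}

#' Restrict binned distributions to their common size support
#'
#' Minimum detectable sizes differ between gels, so cross-gel comparisons
#' are restricted to bins above the largest `sz_min` among the
#' distributions; each distribution is then renormalized to sum to 1.
#' The operation is idempotent.
#'
#' @param dists a list of `binned_size_distribution` objects (at least 2).
#' @return A list of restricted, renormalized distributions.
#' @export
restrict_common_support <- function(dists) {
  if (length(dists) < 2L) stop("need at least 2 distributions",
                               call. = FALSE)
  lapply(dists, function(d) stopifnot(inherits(d,
                                               "binned_size_distribution")))
  sz_min <- max(vapply(dists, function(d) attr(d, "sz_min") %||% 0,
                       numeric(1)))
  lapply(dists, function(d) {
    keep <- d$bin_lo_nt >= sz_min
    if (!any(keep)) stop("empty common support at sz_min = ", sz_min,
                         call. = FALSE)
    out <- d[keep, , drop = FALSE]
    out$fraction <- out$count_per_gb / sum(out$count_per_gb)
    attr(out, "sz_min") <- sz_min
    attr(out, "bin_width") <- attr(d, "bin_width")
    attr(out, "lane_id") <- attr(d, "lane_id")
    class(out) <- class(d)
    rownames(out) <- NULL
    out
  })
}

#' Within-lane fraction profile
#'
#' Normalizes each densitometry sample of a (background-subtracted) lane to
#' the sum over the whole lane, so that profiles of lanes with different
#' loading become directly comparable, as in strand-specific Southern
#' comparisons.
#'
#' @param profile a background-subtracted [intensity_profile()].
#' @return An [intensity_profile()] whose intensities sum to 1.
#' @export
lane_fraction_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  s <- sum(profile$intensity_au)
  if (!is.finite(s) || s <= 0) {
    stop("lane sums to zero; cannot compute fraction profile",
         call. = FALSE)
  }
  update_profile(profile, profile$intensity_au / s,
                 extra_meta = list(normalized = "lane_fraction"))
}

#' @export
print.binned_size_distribution <- function(x, ...) {
  cat(sprintf("Binned size distribution '%s': %d bins of %g nt, sz_min = %.4g\n",
              attr(x, "lane_id") %||% NA, nrow(x), attr(x, "bin_width"),
              attr(x, "sz_min")))
  invisible(x)
}

#' @export
plot.binned_size_distribution <- function(x, y_axis = c("fraction",
                                                        "count_per_gb"),
                                          ...) {
  y_axis <- match.arg(y_axis)
  graphics::plot((x$bin_lo_nt + x$bin_hi_nt) / 2, x[[y_axis]], log = "x",
                 type = "s", xlab = "fragment size (nt)",
                 ylab = if (y_axis == "fraction") "fraction of fragments"
                 else "fragments per Gb",
                 main = attr(x, "lane_id") %||% "", ...)
  invisible(x)
}
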